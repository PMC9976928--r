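test_that("simulate_genome is seed-deterministic with the requested sizes", {
  g1 <- simulate_genome(c(a = 5000L, b = 1000L), seed = 1)
  g2 <- simulate_genome(c(a = 5000L, b = 1000L), seed = 1)
  g3 <- simulate_genome(c(a = 5000L, b = 1000L), seed = 2)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
  expect_equal(unname(nchar(g1)), c(5000L, 1000L))
  gc <- sum(strsplit(g1[["a"]], "")[[1]] %in% c("G", "C")) / 5000
  expect_equal(gc, 0.41, tolerance = 0.05)
})

test_that("the ancestral element satisfies its own construction contract", {
  anc <- make_ancestral_element(seed = 4)
  expect_true(inherits(anc, "ancestral_element"))
  expect_equal(nchar(anc$sequence), 2400L)
  # perfect TIRs at the termini
  left <- substr(anc$sequence, 1, 28)
  right <- substr(anc$sequence, 2400 - 27, 2400)
  expect_identical(right, oracle_revcomp(left))
  tir <- detect_tir(anc$sequence)
  expect_equal(tir$length, 28L)
  expect_equal(tir$mismatches, 0L)
  expect_equal(tir$left_offset, 0L)
  # the planted ORF is the recovered ORF
  orf <- find_longest_orf(anc$sequence)
  expect_equal(orf$nt_start, anc$orf_start)
  expect_identical(orf$protein_seq, anc$protein_seq)
  # catalytic triad at the planted residues with spacer 35
  triad <- find_triad(orf$protein_seq)
  expect_equal(unname(triad$pos_d2), unname(anc$triad["d2"]))
  expect_equal(unname(triad$pos_d3), unname(anc$triad["d3"]))
  expect_equal(triad$spacer23, 35L)
  # both DNA-binding motifs hit at their planted positions
  hits <- purrr::map(toy_dbd_profiles(), ~ scan_motif(orf$protein_seq, .x))
  expect_true(all(purrr::map_lgl(hits, "hit")))
  expect_equal(hits$Brk$position, unname(anc$motif_positions["Brk"]))
  expect_equal(hits$HTH$position, unname(anc$motif_positions["HTH"]))
})

test_that("make_ancestral_element validates its size constraints", {
  expect_error(make_ancestral_element(orf_aa = 300L), "at least 301")
  expect_error(make_ancestral_element(element_len = 1300L), "too small")
})

test_that("solve_k2p_rates inverts the K2P formula to high precision", {
  for (K in c(0.001, 0.01, 0.05, 0.15, 0.25, 0.3)) {
    r <- solve_k2p_rates(K)
    expect_equal(unname(r["P"] / r["Q"]), 2, tolerance = 1e-9)
    back <- -0.5 * log(1 - 2 * r["P"] - r["Q"]) - 0.25 * log(1 - 2 * r["Q"])
    expect_equal(unname(back), K, tolerance = 1e-9)
  }
  expect_equal(solve_k2p_rates(0), c(P = 0, Q = 0))
  expect_error(solve_k2p_rates(0.4), "K_target")
})

test_that("mutate_to_k at K = 0 is the identity and respects the seed", {
  anc <- make_ancestral_element(seed = 6)
  expect_identical(mutate_to_k(anc$sequence, 0), anc$sequence)
  m1 <- mutate_to_k(anc$sequence, 0.1, seed = 3)
  m2 <- mutate_to_k(anc$sequence, 0.1, seed = 3)
  expect_identical(m1, m2)
  expect_equal(nchar(m1), nchar(anc$sequence))
})

test_that("plant_family records an exact, sliceable truth table", {
  g <- simulate_genome(c(chrA = 120000L, chrB = 60000L), seed = 11)
  anc <- make_ancestral_element(seed = 12)
  bursts <- tibble::tibble(K_target = c(0, 0.1), n_copies = c(4L, 4L),
                           intact_fraction = c(1, 0.5))
  planted <- plant_family(g, anc, bursts, seed = 13)
  truth <- planted$truth
  expect_equal(nrow(truth), 8L)
  expect_equal(sum(truth$burst_id == 1), 4L)
  for (i in seq_len(nrow(truth))) {
    contig <- planted$genome[[truth$chrom[i]]]
    el <- substr(contig, truth$true_start[i] + 1L, truth$true_end[i])
    # the TA target-site duplication flanks every copy
    expect_identical(substr(contig, truth$true_start[i] - 1L,
                            truth$true_start[i]), "TA")
    expect_identical(substr(contig, truth$true_end[i] + 1L,
                            truth$true_end[i] + 2L), "TA")
    sense <- if (truth$strand[i] == "-") oracle_revcomp(el) else el
    if (truth$K_target[i] == 0 && truth$intact[i]) {
      expect_identical(sense, anc$sequence)   # burst 1 intact copies are exact
    }
    if (truth$truncation[i] %in% c("trunc_left", "trunc_right")) {
      expect_lte(nchar(el), 0.8 * nchar(anc$sequence))
    } else if (truth$truncation[i] == "orf_break") {
      # a codon of the transposase is replaced by TAA: length is unchanged
      expect_equal(nchar(el), nchar(anc$sequence))
      stop_at <- anc$orf_start + 600L
      expect_identical(substr(sense, stop_at + 1L, stop_at + 3L), "TAA")
    }
  }
  # planted genome grows by exactly the inserted material
  grown <- sum(nchar(planted$genome)) - sum(nchar(g))
  expect_equal(grown, sum(truth$true_end - truth$true_start) + 2L * nrow(truth))
})

test_that("plant_family enforces site spacing and aborts on saturation", {
  g <- simulate_genome(c(tiny = 15000L), seed = 14)
  anc <- make_ancestral_element(seed = 15)
  bursts <- tibble::tibble(K_target = 0, n_copies = 50L, intact_fraction = 1)
  expect_error(plant_family(g, anc, bursts, seed = 16), "well-separated")
})

test_that("truth_to_hits insets hits inside the true boundaries", {
  g <- simulate_genome(c(chrA = 150000L), seed = 17)
  anc <- make_ancestral_element(seed = 18)
  planted <- plant_family(g, anc,
                          tibble::tibble(K_target = 0, n_copies = 6L,
                                         intact_fraction = 1), seed = 19)
  hits <- truth_to_hits(planted$truth, seed = 20)
  expect_equal(nrow(hits), 6L)
  expect_true(all(hits$start - planted$truth$true_start >= 5L))
  expect_true(all(hits$start - planted$truth$true_start <= 25L))
  expect_true(all(planted$truth$true_end - hits$end >= 5L))
  expect_true(all(planted$truth$true_end - hits$end <= 25L))
  expect_identical(hits$strand, planted$truth$strand)
})

test_that("make_gene_models places non-overlapping genes with valid exons", {
  g <- simulate_genome(c(c1 = 80000L, c2 = 40000L), seed = 21)
  genes <- make_gene_models(g, n_genes = 12L, seed = 22)
  expect_equal(nrow(genes), 12L)
  expect_true(all(genes$end > genes$start))
  # pairwise non-overlap per chromosome
  for (ctg in unique(genes$chrom)) {
    sub <- genes[genes$chrom == ctg, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  # exons are ordered, within the gene, non-overlapping
  for (i in seq_len(nrow(genes))) {
    es <- as.integer(strsplit(genes$exon_starts[i], ",")[[1]])
    ee <- as.integer(strsplit(genes$exon_ends[i], ",")[[1]])
    expect_equal(length(es), 3L)
    expect_true(all(ee > es))
    expect_true(all(es[-1] >= ee[-3]))
    expect_gte(es[1], genes$start[i])
    expect_lte(ee[3], genes$end[i])
  }
  expect_true(all(genes$expression > 0))
})

test_that("make_chromatin_states tiles each contig completely without overlap", {
  g <- simulate_genome(c(c1 = 30000L, c2 = 12000L), seed = 23)
  st <- make_chromatin_states(g, n_states = 5L, seed = 24)
  for (ctg in c("c1", "c2")) {
    sub <- st[st$chrom == ctg, ]
    expect_equal(sub$start[1], 0L)
    expect_equal(sub$end[nrow(sub)], unname(nchar(g[ctg])))
    expect_true(all(sub$start[-1] == sub$end[-nrow(sub)]))
  }
  expect_true(all(grepl("^state_", st$state)))
})

test_that("simulate_sites draws only TA positions and respects genic_fold = 0", {
  g <- simulate_genome(c(c1 = 50000L), seed = 25)
  genes <- make_gene_models(g, n_genes = 4L, seed = 26,
                            len_range = c(2000L, 4000L))
  sim <- simulate_sites(g, genes, n_sites = 400L, genic_fold = 0, seed = 27)
  dinuc <- vapply(seq_len(400), function(i) {
    substr(g[[sim$sites$chrom[i]]], sim$sites$position[i] + 1L,
           sim$sites$position[i] + 2L)
  }, character(1))
  expect_true(all(dinuc == "TA"))
  in_gene <- purrr::map_lgl(sim$sites$position, function(p) {
    any(p >= genes$start & p < genes$end)
  })
  expect_false(any(in_gene))
  expect_equal(nrow(sim$truth), 400L)
})

test_that("simulate_sites motif weighting concentrates sites on the motif", {
  set.seed(28)
  g <- simulate_genome(c(c1 = 400000L), seed = 28)
  sim <- simulate_sites(g, genes = NULL, n_sites = 200L,
                        motif_weights = c(AAGTACTT = 1e6), seed = 29)
  ctx <- vapply(seq_len(200), function(i) {
    substr(g[["c1"]], sim$sites$position[i] - 2L, sim$sites$position[i] + 5L)
  }, character(1))
  expect_gt(mean(ctx == "AAGTACTT"), 0.95)
})
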