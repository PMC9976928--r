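# A small hand-checkable gene layout reused across tests:
#   gene_plus : [2000, 6000) on +, exons [2000,2800) [3400,4200) [4800,6000)
#   gene_minus: [9000, 12000) on -, no exon model (genic_unresolved)
toy_genes <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(2000L, 9000L), end = c(6000L, 12000L),
    strand = c("+", "-"), name = c("gp", "gm"),
    expression = c(10, 1),
    exon_starts = c("2000,3400,4800", NA),
    exon_ends = c("2800,4200,6000", NA))
}

test_that("assign_feature matches the per-site brute-force oracle", {
  genes <- toy_genes()
  positions <- c(0L, 999L, 1000L, 1999L, 2000L, 2799L, 2800L, 3399L, 3400L,
                 5999L, 6000L, 6999L, 7000L, 8000L, 8999L, 9000L, 11999L,
                 12000L, 12999L, 13000L, 50000L)
  sites <- tibble::tibble(chrom = "chr1", position = positions,
                          strand = NA_character_, sample_label = "t")
  ann <- assign_feature(sites, genes)
  want <- vapply(positions, oracle_feature, character(1), chrom = "chr1",
                 genes = genes)
  expect_identical(as.character(ann$category), want)
})

test_that("assign_feature agrees with the oracle on random layouts", {
  set.seed(61)
  for (rep in 1:10) {
    g <- simulate_genome(c(c1 = 60000L), seed = rep)
    genes <- make_gene_models(g, n_genes = 4L, seed = rep + 100L,
                              len_range = c(1500L, 4000L))
    pos <- sort(sample(0:59999, 300))
    sites <- tibble::tibble(chrom = "c1", position = pos,
                            strand = NA_character_, sample_label = "t")
    ann <- assign_feature(sites, genes)
    want <- vapply(pos, oracle_feature, character(1), chrom = "c1",
                   genes = genes)
    expect_identical(as.character(ann$category), want)
  }
})

test_that("assign_feature resolves overlaps by precedence then nearest TSS", {
  genes <- toy_genes()
  # promoter of gp is [1000, 2000); put a second gene's body across it
  genes2 <- dplyr::bind_rows(
    genes,
    tibble::tibble(chrom = "chr1", start = 500L, end = 1800L, strand = "+",
                   name = "gx", expression = 5,
                   exon_starts = NA, exon_ends = NA))
  s <- tibble::tibble(chrom = "chr1", position = 1500L,
                      strand = NA_character_, sample_label = "t")
  ann <- assign_feature(s, genes2)
  # promoter (rank 1) beats genic_unresolved (rank 4)
  expect_identical(as.character(ann$category), "promoter")
  expect_identical(ann$gene_name, "gp")
})

test_that("gene_body_decile uses transcript orientation and bin = min(floor(10f), 9)", {
  genes <- toy_genes()
  # gp is 4000 bp: position 2000 -> f = 0 -> bin 0; 5999 -> f ~ 1 -> bin 9
  # gm is on -: position 11999 (first transcribed base) -> bin 0
  sites <- tibble::tibble(chrom = "chr1",
                          position = c(2000L, 5999L, 11999L, 9000L, 100L),
                          strand = NA_character_, sample_label = "t")
  expect_message(dec <- gene_body_decile(sites, genes), "1 site")
  expect_equal(attr(dec, "n_skipped"), 1L)
  expect_equal(sum(dec$count), 4L)
  expect_equal(dec$count[dec$bin == 0], 2L)          # 2000 and 11999
  expect_equal(dec$count[dec$bin == 9], 2L)          # 5999 and 9000 (minus-end)
  expect_equal(sum(dec$fraction), 1)
})

test_that("tss_profile reports signed strand-aware distances", {
  genes <- toy_genes()
  # gp TSS at 2000 (+): site 2150 -> +150 (bin 100); site 1850 -> -150 (bin -200)
  # gm TSS at 11999 (-): site 11849 -> +150 downstream in transcript space
  sites <- tibble::tibble(chrom = "chr1",
                          position = c(2150L, 1850L, 11849L, 50000L),
                          strand = NA_character_, sample_label = "t")
  tp <- tss_profile(sites, genes, halfwidth = 3000L, bin_bp = 100L)
  expect_equal(sum(tp$count), 3L)                    # the far site is excluded
  expect_equal(tp$count[tp$bin_low == 100], 2L)
  expect_equal(tp$count[tp$bin_low == -200], 1L)
})

test_that("expression_binned_frequency normalises by group gene length", {
  genes <- toy_genes()                               # gm (low expr), gp (high)
  sites <- tibble::tibble(chrom = "chr1",
                          position = c(2500L, 3000L, 9500L, 100L),
                          strand = NA_character_, sample_label = "t")
  ef <- expression_binned_frequency(sites, genes, n_groups = 2L)
  expect_equal(ef$group, c(1L, 2L))
  expect_equal(ef$insertions, c(1L, 2L))             # group 1 = gm (3 kb)
  expect_equal(ef$freq_per_mb, c(1 / 0.003, 2 / 0.004))
  expect_error(expression_binned_frequency(sites, genes, n_groups = 3L),
               "fewer genes")
})

test_that("generate_random_loci is seed-deterministic and respects modes", {
  g <- simulate_genome(c(a = 30000L, b = 10000L), seed = 2)
  u1 <- generate_random_loci(g, n = 2000L, seed = 5)
  u2 <- generate_random_loci(g, n = 2000L, seed = 5)
  expect_identical(u1, u2)
  expect_true(all(u1$position >= 0))
  sizes <- setNames(nchar(g), names(g))
  expect_true(all(u1$position < sizes[u1$chrom]))
  # contig mass: chromosome a is 3x the length of b
  expect_gt(mean(u1$chrom == "a"), 0.6)
  ta <- generate_random_loci(g, n = 500L, seed = 5, mode = "ta_matched")
  dinuc <- vapply(seq_len(500), function(i) {
    substr(g[[ta$chrom[i]]], ta$position[i] + 1L, ta$position[i] + 2L)
  }, character(1))
  expect_true(all(dinuc == "TA"))
})

test_that("fisher_exact matches stats::fisher.test on random tables", {
  set.seed(71)
  a <- rpois(200, 8); b <- rpois(200, 40); c <- rpois(200, 8); d <- rpois(200, 40)
  got <- fisher_exact(a, b, c, d)
  want <- vapply(1:200, function(i) {
    stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2, byrow = TRUE))$p.value
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("fisher_exact handles degenerate margins and rejects bad input", {
  expect_equal(fisher_exact(0, 0, 0, 0), 1)
  expect_equal(fisher_exact(0, 10, 0, 20), 1)
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact(1.5, 2, 3, 4), "non-negative")
})

test_that("stars maps the documented p-value bands with inclusive bounds", {
  p <- c(1e-5, 1e-4, 5e-4, 0.001, 0.005, 0.01, 0.03, 0.05, 0.051, NA)
  expect_identical(stars(p),
                   c("****", "****", "***", "***", "**", "**", "*", "*", "ns",
                     NA_character_))
})

test_that("feature_distribution reports fractions, folds and stars per sample", {
  set.seed(73)
  g <- simulate_genome(c(c1 = 50000L), seed = 3)
  genes <- make_gene_models(g, n_genes = 3L, seed = 4,
                            len_range = c(1500L, 3000L))
  sites <- generate_random_loci(g, n = 300L, seed = 6)
  sites$sample_label <- rep(c("s1", "s2"), length.out = 300L)
  bg <- generate_random_loci(g, n = 3000L, seed = 7)
  fd <- feature_distribution(sites, genes, bg)
  expect_s3_class(fd, "feature_distribution")
  expect_equal(sort(unique(fd$sample)), c("s1", "s2"))
  expect_equal(nrow(fd), 12L)                        # 2 samples x 6 categories
  sums <- tapply(fd$fraction, fd$sample, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_true(all(fd$p_value >= 0 & fd$p_value <= 1))
  expect_true(all(fd$stars %in% c("****", "***", "**", "*", "ns")))
})

test_that("chromatin_state_enrichment rejects conflicting overlaps", {
  states <- tibble::tibble(chrom = "c1", start = c(0L, 500L),
                           end = c(1000L, 1500L),
                           state = c("state_01", "state_02"))
  s <- tibble::tibble(chrom = "c1", position = 10L, strand = NA_character_,
                      sample_label = "t")
  expect_error(chromatin_state_enrichment(s, states, s), "conflicting")
})

test_that("chromatin_state_enrichment counts per state with fold vs background", {
  states <- tibble::tibble(chrom = "c1", start = c(0L, 1000L),
                           end = c(1000L, 2000L),
                           state = c("state_01", "state_02"))
  obs <- tibble::tibble(chrom = "c1", position = c(10L, 20L, 30L, 1500L),
                        strand = NA_character_, sample_label = "t")
  bg <- tibble::tibble(chrom = "c1", position = c(100L, 1100L, 1200L, 1300L),
                       strand = NA_character_, sample_label = "random")
  en <- chromatin_state_enrichment(obs, states, bg)
  expect_equal(en$obs_count, c(3L, 1L))
  expect_equal(en$bg_count, c(1L, 3L))
  expect_equal(en$fold, c((3 / 4) / (1 / 4), (1 / 4) / (3 / 4)))
})
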