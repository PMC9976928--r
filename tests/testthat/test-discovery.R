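test_that("merge_hits matches a brute-force union oracle on random intervals", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:30, 1)
    gap <- sample(0:300, 1)
    s <- sample(0:5000, n, replace = TRUE)
    e <- s + sample(50:400, n, replace = TRUE)
    hits <- tibble::tibble(chrom = "c1", start = s, end = e, strand = "+",
                           evalue = 1e-150)
    got <- merge_hits(hits, max_gap = gap)
    want <- oracle_merge(s, e, gap)
    expect_equal(got$core_start, want[, 1])
    expect_equal(got$core_end, want[, 2])
  }
})

test_that("merge_hits keeps strands separate and filters by identity/e-value", {
  hits <- tibble::tibble(
    chrom = "c1", start = c(0L, 50L, 0L), end = c(100L, 150L, 100L),
    strand = c("+", "+", "-"),
    percent_identity = c(95, 95, 95), evalue = c(1e-150, 1e-50, 1e-150))
  out <- merge_hits(hits, max_gap = 0L)
  # the 1e-50 hit fails the default 1e-100 cut; strands never merge
  expect_equal(nrow(out), 2L)
  expect_setequal(out$strand, c("+", "-"))
  out2 <- merge_hits(dplyr::mutate(hits, evalue = 1e-150), max_gap = 0L,
                     min_identity = 96)
  expect_equal(nrow(out2), 0L)
})

test_that("merge_hits merges at gap == max_gap and splits just beyond", {
  hits <- tibble::tibble(chrom = "c1", start = c(0L, 110L), end = c(100L, 200L),
                         strand = "+", evalue = 1e-150)
  expect_equal(nrow(merge_hits(hits, max_gap = 10L)), 1L)
  expect_equal(nrow(merge_hits(hits, max_gap = 9L)), 2L)
})

test_that("merge_hits rejects start >= end records individually", {
  hits <- tibble::tibble(chrom = "c1", start = c(10L, 30L), end = c(10L, 60L),
                         strand = "+", evalue = 1e-150)
  expect_message(out <- merge_hits(hits), "rejected 1")
  expect_equal(nrow(out), 1L)
})

test_that("extract_flanks slices plus and minus loci correctly", {
  set.seed(7)
  contig <- rand_dna(500)
  g <- c(chr = contig)
  loci <- tibble::tibble(chrom = "chr", core_start = 200L, core_end = 260L,
                         strand = c("+", "-"))
  fl <- extract_flanks(loci, g, flank_size = 50L)
  expect_identical(fl$core_seq[1], substr(contig, 201, 260))
  expect_identical(fl$left_flank[1], substr(contig, 151, 200))
  expect_identical(fl$right_flank[1], substr(contig, 261, 310))
  # minus strand: sequence reverse-complemented, flanks swapped
  expect_identical(fl$core_seq[2], oracle_revcomp(substr(contig, 201, 260)))
  expect_identical(fl$left_flank[2], oracle_revcomp(substr(contig, 261, 310)))
  expect_identical(fl$right_flank[2], oracle_revcomp(substr(contig, 151, 200)))
})

test_that("extract_flanks truncates at contig edges and checks coordinates", {
  g <- c(chr = paste(rep("ACGT", 30), collapse = ""))
  fl <- extract_flanks(tibble::tibble(chrom = "chr", core_start = 5L,
                                      core_end = 115L, strand = "+"),
                       g, flank_size = 50L)
  expect_equal(nchar(fl$left_flank), 5L)
  expect_equal(nchar(fl$right_flank), 5L)
  expect_error(
    extract_flanks(tibble::tibble(chrom = "chr", core_start = 10L,
                                  core_end = 500L, strand = "+"), g),
    "invalid coordinates")
  expect_error(
    extract_flanks(tibble::tibble(chrom = "nope", core_start = 0L,
                                  core_end = 10L, strand = "+"), g),
    "absent from genome")
})

test_that("detect_tir recovers a planted perfect TIR exactly", {
  tir <- "CAGTGCTGGCCAAATTGCGTCAGTCAGG"   # 28 bp
  spacer <- paste(rep("A", 150), collapse = "")
  el <- paste0(tir, spacer, oracle_revcomp(tir))
  hit <- detect_tir(el)
  expect_identical(hit$left_seq, tir)
  expect_identical(hit$right_seq, oracle_revcomp(tir))
  expect_equal(hit$length, 28L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$left_offset, 0L)
  expect_equal(hit$right_offset, 0L)
  expect_equal(hit$score, 28L)
})

test_that("detect_tir counts substitutions and applies the mismatch cap", {
  tir <- "CAGTGCTGGCCAAATTGCGTCAGTCAGG"
  spacer <- paste(rep("A", 150), collapse = "")
  right <- strsplit(oracle_revcomp(tir), "")[[1]]
  # two substitutions at distances 5 and 9 from the element 3' terminus
  flip <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
  right[28 - 5] <- flip(right[28 - 5])
  right[28 - 9] <- flip(right[28 - 9])
  el <- paste0(tir, spacer, paste(right, collapse = ""))
  hit <- detect_tir(el)
  expect_equal(hit$mismatches, 2L)
  expect_equal(hit$length, 28L)
  # 7 mismatches in 28 bp exceeds the 20% cap everywhere
  right7 <- strsplit(oracle_revcomp(tir), "")[[1]]
  for (d in c(2, 5, 8, 12, 16, 20, 24)) right7[28 - d] <- flip(right7[28 - d])
  el7 <- paste0(tir, spacer, paste(right7, collapse = ""))
  expect_null(detect_tir(el7))
})

test_that("detect_tir false-positive rate on random sequence is low", {
  set.seed(99)
  hits <- sum(vapply(1:1000, function(i) {
    !is.null(detect_tir(rand_dna(300)))
  }, logical(1)))
  expect_lte(hits, 20)  # <= 2% of 1000 random sequences
})

test_that("detect_tsd returns the longest exact flank word and flags TA", {
  expect_null(detect_tsd("AAAAAGGG", "TTTAAAAA"))
  hit <- detect_tsd("CCCCACGTA", "ACGTACCCC")
  expect_identical(hit$sequence, "ACGTA")
  expect_equal(hit$length, 5L)
  expect_false(hit$is_ta)
  ta <- detect_tsd("GGGGGTA", "TACCCCC")
  expect_identical(ta$sequence, "TA")
  expect_true(ta$is_ta)
  # N never matches
  expect_null(detect_tsd("GGGNA", "NACCC"))
})

test_that("call_boundaries recovers exact termini of a constructed element", {
  set.seed(123)
  tir <- "CAGTGCTGGCCAAATTGCGTCAGTCAGG"
  el <- paste0(tir, rand_dna(300), oracle_revcomp(tir))
  # keep the flank segments near the TSD free of TA (and of chance TSD
  # words) so the construction is unambiguous; a chance double-TA is the
  # documented ambiguity that only the family polish pass resolves
  flank <- function(n) rand_dna(n, gc = 1)           # G/C only
  contig <- paste0(rand_dna(240), flank(60), "TA", el, "TA", flank(60),
                   rand_dna(240))
  true_start <- 302L; true_end <- true_start + nchar(el)
  loci <- extract_flanks(
    tibble::tibble(chrom = "c", core_start = true_start + 12L,
                   core_end = true_end - 17L, strand = "+"),
    c(c = contig), flank_size = 100L)
  out <- call_boundaries(loci)
  expect_equal(out$element_start, true_start)
  expect_equal(out$element_end, true_end)
  expect_identical(out$element_seq, el)
  expect_true(out$tsd_is_ta)
  expect_identical(out$tsd_seq, "TA")
  expect_equal(out$tir_len, 28L)
})

test_that("call_boundaries maps minus-strand loci back to genomic space", {
  set.seed(124)
  tir <- "CAGTGCTGGCCAAATTGCGTCAGTCAGG"
  el <- paste0(tir, rand_dna(300), oracle_revcomp(tir))
  flank <- function(n) rand_dna(n, gc = 1)           # G/C only, no chance TA
  contig <- paste0(rand_dna(190), flank(60), "TA", oracle_revcomp(el), "TA",
                   flank(60), rand_dna(190))
  true_start <- 252L; true_end <- true_start + nchar(el)
  loci <- extract_flanks(
    tibble::tibble(chrom = "c", core_start = true_start + 9L,
                   core_end = true_end - 21L, strand = "-"),
    c(c = contig), flank_size = 100L)
  out <- call_boundaries(loci)
  expect_equal(out$element_start, true_start)
  expect_equal(out$element_end, true_end)
  expect_identical(out$element_seq, el)  # reported in transposase sense
  expect_true(out$tsd_is_ta)
})

test_that("loci without a detectable TIR keep core boundaries at score 0", {
  set.seed(125)
  contig <- rand_dna(1200)
  loci <- extract_flanks(
    tibble::tibble(chrom = "c", core_start = 400L, core_end = 800L,
                   strand = "+"),
    c(c = contig), flank_size = 100L)
  out <- call_boundaries(loci)
  if (is.na(out$tir_len)) {   # random sequence: overwhelmingly likely
    expect_equal(out$element_start, 400L)
    expect_equal(out$element_end, 800L)
    expect_equal(out$boundary_score, 0)
  } else {
    expect_gte(out$boundary_score, 0)
  }
})
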