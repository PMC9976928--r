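# Independent brute-force oracles used to cross-check the package
# implementations. Everything here is written from first principles on
# purpose: no code is shared with the package internals.

# Random DNA string (plain base R, independent of the package generator).
rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# Manual reverse complement via chartr + string reversal.
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Brute-force interval union with a merge gap: mark every covered (or
# gap-bridged) unit, then read off maximal runs. Intervals are 0-based
# half-open; two intervals merge when the gap between them is <= max_gap.
oracle_merge <- function(starts, ends, max_gap = 0L) {
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  out_s <- starts[1]; out_e <- ends[1]
  res <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e + max_gap) {
      out_e <- max(out_e, ends[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  do.call(rbind, res)
}

# Textbook Needleman-Wunsch global alignment score with linear gap costs.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- gap * (0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      diag <- prev[j] + if (av[i] == bv[j]) match else mismatch
      cur[j + 1] <- max(diag, prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1]
}

# Closed-form Kimura 2-parameter distance from two equal-length gapped
# sequences, computed independently of the package (explicit base-pair
# tables rather than purine logic).
oracle_k2p <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]; bv <- strsplit(toupper(b), "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  if (n == 0) return(NULL)
  pair <- paste0(pmin(av, bv), pmax(av, bv))
  transitions <- sum(pair %in% c("AG", "CT"))
  transversions <- sum(av != bv) - transitions
  P <- transitions / n; Q <- transversions / n
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  list(P = P, Q = Q, n = n,
       K = if (a1 <= 0 || a2 <= 0) NA_real_ else -0.5 * log(a1) - 0.25 * log(a2),
       saturated = a1 <= 0 || a2 <= 0)
}

# Exhaustive catalytic-triad search: all (i, j, k) aspartate triples with
# k = j + spacer + 1 and j - i inside the range; smallest i, then j wins.
oracle_triad <- function(protein, spacer = 35L, range = c(50L, 250L)) {
  aa <- strsplit(toupper(protein), "")[[1]]
  d <- which(aa == "D")
  best <- NULL
  for (i in d) for (j in d) {
    if (j - i < range[1] || j - i > range[2]) next
    k <- j + spacer + 1L
    if (k > length(aa) || aa[k] != "D") next
    if (is.null(best) || i < best[1] || (i == best[1] && j < best[2])) {
      best <- c(i, j, k)
    }
  }
  best
}

# Per-site feature assignment by plain loops: precedence promoter > exon >
# intron > genic_unresolved > downstream > intergenic; within a category the
# gene with the nearest TSS wins.
oracle_feature <- function(pos, chrom, genes, promoter_bp = 1000L,
                           downstream_bp = 1000L) {
  best <- list(rank = 7L, gene = NA_character_, dist = Inf)
  consider <- function(rank, gene, tss) {
    d <- abs(pos - tss)
    if (rank < best$rank || (rank == best$rank && d < best$dist)) {
      best <<- list(rank = rank, gene = gene, dist = d)
    }
  }
  for (g in seq_len(nrow(genes))) {
    if (genes$chrom[g] != chrom) next
    s <- genes$start[g]; e <- genes$end[g]; plus <- genes$strand[g] == "+"
    tss <- if (plus) s else e - 1L
    has_ex <- all(c("exon_starts", "exon_ends") %in% names(genes)) &&
      !is.na(genes$exon_starts[g]) && !is.na(genes$exon_ends[g])
    prom <- if (plus) c(max(s - promoter_bp, 0L), s) else c(e, e + promoter_bp)
    down <- if (plus) c(e, e + downstream_bp) else c(max(s - downstream_bp, 0L), s)
    if (pos >= prom[1] && pos < prom[2]) consider(1L, genes$name[g], tss)
    in_exon <- FALSE
    if (has_ex) {
      es <- as.integer(strsplit(genes$exon_starts[g], ",")[[1]])
      ee <- as.integer(strsplit(genes$exon_ends[g], ",")[[1]])
      in_exon <- any(pos >= es & pos < ee)
    }
    if (in_exon) consider(2L, genes$name[g], tss)
    if (pos >= s && pos < e) {
      if (has_ex) {
        if (!in_exon) consider(3L, genes$name[g], tss)
      } else {
        consider(4L, genes$name[g], tss)
      }
    }
    if (pos >= down[1] && pos < down[2]) consider(5L, genes$name[g], tss)
  }
  c("promoter", "exon", "intron", "genic_unresolved", "downstream",
    "intergenic", "intergenic")[best$rank]
}

# Build a minimal outfmt-6 line.
outfmt6_line <- function(qseqid, sseqid, pident, length, sstart, send,
                         evalue) {
  paste(qseqid, sseqid, pident, length, 0, 0, 1, length, sstart, send,
        format(evalue, scientific = TRUE), 100, sep = "\t")
}

# Hamming mismatch fraction of two equal-length strings.
hamming_frac <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  mean(av != bv)
}
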