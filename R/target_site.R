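# Target-site sequence context: per-position base counts around the TA
# insertion dinucleotide, consensus recovery and palindrome scoring.

IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

#' Base-count matrix around TA insertion sites
#'
#' Extracts the genomic window of `halfwidth` bp on each side of the TA
#' target dinucleotide at every site (reverse-complemented for
#' minus-strand sites so the window is always in insertion orientation),
#' counts bases per position, and derives the consensus (per-position
#' majority base; ties become IUPAC ambiguity codes) and the palindrome
#' score of the central 8-mer. Sites whose genomic dinucleotide is not TA
#' are dropped with a message; windows truncated by a contig edge are
#' excluded from the counts and tallied as partial.
#'
#' @param sites Site tibble.
#' @param genome Named character vector of contigs.
#' @param halfwidth Context half-width, bp (default 10).
#' @param validate_ta Drop sites whose genome dinucleotide is not TA.
#' @return A `target_site_matrix` list: `halfwidth`, `counts` (4 x
#'   (2*halfwidth + 2), columns named by offset from the TA start),
#'   `consensus`, `central_8mer`, `palindrome_score`, `n_sites`,
#'   `n_partial`, `n_non_ta`.
#' @export
target_site_matrix <- function(sites, genome, halfwidth = 10L, validate_ta = TRUE) {
  genome <- as_genome(genome)
  width <- 2L * halfwidth + 2L
  dinuc <- vapply(seq_len(nrow(sites)), function(i) {
    substr(genome[[sites$chrom[i]]], sites$position[i] + 1L, sites$position[i] + 2L)
  }, character(1))
  non_ta <- dinuc != "TA"
  if (any(non_ta)) {
    inform(sprintf("%d site(s) not TA-anchored%s", sum(non_ta),
                   if (validate_ta) " (excluded)" else ""))
    if (validate_ta) sites <- sites[!non_ta, , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4L, width, dimnames = list(bases, seq_len(width) - halfwidth - 1L))
  n_partial <- 0L
  for (i in seq_len(nrow(sites))) {
    contig <- genome[[sites$chrom[i]]]
    p <- sites$position[i]
    lo <- p - halfwidth; hi <- p + 1L + halfwidth      # 0-based inclusive
    if (lo < 0L || hi >= nchar(contig)) {
      n_partial <- n_partial + 1L
      next
    }
    win <- substr(contig, lo + 1L, hi + 1L)
    if (!is.na(sites$strand[i]) && identical(sites$strand[i], "-")) win <- revcomp(win)
    ch <- seq_chars(win)
    ok <- ch %in% bases
    idx <- cbind(match(ch[ok], bases), which(ok))
    counts[idx] <- counts[idx] + 1L
  }
  consensus <- apply(counts, 2, function(col) {
    if (sum(col) == 0) return("N")
    winners <- bases[col == max(col)]
    IUPAC_FROM_SET[[paste(winners, collapse = "")]]
  })
  consensus <- paste(consensus, collapse = "")
  central <- substr(consensus, halfwidth - 2L, halfwidth + 5L)   # offsets -3..+4
  out <- list(halfwidth = halfwidth, counts = counts, consensus = consensus,
              central_8mer = central,
              palindrome_score = palindrome_score(central),
              n_sites = nrow(sites) - n_partial, n_partial = n_partial,
              n_non_ta = sum(non_ta))
  class(out) <- "target_site_matrix"
  out
}

#' Palindrome score of a DNA word
#'
#' Fraction of positions whose base equals the corresponding position of
#' the word's reverse complement; 1 for a perfect palindrome such as
#' `AAGTACTT`.
#'
#' @param word DNA word (IUPAC codes allowed).
#' @return Score in `[0, 1]`.
#' @export
palindrome_score <- function(word) {
  if (!nzchar(word)) return(NA_real_)
  a <- seq_chars(word)
  b <- seq_chars(revcomp(word))
  mean(a == b)
}

#' @export
print.target_site_matrix <- function(x, ...) {
  cat(sprintf("<target_site_matrix> %d sites (+%d partial, %d non-TA)\n",
              x$n_sites, x$n_partial, x$n_non_ta))
  cat("consensus:", x$consensus, "\n")
  cat(sprintf("central 8-mer: %s (palindrome score %.2f)\n",
              x$central_8mer, x$palindrome_score))
  invisible(x)
}
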