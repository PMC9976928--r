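# Evolutionary dynamics: global alignment, family consensus construction,
# identity statistics, Kimura two-parameter (K2P) divergence and
# coverage-vs-divergence landscapes.

#' Global pairwise alignment with linear gap costs
#'
#' Needleman-Wunsch global alignment under match +1 / mismatch -1 /
#' gap -2 (linear), computed by `Biostrings::pairwiseAlignment`.
#'
#' @param a,b DNA sequences (character scalars, `ACGTN`).
#' @param match,mismatch,gap Scoring parameters (gap is the per-base cost,
#'   given as a negative number).
#' @param max_len Guard against accidental whole-chromosome alignments.
#' @return List with `seq_a_aligned`, `seq_b_aligned` (equal-length gapped
#'   strings) and `score`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2,
                         max_len = 20000L) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  if (nchar(a) > max_len || nchar(b) > max_len) {
    abort(sprintf("sequence exceeds %d bp; align in windows instead", max_len))
  }
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                  baseOnly = FALSE, type = "DNA")
  al <- Biostrings::pairwiseAlignment(
    normalize_seq(a), normalize_seq(b), type = "global",
    substitutionMatrix = sub, gapOpening = 0, gapExtension = abs(gap))
  list(seq_a_aligned = as.character(Biostrings::alignedPattern(al)),
       seq_b_aligned = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Build a family consensus (or pick a representative)
#'
#' With more than five copies, builds a majority-rule consensus by
#' center-star alignment of every copy to the reference: per reference
#' column the majority base wins (ties broken in fixed A<C<G<T order and
#' counted), and columns where gaps outnumber bases are dropped. With five
#' or fewer copies the reference itself is returned as the family
#' representative (callers should pass the intact copy with complete TIRs
#' and an intact transposase).
#'
#' @param copies Character vector of copy sequences (sense orientation).
#' @param reference Anchor sequence; defaults to the longest copy.
#' @return A `consensus_element` list: `sequence`, `column_support`
#'   (4 x L base-count matrix, consensus mode only), `n_copies_used`,
#'   `mode`, `n_ties`.
#' @export
build_consensus <- function(copies, reference = NULL) {
  if (length(copies) == 0) abort("no copies supplied")
  copies <- vapply(copies, normalize_seq, character(1), USE.NAMES = FALSE)
  reference <- normalize_seq(reference %||% copies[[which.max(nchar(copies))]])
  if (length(copies) <= 5L) {
    out <- list(sequence = reference, column_support = NULL,
                n_copies_used = length(copies), mode = "representative",
                n_ties = 0L)
    class(out) <- "consensus_element"
    return(out)
  }
  L <- nchar(reference)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(c(bases, "-"), NULL))
  for (s in copies) {
    al <- align_global(s, reference)
    aa <- seq_chars(al$seq_a_aligned); bb <- seq_chars(al$seq_b_aligned)
    ref_col <- cumsum(bb != "-")
    keep <- bb != "-"
    obs <- aa[keep]; col <- ref_col[keep]
    for (x in c(bases, "-")) {
      sel <- obs == x
      if (any(sel)) {
        t <- tabulate(col[sel], nbins = L)
        counts[x, ] <- counts[x, ] + t
      }
    }
  }
  base_counts <- counts[bases, , drop = FALSE]
  gap_counts <- counts["-", ]
  keep_col <- gap_counts <= colSums(base_counts) & colSums(base_counts) > 0
  maxes <- apply(base_counts[, keep_col, drop = FALSE], 2, max)
  winner <- apply(base_counts[, keep_col, drop = FALSE], 2, which.max)
  n_ties <- sum(colSums(base_counts[, keep_col, drop = FALSE] ==
                          rep(maxes, each = 4)) > 1)
  if (n_ties > 0) inform(sprintf("%d consensus column(s) tied; broken A<C<G<T", n_ties))
  out <- list(sequence = paste(bases[winner], collapse = ""),
              column_support = base_counts[, keep_col, drop = FALSE],
              n_copies_used = length(copies), mode = "consensus",
              n_ties = n_ties)
  class(out) <- "consensus_element"
  out
}

#' @export
print.consensus_element <- function(x, ...) {
  cat(sprintf("<consensus_element> mode=%s, %d copies, %d bp\n",
              x$mode, x$n_copies_used, nchar(x$sequence)))
  invisible(x)
}

#' Mean pairwise identity of a sequence set
#'
#' All-pairs mode averages, over all unordered pairs, the match fraction on
#' columns where neither sequence has a gap (sequences of unequal length
#' are globally aligned first). Reference mode averages each sequence's
#' identity to a reference instead.
#'
#' @param seqs Character vector (>= 2 sequences for all-pairs mode).
#' @param mode `"all_pairs_mean"` (default) or `"to_reference"`.
#' @param reference Reference sequence for `"to_reference"` mode.
#' @return Identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(seqs, mode = c("all_pairs_mean", "to_reference"),
                              reference = NULL) {
  mode <- match.arg(mode)
  pair_id <- function(x, y) {
    if (nchar(x) != nchar(y)) {
      if (grepl("[^ACGTN-]", toupper(paste0(x, y)))) {
        abort("unequal-length non-nucleotide sequences must be pre-aligned")
      }
      al <- align_global(x, y)
      x <- al$seq_a_aligned; y <- al$seq_b_aligned
    }
    cx <- seq_chars(x); cy <- seq_chars(y)
    keep <- cx != "-" & cy != "-"
    if (!any(keep)) return(NA_real_)
    100 * mean(cx[keep] == cy[keep])
  }
  if (mode == "to_reference") {
    if (is.null(reference)) abort("reference required for to_reference mode")
    return(mean(vapply(seqs, pair_id, numeric(1), y = reference), na.rm = TRUE))
  }
  if (length(seqs) < 2) abort("need at least 2 sequences")
  ids <- utils::combn(length(seqs), 2, function(ix) pair_id(seqs[[ix[1]]], seqs[[ix[2]]]))
  mean(ids, na.rm = TRUE)
}

#' Kimura two-parameter divergence of an aligned pair
#'
#' Valid columns are those where both sequences carry an unambiguous base
#' (gaps and N excluded, pairwise deletion). With transition proportion P
#' and transversion proportion Q,
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`; when either log argument
#' is non-positive the distance is saturated (`K` is `NA` and the record is
#' excluded from landscapes).
#'
#' @param alignment List with `seq_a_aligned` / `seq_b_aligned` (from
#'   [align_global()]) or a character vector of two equal-length gapped
#'   sequences.
#' @return One-row tibble: `P`, `Q`, `K`, `valid_columns`, `aligned_bp`
#'   (columns where neither sequence is gapped), `saturated`.
#' @export
k2p <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 2) {
    alignment <- list(seq_a_aligned = alignment[1], seq_b_aligned = alignment[2])
  }
  a <- seq_chars(toupper(alignment$seq_a_aligned))
  b <- seq_chars(toupper(alignment$seq_b_aligned))
  if (length(a) != length(b)) abort("aligned sequences differ in length")
  bases <- c("A", "C", "G", "T")
  aligned <- a != "-" & b != "-"
  valid <- aligned & a %in% bases & b %in% bases
  n <- sum(valid)
  if (n == 0) abort("no comparable sites")
  av <- a[valid]; bv <- b[valid]
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  diff <- av != bv
  ts <- diff & (purine[av] == purine[bv])
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  saturated <- arg1 <= 0 || arg2 <= 0
  K <- if (saturated) NA_real_ else -0.5 * log(arg1) - 0.25 * log(arg2)
  tibble(P = P, Q = Q, K = K, valid_columns = n, aligned_bp = sum(aligned),
         saturated = saturated)
}

#' Per-copy divergence from the family consensus
#'
#' Globally aligns every copy to the consensus and computes its K2P
#' divergence (the copy-versus-consensus convention of repeat-landscape
#' tools).
#'
#' @param copy_seqs Named character vector of copy sequences.
#' @param consensus Consensus sequence or a `consensus_element`.
#' @return Divergence tibble with one row per copy (`copy_id`, `P`, `Q`,
#'   `K`, `valid_columns`, `aligned_bp`, `saturated`).
#' @export
divergence_from_consensus <- function(copy_seqs, consensus) {
  if (inherits(consensus, "consensus_element")) consensus <- consensus$sequence
  ids <- names(copy_seqs) %||% paste0("copy_", seq_along(copy_seqs))
  purrr::map2_dfr(copy_seqs, ids, function(s, id) {
    rec <- k2p(align_global(s, consensus))
    dplyr::bind_cols(tibble(copy_id = id), rec)
  })
}

#' Bin per-copy divergence into a coverage landscape
#'
#' Each non-saturated record contributes its aligned bp to the K% bin
#' `floor(100 K / bin_width)`; the binned coverages sum exactly to the
#' total aligned bp of the records used.
#'
#' @param records Divergence tibble (from [divergence_from_consensus()]).
#' @param bin_width Bin width in K percent (default 1).
#' @param family_id Optional family label stored on the result.
#' @return A `divergence_landscape` tibble: `bin_low` (bin lower edge, K%)
#'   and `coverage_bp`.
#' @export
landscape <- function(records, bin_width = 1, family_id = NULL) {
  drop <- records$saturated | is.na(records$K)
  if (any(drop)) inform(sprintf("excluded %d saturated record(s) from landscape", sum(drop)))
  rec <- records[!drop, , drop = FALSE]
  bins <- floor(100 * rec$K / bin_width)
  out <- tibble(bin = bins, coverage_bp = rec$aligned_bp) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(coverage_bp = sum(.data$coverage_bp), .groups = "drop") |>
    dplyr::mutate(bin_low = .data$bin * bin_width) |>
    dplyr::select("bin_low", "coverage_bp")
  structure(out, class = c("divergence_landscape", class(out)),
            bin_width = bin_width, family_id = family_id)
}

#' Flag young copies and recently active families
#'
#' A copy is young when its K divergence is strictly below `threshold`
#' (default 2%, the conventional bound for very recent insertions). The
#' family is called recently active when at least `min_young_copies` or at
#' least a fraction `min_young_frac` of its copies are young; the call is
#' stored in the `recently_active` attribute.
#'
#' @param records Divergence tibble.
#' @param threshold Young/old K boundary (default 0.02, strict `<`).
#' @param min_young_copies,min_young_frac Family-level activity rule.
#' @return The records tibble with a logical `young` column and a
#'   `recently_active` attribute.
#' @export
flag_young <- function(records, threshold = 0.02, min_young_copies = 5L,
                       min_young_frac = 0.10) {
  records$young <- !records$saturated & !is.na(records$K) & records$K < threshold
  n_young <- sum(records$young)
  attr(records, "recently_active") <-
    n_young >= min_young_copies || n_young >= min_young_frac * nrow(records)
  records
}

#' Family identity report
#'
#' Identity statistics mirroring a family summary table: mean all-pairs
#' transposase identity, 5' and 3' TIR identities across copies, and the
#' mean within-element identity between each copy's left TIR and the
#' reverse complement of its right TIR.
#'
#' @param transposases Character vector of intact transposase sequences
#'   (amino acid or nucleotide).
#' @param tir_left,tir_right Character vectors of left / right TIR
#'   sequences per copy (right TIR as it appears at the element 3' end).
#' @return One-row tibble of identity percentages.
#' @export
identity_report <- function(transposases, tir_left, tir_right) {
  intra <- mean(purrr::map2_dbl(tir_left, tir_right, function(l, r) {
    pairwise_identity(c(l, revcomp(r)))
  }))
  tibble(
    transposase_identity = if (length(transposases) >= 2) pairwise_identity(transposases) else 100,
    tir_identity_5p = if (length(tir_left) >= 2) pairwise_identity(tir_left) else 100,
    tir_identity_3p = if (length(tir_right) >= 2) pairwise_identity(tir_right) else 100,
    intraelement_tir_identity = intra
  )
}
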