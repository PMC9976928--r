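# Copy annotation: transposase ORF finding, DD35D catalytic-triad and
# DNA-binding-motif detection, intact/coding/fragment classification and
# family copy counting at coverage/identity thresholds.

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

#' Find the longest transposase ORF in an element
#'
#' Scans the three forward frames (the element is assumed to be in
#' transposase-sense orientation; the transposase is encoded by a single
#' intron-less gene) and returns the longest ATG-to-stop open reading frame
#' of at least `min_aa` residues.
#'
#' @param element_seq Element sequence, sense orientation.
#' @param min_aa Minimum protein length in residues (default 300,
#'   inclusive).
#' @return One-row tibble (`nt_start`, `nt_end` 0-based half-open within
#'   the element and including the stop codon, `protein_seq`, `length_aa`)
#'   or `NULL`.
#' @export
find_longest_orf <- function(element_seq, min_aa = 300L) {
  element_seq <- normalize_seq(element_seq)
  L <- nchar(element_seq)
  best <- NULL
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3L
    if (n_codon < 2L) next
    starts <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(element_seq, starts, starts + 2L)
    stop_idx <- which(codons %in% GENETIC_CODE_STOPS)
    atg_idx <- which(codons == "ATG")
    if (!length(stop_idx) || !length(atg_idx)) next
    for (si in stop_idx) {
      prev_stop <- max(c(0L, stop_idx[stop_idx < si]))
      cand <- atg_idx[atg_idx > prev_stop & atg_idx < si]
      if (!length(cand)) next
      ai <- min(cand)
      aa_len <- si - ai                      # residues excluding the stop
      if (aa_len < min_aa) next
      if (is.null(best) || aa_len > best$aa_len) {
        best <- list(frame = frame, ai = ai, si = si, aa_len = aa_len)
      }
    }
  }
  if (is.null(best)) return(NULL)
  nt_start <- best$frame + 3L * (best$ai - 1L)      # 0-based
  nt_end <- best$frame + 3L * best$si               # includes stop codon
  cds <- substr(element_seq, nt_start + 1L, nt_end - 3L)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             if.fuzzy.codon = "solve"))
  tibble(nt_start = nt_start, nt_end = nt_end,
         protein_seq = prot, length_aa = best$aa_len)
}

#' Find the DD35D catalytic triad in a transposase
#'
#' Searches for three aspartate residues D1, D2, D3 with exactly
#' `spacer23` residues between D2 and D3 and a D1-D2 spacing inside
#' `d1_d2_range` (the first spacer is variable in DD x D transposases).
#' When several triads exist the one with the smallest D1 position, then
#' smallest D2 position, wins.
#'
#' @param protein_seq Amino-acid sequence.
#' @param spacer23 Residues strictly between D2 and D3 (default 35).
#' @param d1_d2_range Allowed D2 - D1 position difference, inclusive.
#' @param allow_e Also accept glutamate (E) as the third residue (DDE
#'   variant); off by default.
#' @return One-row tibble (`pos_d1`, `pos_d2`, `pos_d3` 0-based,
#'   `spacer23`) or `NULL`.
#' @export
find_triad <- function(protein_seq, spacer23 = 35L, d1_d2_range = c(50L, 250L),
                       allow_e = FALSE) {
  if (!nzchar(protein_seq)) abort("empty protein")
  aa <- seq_chars(toupper(protein_seq))
  d_pos <- which(aa == "D")                          # 1-based
  third_pos <- if (allow_e) which(aa %in% c("D", "E")) else d_pos
  if (length(d_pos) < 2L || !length(third_pos)) return(NULL)
  best <- NULL
  for (j in d_pos) {
    k <- j + spacer23 + 1L
    if (!(k %in% third_pos)) next
    i_cand <- d_pos[d_pos >= j - d1_d2_range[2] & d_pos <= j - d1_d2_range[1]]
    if (!length(i_cand)) next
    i <- min(i_cand)
    if (is.null(best) || i < best$i || (i == best$i && j < best$j)) {
      best <- list(i = i, j = j, k = k)
    }
  }
  if (is.null(best)) return(NULL)
  tibble(pos_d1 = best$i - 1L, pos_d2 = best$j - 1L, pos_d3 = best$k - 1L,
         spacer23 = best$k - best$j - 1L)
}

#' Scan a protein with a position-weight motif profile
#'
#' Slides the profile over the protein and reports the best-scoring window
#' (leftmost on ties). A hit is called when the best score reaches the
#' profile's threshold. Residues absent from the profile's columns score 0.
#'
#' @param protein_seq Amino-acid sequence.
#' @param profile A [motif_profile()].
#' @return One-row tibble (`name`, `score`, `position` 0-based, `hit`).
#' @export
scan_motif <- function(protein_seq, profile) {
  aa <- seq_chars(toupper(protein_seq))
  w <- nrow(profile$matrix)
  n <- length(aa)
  if (w > n) {
    warn(sprintf("profile '%s' (width %d) wider than protein (%d aa): no hit",
                 profile$name, w, n))
    return(tibble(name = profile$name, score = NA_real_,
                  position = NA_integer_, hit = FALSE))
  }
  cols <- colnames(profile$matrix)
  col_idx <- match(aa, cols)
  scores <- vapply(seq_len(n - w + 1L), function(s) {
    ci <- col_idx[s:(s + w - 1L)]
    ok <- !is.na(ci)
    sum(profile$matrix[cbind(which(ok), ci[ok])])
  }, numeric(1))
  pos <- which.max(scores)
  tibble(name = profile$name, score = scores[pos],
         position = pos - 1L, hit = scores[pos] >= profile$threshold)
}

#' Toy DNA-binding-domain profiles
#'
#' Small consensus-peptide weight matrices standing in for the Brk and
#' helix-turn-helix (HTH) DNA-binding motifs of pogo-superfamily
#' transposases. Intended for tests and synthetic data; real analyses
#' should supply curated profiles via [read_motif_profile()].
#'
#' @param match Score per consensus residue.
#' @param threshold_frac Hit threshold as a fraction of the maximum score.
#' @return Named list of two [motif_profile()] objects (`Brk`, `HTH`).
#' @export
toy_dbd_profiles <- function(match = 2, threshold_frac = 0.75) {
  peptides <- c(Brk = "KRPRGRPKKW", HTH = "LTQEQLAELLGVSR")
  purrr::imap(as.list(peptides), function(pep, nm) {
    aa <- seq_chars(pep)
    mat <- matrix(0, nrow = length(aa), ncol = 20,
                  dimnames = list(NULL, seq_chars("ACDEFGHIKLMNPQRSTVWY")))
    mat[cbind(seq_along(aa), match(aa, colnames(mat)))] <- match
    motif_profile(nm, mat, threshold = threshold_frac * match * length(aa))
  })
}

#' Classify a called copy as intact, transposase-coding or fragment
#'
#' A copy is `intact` when both TIRs and a TSD were found, its longest ORF
#' reaches `min_aa` residues, both DNA-binding motifs hit, and the DD35D
#' catalytic triad is present; `coding_only` when the protein rules all
#' pass but the TIR/TSD structure is incomplete; `fragment` otherwise. The
#' `reasons` string lists every rule outcome.
#'
#' @param copy One-row copy tibble from [call_boundaries()] (or any tibble
#'   with `element_seq`, `tir_len`, `tsd_len`).
#' @param profiles List of [motif_profile()] objects (both must hit);
#'   default [toy_dbd_profiles()].
#' @param min_aa Minimum transposase length, residues.
#' @inheritParams find_triad
#' @return One-row tibble: `category`, `orf_aa`, `triad`, `motif_hits`,
#'   `reasons`.
#' @export
classify_copy <- function(copy, profiles = toy_dbd_profiles(), min_aa = 300L,
                          spacer23 = 35L, d1_d2_range = c(50L, 250L),
                          allow_e = FALSE) {
  has_tir <- !is.na(copy$tir_len)
  has_tsd <- !is.na(copy$tsd_len)
  orf <- find_longest_orf(copy$element_seq, min_aa = min_aa)
  has_orf <- !is.null(orf)
  triad <- if (has_orf) find_triad(orf$protein_seq, spacer23 = spacer23,
                                   d1_d2_range = d1_d2_range, allow_e = allow_e) else NULL
  has_triad <- !is.null(triad)
  motifs <- if (has_orf) purrr::map(profiles, ~ scan_motif(orf$protein_seq, .x)) else list()
  motif_ok <- length(motifs) > 0 && all(purrr::map_lgl(motifs, "hit"))
  coding <- has_orf && has_triad && motif_ok
  structural <- has_tir && has_tsd
  category <- if (coding && structural) "intact" else if (coding) "coding_only" else "fragment"
  reasons <- c(
    if (has_tir) "TIR pair found" else "TIR missing",
    if (has_tsd) "TSD found" else "TSD missing",
    if (has_orf) sprintf("ORF %d aa (>= %d)", orf$length_aa, min_aa) else sprintf("no ORF >= %d aa", min_aa),
    if (has_triad) sprintf("DD%dD triad at %d/%d/%d", spacer23, triad$pos_d1, triad$pos_d2, triad$pos_d3) else "catalytic triad missing",
    if (length(motifs)) paste0("motif ", purrr::map_chr(motifs, "name"), ": ",
                               ifelse(purrr::map_lgl(motifs, "hit"), "hit", "miss"))
  )
  tibble(category = category,
         orf_aa = if (has_orf) orf$length_aa else NA_integer_,
         triad = has_triad,
         motif_hits = sum(purrr::map_lgl(motifs, "hit")),
         reasons = paste(reasons, collapse = "; "))
}

#' Classify every copy in a called-copy table
#'
#' @param copies Copy tibble from [call_boundaries()].
#' @inheritParams classify_copy
#' @return The input tibble with classification columns appended.
#' @export
classify_copies <- function(copies, profiles = toy_dbd_profiles(), min_aa = 300L,
                            spacer23 = 35L, d1_d2_range = c(50L, 250L),
                            allow_e = FALSE) {
  cls <- purrr::map(seq_len(nrow(copies)), function(i) {
    classify_copy(copies[i, ], profiles = profiles, min_aa = min_aa,
                  spacer23 = spacer23, d1_d2_range = d1_d2_range,
                  allow_e = allow_e)
  })
  dplyr::bind_cols(copies, dplyr::bind_rows(cls))
}

#' Coverage and identity of copies against a family consensus
#'
#' Each copy is globally aligned to the consensus; coverage is the aligned
#' (non-gap in both) bp divided by the consensus length, identity the
#' match fraction over aligned columns.
#'
#' @param copy_seqs Character vector of copy sequences.
#' @param consensus Consensus (or representative) sequence.
#' @return Tibble with `coverage` and `identity` per copy (both 0-1).
#' @export
copy_family_stats <- function(copy_seqs, consensus) {
  purrr::map_dfr(copy_seqs, function(s) {
    al <- align_global(s, consensus)
    a <- seq_chars(al$seq_a_aligned); b <- seq_chars(al$seq_b_aligned)
    both <- a != "-" & b != "-"
    tibble(coverage = sum(both) / nchar(consensus),
           identity = if (any(both)) mean(a[both] == b[both]) else 0)
  })
}

#' Count family copies at coverage/identity thresholds
#'
#' Counts copies strictly exceeding both the coverage and the identity
#' threshold (the conventional >40% length coverage and >80% identity rule
#' for copy-number estimation).
#'
#' @param copy_stats Tibble with `coverage` and `identity` columns (0-1
#'   scale), e.g. from [copy_family_stats()].
#' @param min_coverage,min_identity Strict lower bounds (0-1).
#' @return Integer copy count.
#' @export
count_copies <- function(copy_stats, min_coverage = 0.40, min_identity = 0.80) {
  if (is.null(copy_stats) || nrow(copy_stats) == 0) return(0L)
  sum(copy_stats$coverage > min_coverage & copy_stats$identity > min_identity)
}
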