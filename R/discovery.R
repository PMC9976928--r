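# Element discovery: merge homology hits into candidate loci, extract
# flanks, and refine element boundaries by joint TIR/TSD scoring.
#
# All genomic coordinates are 0-based half-open. Minus-strand loci are
# normalised to transposase-sense orientation at flank extraction, so every
# downstream step sees the element 5'->3' with the left TIR first.

#' Merge homology hits into candidate loci
#'
#' Filters hits by identity and e-value, then merges same-chromosome,
#' same-strand hits whose gaps are at most `max_gap` bp into single
#' candidate intervals. Records with `start >= end` are rejected
#' individually (with a message), not fatally.
#'
#' @param hits Hit tibble as returned by [read_blast_hits()]: columns
#'   `chrom`, `start`, `end`, `strand`, and optionally `percent_identity`,
#'   `evalue`.
#' @param max_gap Maximum gap (bp) between hits to merge; 0 merges only
#'   overlapping or abutting hits.
#' @param min_identity Minimum percent identity (0-100) for a hit to be
#'   kept.
#' @param max_evalue Maximum e-value for a hit to be kept. The default is
#'   the conventional cut for transposase TblastN searches.
#' @return Tibble of candidate loci: `chrom`, `core_start`, `core_end`,
#'   `strand`, `n_hits`, sorted by (chrom, core_start); intervals are
#'   disjoint per strand.
#' @export
merge_hits <- function(hits, max_gap = 0L, min_identity = 0, max_evalue = 1e-100) {
  stopifnot(max_gap >= 0)
  hits <- as_tibble(hits)
  bad <- hits$start >= hits$end
  if (any(bad)) {
    inform(sprintf("rejected %d hit(s) with start >= end", sum(bad)))
    hits <- hits[!bad, , drop = FALSE]
  }
  if ("percent_identity" %in% names(hits)) hits <- hits[hits$percent_identity >= min_identity, ]
  if ("evalue" %in% names(hits)) hits <- hits[hits$evalue <= max_evalue, ]
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), core_start = integer(),
                  core_end = integer(), strand = character(), n_hits = integer()))
  }
  hits |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$start, df$end), ]
      grp <- cumsum(c(1L, as.integer(df$start[-1] > cummax(df$end[-nrow(df)]) + max_gap)))
      out <- df |>
        dplyr::mutate(.grp = grp) |>
        dplyr::group_by(.data$.grp) |>
        dplyr::summarise(core_start = min(.data$start), core_end = max(.data$end),
                         n_hits = dplyr::n(), .groups = "drop")
      out[, c("core_start", "core_end", "n_hits")]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$core_start) |>
    dplyr::select("chrom", "core_start", "core_end", "strand", "n_hits")
}

#' Extract flanking sequence around candidate loci
#'
#' Adds the core sequence and up to `flank_size` bp of genomic flank on
#' each side to every locus. Flanks are truncated (never padded) at contig
#' edges. Minus-strand loci are reverse-complemented so the element is in
#' transposase-sense orientation, with flanks swapped accordingly.
#'
#' @param loci Locus tibble from [merge_hits()] (or any tibble with
#'   `chrom`, `core_start`, `core_end`, `strand`).
#' @param genome Named character vector / `DNAStringSet` of contigs.
#' @param flank_size Flank length in bp (default 2000).
#' @return The locus tibble with added `left_flank`, `right_flank`,
#'   `core_seq` columns (sense orientation).
#' @export
extract_flanks <- function(loci, genome, flank_size = 2000L) {
  stopifnot(flank_size > 0)
  genome <- as_genome(genome)
  missing <- setdiff(unique(loci$chrom), names(genome))
  if (length(missing)) {
    abort(paste0("contig(s) absent from genome: ", paste(missing, collapse = ", ")))
  }
  n <- nrow(loci)
  left <- character(n); right <- character(n); core <- character(n)
  for (i in seq_len(n)) {
    contig <- genome[[loci$chrom[i]]]
    L <- nchar(contig)
    s <- loci$core_start[i]; e <- loci$core_end[i]
    if (s < 0 || e > L || s >= e) abort(sprintf("locus %d has invalid coordinates", i))
    g_left <- substr(contig, max(0L, s - flank_size) + 1L, s)
    g_core <- substr(contig, s + 1L, e)
    g_right <- substr(contig, e + 1L, min(L, e + flank_size))
    if (identical(loci$strand[i], "-")) {
      left[i] <- revcomp(g_right)
      core[i] <- revcomp(g_core)
      right[i] <- revcomp(g_left)
    } else {
      left[i] <- g_left; core[i] <- g_core; right[i] <- g_right
    }
  }
  dplyr::mutate(loci, left_flank = left, right_flank = right, core_seq = core)
}

# Cumulative mismatch vector between the forward word starting at 1-based
# position p and the reverse complement of the word ending at q, over
# lengths 1..maxlen. N never matches.
tir_mismatch_cum <- function(chars, p, q, maxlen) {
  lf <- chars[p:(p + maxlen - 1L)]
  rt <- chars[q:(q - maxlen + 1L)]
  rc <- unname(complement_base[rt])
  rc[is.na(rc)] <- "N"
  cumsum(lf != rc | lf == "N" | rc == "N")
}

#' Detect a terminal inverted repeat in an element sequence
#'
#' Searches for the highest-scoring inverted repeat anchored within
#' `max_terminal_offset` bp of both termini (substitution-only model;
#' score = matches - 2 x mismatches). Ties prefer longer repeats, then
#' fewer mismatches, then smaller terminal offsets.
#'
#' @param element_seq Element sequence (sense orientation).
#' @param min_len,max_len TIR length bounds in bp.
#' @param terminal_window Terminal region searched, bp.
#' @param max_mismatch_frac Maximum mismatch fraction within the repeat.
#' @param max_terminal_offset Maximum distance of a repeat copy from its
#'   terminus, bp.
#' @return One-row tibble (`left_seq`, `right_seq`, `length`, `mismatches`,
#'   `left_offset`, `right_offset`, `score`) or `NULL` when no repeat of at
#'   least `min_len` bp passes the mismatch cap.
#' @export
detect_tir <- function(element_seq, min_len = 10L, max_len = 40L,
                       terminal_window = 60L, max_mismatch_frac = 0.2,
                       max_terminal_offset = 5L) {
  element_seq <- normalize_seq(element_seq)
  L <- nchar(element_seq)
  if (L < 2L * terminal_window) abort("element too short")
  chars <- seq_chars(element_seq)
  best <- NULL
  for (a in 0:max_terminal_offset) {
    for (b in 0:max_terminal_offset) {
      maxlen <- min(max_len, terminal_window - a, terminal_window - b,
                    (L - a - b) %/% 2L)
      if (maxlen < min_len) next
      cum <- tir_mismatch_cum(chars, a + 1L, L - b, maxlen)
      lens <- min_len:maxlen
      mm <- cum[lens]
      ok <- mm <= max_mismatch_frac * lens
      if (!any(ok)) next
      score <- lens - 3L * mm
      for (i in which(ok)) {
        cand <- c(score[i], lens[i], -mm[i], -(a + b), -a)
        if (is.null(best) || tir_better(cand, best$key)) {
          best <- list(key = cand, a = a, b = b, len = lens[i], mm = mm[i])
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  tibble(
    left_seq = substr(element_seq, best$a + 1L, best$a + best$len),
    right_seq = substr(element_seq, L - best$b - best$len + 1L, L - best$b),
    length = best$len,
    mismatches = best$mm,
    left_offset = best$a,
    right_offset = best$b,
    score = best$len - 3L * best$mm
  )
}

# Lexicographic comparison of candidate keys (all maximised).
tir_better <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] > 0
}

#' Detect a target-site duplication between element flanks
#'
#' Returns the longest exact word of length `k_min..k_max` shared between
#' the left-flank suffix and the right-flank prefix. Words containing N are
#' never matched.
#'
#' @param left_flank,right_flank Flank sequences (sense orientation).
#' @param k_min,k_max TSD length bounds, bp.
#' @return One-row tibble (`sequence`, `length`, `is_ta`) or `NULL`.
#' @export
detect_tsd <- function(left_flank, right_flank, k_min = 2L, k_max = 10L) {
  if (!nzchar(left_flank) || !nzchar(right_flank)) {
    inform("empty flank: no TSD search possible")
    return(NULL)
  }
  left_flank <- normalize_seq(left_flank); right_flank <- normalize_seq(right_flank)
  kmax <- min(k_max, nchar(left_flank), nchar(right_flank))
  for (k in rev(seq(k_min, kmax))) {
    word <- substr(left_flank, nchar(left_flank) - k + 1L, nchar(left_flank))
    if (grepl("N", word, fixed = TRUE)) next
    if (identical(word, substr(right_flank, 1L, k))) {
      return(tibble(sequence = word, length = k, is_ta = identical(word, "TA")))
    }
  }
  NULL
}

# Longest exact TSD length for element boundaries (s, e) inside the padded
# sequence `chars` (1-based: element occupies s..e). Returns c(len, is_ta);
# len 0 when none.
tsd_at <- function(full, n, s, e, k_min, k_max) {
  kmax <- min(k_max, s - 1L, n - e)
  if (kmax >= k_min) {
    for (k in rev(seq(k_min, kmax))) {
      word <- substr(full, s - k, s - 1L)
      if (grepl("N", word, fixed = TRUE)) next
      if (identical(word, substr(full, e + 1L, e + k))) {
        return(c(k, as.integer(identical(word, "TA"))))
      }
    }
  }
  c(0L, 0L)
}

# Boundary refinement for one locus. Scans (start, end) pairs within
# +/- boundary_slop of the homology core; the element termini are taken to
# be the TIR termini (offset 0) because a genuine TSD directly abuts the
# TIR of a fresh insertion. Mismatch vectors are shared across lengths via
# cumulative sums.
call_boundaries_one <- function(left_flank, core_seq, right_flank,
                                boundary_slop = 30L,
                                min_len = 10L, max_len = 40L,
                                terminal_window = 60L, max_mismatch_frac = 0.2,
                                max_terminal_offset = 5L,
                                k_min = 2L, k_max = 10L, ta_bonus = 10) {
  full <- paste0(left_flank, core_seq, right_flank)
  n <- nchar(full)
  chars <- seq_chars(full)
  nL <- nchar(left_flank); nC <- nchar(core_seq)
  # candidate element starts/ends, 1-based inclusive positions in `full`
  s_min <- max(1L, nL + 1L - boundary_slop); s_max <- min(n, nL + 1L + boundary_slop)
  e_min <- max(1L, nL + nC - boundary_slop); e_max <- min(n, nL + nC + boundary_slop)

  # memoised TSD score per (s, e): ta_bonus * is_ta + tsd length
  tsd_cache <- new.env(parent = emptyenv())
  tsd_score <- function(s, e) {
    key <- paste0(s, "_", e)
    v <- tsd_cache[[key]]
    if (is.null(v)) {
      r <- tsd_at(full, n, s, e, k_min, k_max)
      v <- c(r[1] + ta_bonus * r[2], r[1], r[2])
      tsd_cache[[key]] <- v
    }
    v
  }

  best <- NULL # list(key, p, q, len, mm, s, e, tsd_len, tsd_is_ta)
  for (p in s_min:s_max) {
    q_lo <- max(e_min, p)
    if (q_lo > e_max) next
    for (q in q_lo:e_max) {
      maxlen <- min(max_len, (q - p + 1L) %/% 2L,
                    terminal_window, n - p + 1L, q)
      if (maxlen < min_len) next
      cum <- tir_mismatch_cum(chars, p, q, maxlen)
      lens <- min_len:maxlen
      mm <- cum[lens]
      ok <- mm <= max_mismatch_frac * lens
      if (!any(ok)) next
      # best TIR at this anchor pair: score desc, longer, fewer mismatches
      sc <- ifelse(ok, lens - 3L * mm, -Inf)
      i <- which.max(sc + lens * 1e-3 - mm * 1e-6)
      tir_score <- lens[i] - 3L * mm[i]
      # element termini are the TIR termini: a genuine TSD abuts the TIR,
      # so allowing slack here would only invite spurious flank matches
      s <- p; e <- q
      if (s < s_min || s > s_max || e < e_min || e > e_max) next
      if (e - s + 1L < 2L * terminal_window) next
      ts <- tsd_score(s, e)
      key <- c(tir_score + ts[1], lens[i], -mm[i], -s)
      if (is.null(best) || tir_better(key, best$key)) {
        best <- list(key = key, p = p, q = q, len = lens[i], mm = mm[i],
                     s = s, e = e, tsd_len = ts[2], tsd_is_ta = ts[3] == 1)
      }
    }
  }

  if (is.null(best)) {
    s <- nL + 1L; e <- nL + nC
    ts <- tsd_at(full, n, s, e, k_min, k_max)
    return(list(rel_start = s - 1L - nL, rel_end = e - nL,
                element_seq = core_seq,
                tir_len = NA_integer_, tir_mismatches = NA_integer_,
                tir_left = NA_character_, tir_right = NA_character_,
                tir_left_offset = NA_integer_, tir_right_offset = NA_integer_,
                tsd_seq = if (ts[1] > 0) substr(full, s - ts[1], s - 1L) else NA_character_,
                tsd_len = if (ts[1] > 0) ts[1] else NA_integer_,
                tsd_is_ta = ts[1] > 0 && ts[2] == 1,
                boundary_score = 0))
  }
  list(
    rel_start = best$s - 1L - nL,      # 0-based, relative to core_start in sense space
    rel_end = best$e - nL,
    element_seq = substr(full, best$s, best$e),
    tir_len = best$len,
    tir_mismatches = best$mm,
    tir_left = substr(full, best$p, best$p + best$len - 1L),
    tir_right = substr(full, best$q - best$len + 1L, best$q),
    tir_left_offset = best$p - best$s,
    tir_right_offset = best$e - best$q,
    tsd_seq = if (best$tsd_len > 0) substr(full, best$s - best$tsd_len, best$s - 1L) else NA_character_,
    tsd_len = if (best$tsd_len > 0) best$tsd_len else NA_integer_,
    tsd_is_ta = isTRUE(best$tsd_is_ta),
    boundary_score = unname(best$key[1])
  )
}

#' Call element boundaries for candidate loci
#'
#' For every locus, scans start/end pairs within `boundary_slop` bp of the
#' homology core, scoring each implied element by its best terminal
#' inverted repeat plus a TA target-site-duplication bonus
#' (`boundary_score = tir_score + ta_bonus x [TA TSD] + tsd_length`), and
#' keeps the maximising boundaries. Loci with no detectable TIR keep their
#' core boundaries with score 0. This automated refinement stands in for
#' the manual boundary curation typical of transposon surveys and is
#' flagged as heuristic in reports.
#'
#' @param loci Locus tibble with flanks, from [extract_flanks()].
#' @param boundary_slop Search slop around the homology core, bp.
#' @param ta_bonus Score bonus for a TA TSD.
#' @inheritParams detect_tir
#' @inheritParams detect_tsd
#' @param family_polish After the per-copy scan, re-anchor every copy's
#'   termini against the family's consensus TIR (majority sequence over
#'   high-confidence calls). This second pass resolves the boundary
#'   ambiguity created by the palindromic TA TSD, which can otherwise let
#'   a chance flank match pull a terminus a few bp off; it mirrors the
#'   usual practice of determining boundaries by aligning copies.
#' @return Tibble of called copies: `copy_id`, `chrom`, `strand`,
#'   `element_start`, `element_end` (genomic, 0-based half-open),
#'   `element_seq` (sense), TIR/TSD columns and `boundary_score`.
#' @export
call_boundaries <- function(loci, boundary_slop = 30L,
                            min_len = 10L, max_len = 40L,
                            terminal_window = 60L, max_mismatch_frac = 0.2,
                            max_terminal_offset = 5L,
                            k_min = 2L, k_max = 10L, ta_bonus = 10,
                            family_polish = TRUE) {
  stopifnot(boundary_slop >= 0, all(c("left_flank", "right_flank", "core_seq") %in% names(loci)))
  calls <- purrr::pmap(
    list(loci$left_flank, loci$core_seq, loci$right_flank),
    function(lf, cs, rf) {
      r <- call_boundaries_one(lf, cs, rf, boundary_slop, min_len, max_len,
                               terminal_window, max_mismatch_frac,
                               max_terminal_offset, k_min, k_max, ta_bonus)
      r$full <- paste0(lf, cs, rf)
      r$nL <- nchar(lf)
      r
    })
  if (isTRUE(family_polish)) {
    calls <- polish_family_boundaries(calls, boundary_slop, k_min, k_max,
                                      ta_bonus, max_mismatch_frac)
  }
  rows <- purrr::map(seq_along(calls), function(i) {
    r <- calls[[i]]
    # map sense-relative boundaries back to genomic coordinates
    cs0 <- loci$core_start[i]; ce0 <- loci$core_end[i]
    if (identical(loci$strand[i], "-")) {
      g_start <- ce0 - r$rel_end
      g_end <- ce0 - r$rel_start
    } else {
      g_start <- cs0 + r$rel_start
      g_end <- cs0 + r$rel_end
    }
    tibble(
      copy_id = sprintf("%s_%d_%d_%s", loci$chrom[i], g_start, g_end, loci$strand[i]),
      chrom = loci$chrom[i], strand = loci$strand[i],
      element_start = g_start, element_end = g_end,
      element_seq = r$element_seq,
      tir_len = r$tir_len, tir_mismatches = r$tir_mismatches,
      tir_left = r$tir_left, tir_right = r$tir_right,
      tir_left_offset = r$tir_left_offset, tir_right_offset = r$tir_right_offset,
      tsd_seq = r$tsd_seq, tsd_len = r$tsd_len, tsd_is_ta = r$tsd_is_ta,
      boundary_score = r$boundary_score
    )
  })
  dplyr::bind_rows(rows)
}

# Majority-rule consensus TIR from high-confidence first-pass calls, then
# per-copy re-anchoring of each terminus at the offset (within
# boundary_slop of the first-pass call) minimising mismatches to the
# consensus TIR. A terminus is only moved when the consensus matches there
# at most `max_mismatch_frac` mismatches; otherwise (e.g. a truncated
# end) the first-pass call stands.
polish_family_boundaries <- function(calls, boundary_slop, k_min, k_max,
                                     ta_bonus, max_mismatch_frac) {
  conf <- purrr::keep(calls, function(r) {
    !is.na(r$tir_len) && isTRUE(r$tsd_is_ta) && r$tir_mismatches <= 1L
  })
  if (length(conf) < 3L) return(calls)
  lens <- purrr::map_int(conf, "tir_len")
  L <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  conf <- purrr::keep(conf, ~ .x$tir_len == L)
  if (length(conf) < 3L) return(calls)
  tir_seqs <- c(purrr::map_chr(conf, "tir_left"),
                revcomp(purrr::map_chr(conf, "tir_right")))
  mat <- do.call(rbind, strsplit(tir_seqs, ""))
  cons <- apply(mat, 2, function(col) {
    tb <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tb)[which.max(tb)]
  })
  cons_rc <- rev(unname(complement_base[cons]))
  max_mm <- max(2L, ceiling(max_mismatch_frac * L))

  purrr::map(calls, function(r) {
    ch <- seq_chars(r$full)
    n <- length(ch)
    scan_end <- function(anchor, rc) {
      # anchor: first-pass terminus (rel to element sense space, 1-based in full)
      offs <- (anchor - boundary_slop):(anchor + boundary_slop)
      best <- NULL
      for (o in offs) {
        st <- if (rc) o - L + 1L else o
        en <- st + L - 1L
        if (st < 1L || en > n) next
        mm <- sum(ch[st:en] != (if (rc) cons_rc else cons))
        if (mm > max_mm) next
        key <- c(-mm, -abs(o - anchor))
        if (is.null(best) || tir_better(key, best$key)) best <- list(key = key, o = o, mm = mm)
      }
      best
    }
    s1 <- r$nL + 1L + r$rel_start            # 1-based element start in full
    e1 <- r$nL + r$rel_end                   # 1-based element end in full
    bs <- scan_end(s1, rc = FALSE)
    be <- scan_end(e1, rc = TRUE)
    s <- if (!is.null(bs)) bs$o else s1
    e <- if (!is.null(be)) be$o else e1
    if (e - s + 1L < 2L * L || (s == s1 && e == e1)) {
      if (is.null(bs) && is.null(be)) return(r)
      if (e - s + 1L < 2L * L) return(r)
    }
    left <- paste(ch[s:(s + L - 1L)], collapse = "")
    right <- paste(ch[(e - L + 1L):e], collapse = "")
    mm_pair <- hamming(left, revcomp(right))
    ts <- tsd_at(r$full, n, s, e, k_min, k_max)
    r$rel_start <- s - 1L - r$nL
    r$rel_end <- e - r$nL
    r$element_seq <- substr(r$full, s, e)
    r$tir_len <- L
    r$tir_mismatches <- mm_pair
    r$tir_left <- left
    r$tir_right <- right
    r$tir_left_offset <- 0L
    r$tir_right_offset <- 0L
    r$tsd_len <- if (ts[1] > 0) ts[1] else NA_integer_
    r$tsd_seq <- if (ts[1] > 0) substr(r$full, s - ts[1], s - 1L) else NA_character_
    r$tsd_is_ta <- ts[1] > 0 && ts[2] == 1
    r$boundary_score <- (L - 3 * mm_pair) + ta_bonus * (ts[1] > 0 && ts[2] == 1) +
      if (ts[1] > 0) ts[1] else 0
    r
  })
}

#' Run the discovery stage end-to-end
#'
#' Merges hits, extracts flanks and calls boundaries with one call.
#'
#' @inheritParams merge_hits
#' @inheritParams extract_flanks
#' @inheritParams call_boundaries
#' @return The called-copy tibble of [call_boundaries()].
#' @export
discover_elements <- function(hits, genome, max_gap = 200L, min_identity = 0,
                              max_evalue = 1e-100, flank_size = 2000L,
                              boundary_slop = 30L, ta_bonus = 10) {
  loci <- merge_hits(hits, max_gap = max_gap, min_identity = min_identity,
                     max_evalue = max_evalue)
  loci <- extract_flanks(loci, genome, flank_size = flank_size)
  call_boundaries(loci, boundary_slop = boundary_slop, ta_bonus = ta_bonus)
}

#' Write called copies as BED6 plus annotation columns
#'
#' @param copies Copy tibble from [call_boundaries()].
#' @param path Output path.
#' @export
write_copies_bed <- function(copies, path) {
  df <- data.frame(copies$chrom, copies$element_start, copies$element_end,
                   copies$copy_id, round(copies$boundary_score, 3), copies$strand,
                   copies$tir_len, copies$tir_mismatches, copies$tsd_seq,
                   copies$boundary_score)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
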