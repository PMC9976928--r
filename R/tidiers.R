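# broom-style tidiers for the package's classed results.

#' Tidy a divergence landscape
#'
#' @param x A `divergence_landscape`.
#' @param ... Unused.
#' @return Tibble with `bin_low` (K%) and `coverage_bp`.
#' @export
tidy.divergence_landscape <- function(x, ...) {
  tibble(bin_low = x$bin_low, coverage_bp = x$coverage_bp)
}

#' One-row summary of a divergence landscape
#'
#' @param x A `divergence_landscape`.
#' @param ... Unused.
#' @return Tibble with total coverage, number of occupied bins, and the
#'   modal bin's lower edge (K%).
#' @export
glance.divergence_landscape <- function(x, ...) {
  tibble(total_coverage_bp = sum(x$coverage_bp),
         n_bins = nrow(x),
         mode_bin_low = x$bin_low[which.max(x$coverage_bp)],
         bin_width = attr(x, "bin_width"))
}

#' Tidy a consensus element
#'
#' @param x A `consensus_element`.
#' @param ... Unused.
#' @return Tibble with one row per consensus column: `position` (0-based),
#'   `base` and per-base support counts (consensus mode only).
#' @export
tidy.consensus_element <- function(x, ...) {
  base <- seq_chars(x$sequence)
  out <- tibble(position = seq_along(base) - 1L, base = base)
  if (!is.null(x$column_support)) {
    out <- dplyr::bind_cols(out, as_tibble(t(x$column_support)))
  }
  out
}

#' One-row summary of a consensus element
#'
#' @param x A `consensus_element`.
#' @param ... Unused.
#' @return Tibble with mode, length and copies used.
#' @export
glance.consensus_element <- function(x, ...) {
  tibble(mode = x$mode, length_bp = nchar(x$sequence),
         n_copies_used = x$n_copies_used, n_ties = x$n_ties)
}

#' Tidy a target-site matrix
#'
#' @param x A `target_site_matrix`.
#' @param ... Unused.
#' @return Long tibble with `offset` (bp from the TA start), `base`,
#'   `count` and `frequency`.
#' @export
tidy.target_site_matrix <- function(x, ...) {
  counts <- x$counts
  tibble(
    offset = rep(as.integer(colnames(counts)), each = nrow(counts)),
    base = rep(rownames(counts), ncol(counts)),
    count = as.integer(counts)
  ) |>
    dplyr::group_by(.data$offset) |>
    dplyr::mutate(frequency = .data$count / pmax(sum(.data$count), 1L)) |>
    dplyr::ungroup()
}

#' One-row summary of a target-site matrix
#'
#' @param x A `target_site_matrix`.
#' @param ... Unused.
#' @return Tibble with consensus, central 8-mer, palindrome score and site
#'   counts.
#' @export
glance.target_site_matrix <- function(x, ...) {
  tibble(consensus = x$consensus, central_8mer = x$central_8mer,
         palindrome_score = x$palindrome_score, n_sites = x$n_sites,
         n_partial = x$n_partial, n_non_ta = x$n_non_ta)
}

#' One-row summary of an enrichment table
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return Tibble with the number of states, the most enriched state and
#'   its fold, and the count of significant states (p <= 0.05).
#' @export
glance.enrichment_result <- function(x, ...) {
  top <- which.max(x$fold)
  tibble(n_labels = nrow(x),
         top_label = x$state[top] %||% NA_character_,
         top_fold = x$fold[top],
         n_significant = sum(x$p_value <= 0.05, na.rm = TRUE))
}
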