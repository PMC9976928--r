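# ggplot2 visualisations for each result type.

#' Plot a divergence landscape
#'
#' Coverage (bp) per Kimura-divergence bin, the classic repeat-landscape
#' bar chart.
#'
#' @param object A `divergence_landscape`.
#' @param fill Bar fill colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_landscape <- function(object, fill = "#4477AA", ...) {
  bw <- attr(object, "bin_width") %||% 1
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$bin_low + bw / 2, y = .data$coverage_bp)) +
    ggplot2::geom_col(width = bw * 0.95, fill = fill) +
    ggplot2::labs(x = "Kimura divergence (%)", y = "Coverage (bp)",
                  title = attr(object, "family_id")) +
    ggplot2::theme_classic()
}

#' @rdname autoplot.divergence_landscape
#' @export
plot_landscape <- function(object, ...) autoplot.divergence_landscape(object, ...)

#' Plot a feature-category distribution
#'
#' Per-sample category fractions with significance stars from the Fisher
#' tests against the background.
#'
#' @param object A `feature_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_distribution <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction,
                                   fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$stars == "ns", "", .data$stars)),
      position = ggplot2::position_dodge(width = 0.9), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "Fraction of insertions") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot chromatin-state enrichment
#'
#' Fold change per state relative to the random expectation (dashed line
#' at 1), starred by Fisher p-value.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$fold)) +
    ggplot2::geom_col(fill = "#CC6677") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$stars == "ns", "", .data$stars)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "Fold change vs random") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a target-site base-frequency matrix
#'
#' Per-position base frequencies around the TA target dinucleotide.
#'
#' @param object A `target_site_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.target_site_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$offset, y = .data$frequency,
                               fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Offset from TA start (bp)", y = "Base frequency") +
    ggplot2::theme_classic()
}

#' Plot a TSS-centred insertion profile
#'
#' @param profile Tibble from [tss_profile()].
#' @param bin_bp Bin width used (for bar widths).
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile, bin_bp = 100L) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin_low + bin_bp / 2,
                                        y = .data$fraction)) +
    ggplot2::geom_col(width = bin_bp * 0.95, fill = "#228833") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Distance to TSS (bp)", y = "Fraction of insertions") +
    ggplot2::theme_classic()
}
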