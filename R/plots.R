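# ggplot2 visualizations for the main result types.

#' Plot the selectivity index distribution
#'
#' Histogram of S10 values with the inclusion threshold marked.
#'
#' @param s10_result tibble from [compute_s10()].
#' @param s10_max threshold line to draw (default 0.025).
#' @return a ggplot object.
#' @export
plot_s10_distribution <- function(s10_result, s10_max = 0.025) {
  ggplot2::ggplot(s10_result, ggplot2::aes(x = .data$s10)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::geom_vline(xintercept = s10_max, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = expression(S[10]), y = "compounds",
                  title = "Selectivity index distribution") +
    ggplot2::theme_minimal()
}

#' Plot chemotype bin occupancy
#'
#' Bar chart of member counts per occupied bin, largest first.
#'
#' @param assignments tibble from [assign_chemotypes()].
#' @return a ggplot object.
#' @export
plot_bin_occupancy <- function(assignments) {
  counts <- bin_histogram(assignments)$counts[[1]]
  counts$bin <- factor(counts$bin, levels = counts$bin)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "inhibitors",
                  title = "Chemotype bin occupancy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of GR values across compounds and cell lines
#'
#' @param gr tibble with `compound_id`, `cell_line`, `gr` (e.g. from
#'   [compute_gr()]).
#' @return a ggplot object.
#' @export
plot_gr_heatmap <- function(gr) {
  ggplot2::ggplot(gr, ggplot2::aes(x = .data$compound_id,
                                   y = .data$cell_line,
                                   fill = .data$gr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey60",
                                  high = "gold", midpoint = 0.5,
                                  limits = c(-0.5, 1.3),
                                  oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "GR",
                  title = "Growth-rate inhibition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot normalized flux series with the hit threshold
#'
#' @param pct tibble from [autophagy_normalize()].
#' @param threshold hit threshold in percent (default 20).
#' @return a ggplot object.
#' @export
plot_flux_series <- function(pct, threshold = 20) {
  ggplot2::ggplot(pct, ggplot2::aes(x = .data$time_h, y = .data$pct_flux,
                                    group = .data$compound_id,
                                    colour = .data$compound_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time (h)", y = "% of control span",
                  title = "Autophagic flux, normalized") +
    ggplot2::theme_minimal()
}

#' Plot family coverage
#'
#' @param coverage tibble from [family_coverage()]; the totals row is
#'   dropped.
#' @return a ggplot object.
#' @export
plot_family_coverage <- function(coverage) {
  df <- coverage[coverage$family != "Total" & !is.na(coverage$pct), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "% of assayed kinases covered",
                  title = "Kinome family coverage") +
    ggplot2::theme_minimal()
}
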