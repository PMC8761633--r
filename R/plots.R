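#' Forest-style plot of a correlation report
#'
#' Spearman coefficients per (feature, response) with significance marked;
#' the companion to a correlation table.
#'
#' @param report Output of [correlation_report()].
#' @param alpha Significance threshold used for coloring.
#' @return A ggplot object.
#' @export
plot_correlation_report <- function(report, alpha = 0.05) {
  d <- report[!is.na(report$rho), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho, y = .data$feature,
                                  color = .data$p_value < alpha)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~response) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      name = paste0("p < ", alpha)) +
    ggplot2::labs(x = "Spearman rho", y = NULL) +
    ggplot2::theme_bw()
}

#' Time-course cleavage curves
#'
#' Mean raw cleavage ratio against time per substrate, from
#' [timecourse_summary()].
#'
#' @param summary Output of [timecourse_summary()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$timepoint, y = .data$mean_ratio,
                               group = .data$substrate_id,
                               color = .data$substrate_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "raw cleavage ratio",
                  color = "substrate") +
    ggplot2::theme_bw()
}

#' Motif-count strata bar plot
#'
#' Mean response with SD bars per number of carried UG/UGU/CNNC motifs.
#' Expression responses are usually drawn on a log scale
#' (`ggplot2::scale_y_log10()`); the underlying rank statistics are
#' transform-invariant.
#'
#' @param strata Output of [stratify_by_motif_count()].
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_motif_strata <- function(strata, ylab = "relative efficiency") {
  d <- strata[strata$n > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$motif_count),
                                  y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = "number of UG/UGU/CNNC motifs", y = ylab) +
    ggplot2::theme_bw()
}
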