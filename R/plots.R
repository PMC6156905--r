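#' Plot empirical power against heritability
#'
#' One line per estimator, faceted by outcome setting and threshold; the
#' pooled Type I error rows are dropped (see [plot_type1()]).
#'
#' @param object A `famgxm_power` from [summarize_power()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.famgxm_power <- function(object, ...) {
  pw <- dplyr::filter(object, .data$metric == "power") |>
    dplyr::mutate(threshold_lab = sprintf("p < %.3g", .data$threshold))
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$h2, y = .data$rate,
                                   colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$threshold_lab),
                        ggplot2::vars(.data$setting)) +
    ggplot2::labs(x = expression(h[g]^2), y = "empirical power",
                  colour = "estimator") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Plot pooled Type I error by estimator
#'
#' Bars per estimator and setting at the nominal threshold, with a dashed
#' reference line at the nominal level.
#'
#' @param power A `famgxm_power`.
#' @param threshold Which threshold's rows to show (default 0.05).
#' @return A ggplot.
#' @export
plot_type1 <- function(power, threshold = 0.05) {
  t1 <- dplyr::filter(power, .data$metric == "type1",
                      abs(.data$threshold - !!threshold) < 1e-12)
  ggplot2::ggplot(t1, ggplot2::aes(x = .data$estimator, y = .data$rate,
                                   fill = .data$setting)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "pooled Type I error", fill = "setting") +
    ggplot2::theme_bw()
}
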