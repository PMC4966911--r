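# ggplot2 summaries of sweep and verification results.

#' Heatmap of a conductivity sweep
#'
#' Median RE (or CC) of every (K_ref, K_test) pair.
#'
#' @param object a `sweep_result` from [conductivity_sweep()].
#' @param metric `"re"` or `"cc"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sweep_result <- function(object, metric = c("re", "cc"), ...) {
  metric <- match.arg(metric)
  tb <- tibble::as_tibble(object)
  col <- if (metric == "re") "median_re" else "median_cc"
  ggplot2::ggplot(tb, ggplot2::aes(x = factor(.data$K_test),
                                   y = factor(.data$K_ref),
                                   fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (metric == "re") "median RE"
                                  else "median CC",
                                  direction = if (metric == "re") -1 else 1) +
    ggplot2::labs(x = expression(K[test]), y = expression(K[ref]),
                  title = sprintf("%s %s sweep",
                                  attr(object, "modality") %||% "",
                                  attr(object, "test_kind") %||% "")) +
    ggplot2::theme_minimal()
}

#' Convergence plot of verification results
#'
#' Median RE against the analytic sphere oracle as a function of mesh level,
#' per method and modality, with 16th/84th percentile ribbons.
#'
#' @param verification tibble from [cmd_verify_sphere()] /
#'   [verify_sphere_models()].
#' @return a ggplot object.
#' @export
plot_convergence <- function(verification) {
  ggplot2::ggplot(verification,
                  ggplot2::aes(x = .data$level, y = .data$median_re,
                               colour = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p16_re,
                                      ymax = .data$p84_re,
                                      fill = .data$method),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = "icosphere level (pial / inner skull)",
                  y = "median RE vs analytic oracle") +
    ggplot2::theme_minimal()
}
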