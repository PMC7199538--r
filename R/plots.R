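#' Plot the KO-vs-FA improvement curve
#'
#' @param sweep A tibble from [evaluate_improvement()].
#' @return A ggplot object.
#' @export
plot_improvement <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = K, y = improvement_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = improvement_pct - 2 * se,
                                      ymax = improvement_pct + 2 * se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Total bed capacity K",
                  y = "Improvement of KO over FA (%)") +
    ggplot2::theme_minimal()
}

#' Plot a kernel-optimization learning curve
#'
#' @param curve A tibble from [ko_learning_curve()].
#' @return A ggplot object faceting the chosen urgent quota and the
#'   objective against the sample size.
#' @export
plot_learning_curve <- function(curve) {
  long <- tidyr::pivot_longer(curve, c(Q1, objective))
  ggplot2::ggplot(long, ggplot2::aes(x = n, y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "Sample size n", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname sweep_controls
#' @param object An `equity_sweep`.
#' @param ... Unused.
#' @export
autoplot.equity_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = alpha, y = xi, fill = f)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "alpha (waiting-mix coefficient)",
                  y = "xi (reservation proportion)", fill = "f") +
    ggplot2::theme_minimal()
}

#' @rdname sweep_cost
#' @param object A `cost_sweep`.
#' @param ... Unused.
#' @export
autoplot.cost_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = xi, y = f, colour = factor(b))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "xi (reservation proportion)", y = "f",
                  colour = "extra-bed cost b") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
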