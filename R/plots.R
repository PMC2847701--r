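#' Plot the risk functions of a benchmark set
#'
#' Draws each model's risk function \eqn{g_x} over the populated range of
#' risk-allele counts, with the proportion of the population carrying `x` or
#' more risk alleles as a dotted reference curve.
#'
#' @param object A [benchmark_set()].
#' @param models Which of the four models to draw (default: the three
#'   constrained ones; the unconstrained multiplicative model's risks can
#'   exceed 1 and distort the scale).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(benchmark_set(K = 0.05, n = 200, p = 0.3, h2l = 0.5))
#' @method autoplot benchmark_set
#' @export
autoplot.benchmark_set <- function(object,
                                   models = c("crisch", "odds", "probit"),
                                   ...) {
  models <- match.arg(models, c("risch", "crisch", "odds", "probit"),
                      several.ok = TRUE)
  tab <- risk_function_table(object$models[models])
  long <- tidyr::pivot_longer(tab, dplyr::all_of(models),
                              names_to = "model", values_to = "g")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$g, colour = .data$model)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_ge), linetype = "dotted") +
    ggplot2::labs(
      x = "risk alleles carried (x)",
      y = expression(paste("risk of disease ", g[x])),
      colour = "model",
      title = sprintf("K = %g, n = %d, p = %g, h2l = %g (benchmark tau = %.3f)",
                      object$K, object$n, object$p, object$h2l,
                      object$tau_benchmark),
      caption = "dotted: proportion of the population with x or more risk alleles"
    ) +
    ggplot2::theme_minimal()
}

#' Plot risk-scale heritability against liability-scale heritability
#'
#' Companion display for [comparison_grid()] output: one line per model kind
#' (faceted by prevalence when several `K` are present), showing how the
#' broad-sense heritability on the risk scale grows with the liability-scale
#' heritability used to anchor the set.
#'
#' @param grid A tibble from [comparison_grid()].
#' @return A ggplot object.
#' @export
plot_comparison_grid <- function(grid) {
  stopifnot(all(c("K", "h2l", "kind", "h2_01") %in% names(grid)))
  pl <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$h2l, y = .data$h2_01,
                                           colour = .data$kind)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "heritability on the liability scale (h2l)",
                  y = "broad-sense heritability on the risk scale (H2_01)",
                  colour = "model") +
    ggplot2::theme_minimal()
  if (length(unique(grid$K)) > 1L) {
    pl <- pl + ggplot2::facet_wrap(ggplot2::vars(.data$K), labeller = "label_both")
  }
  pl
}
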