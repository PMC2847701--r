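#' Distribution of risk-allele counts in the population
#'
#' Under Hardy-Weinberg equilibrium and `n` independent biallelic loci with a
#' shared risk-allele frequency `p`, the number of risk alleles carried by an
#' individual is Binomial(2n, p). Probabilities are computed in log space so
#' the tails remain exact for `n` well beyond 10^4.
#'
#' @param n Number of risk loci.
#' @param p Risk-allele frequency.
#' @return A tibble with columns `x` (risk-allele count, `0:(2n)`), `q`
#'   (probability of carrying exactly `x` risk alleles) and `cum_ge`
#'   (probability of carrying `x` or more).
#' @examples
#' genotype_pmf(2, 0.5)
#' @export
genotype_pmf <- function(n, p) {
  check_prob(p, "p")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer.")
  }
  x <- 0:(2L * n)
  tibble::tibble(
    x = x,
    q = exp(dbinom(x, 2L * n, p, log = TRUE)),
    cum_ge = pbinom(x - 1L, 2L * n, p, lower.tail = FALSE)
  )
}

#' Broad-sense heritability on the disease risk scale
#'
#' The variance of the risk function over the population genotype
#' distribution, divided by the phenotypic variance of the 0/1 disease
#' outcome, \eqn{K(1-K)}:
#' \deqn{H^2_{01} = \sum_x q_x (g_x - \bar g)^2 / (K(1-K)).}
#' For the unconstrained `risch` model the impossible risks \eqn{g_x > 1}
#' enter the sum as-is, which is exactly how that model inflates its
#' heritability; the constrained model caps them first.
#'
#' @param model A calibrated [risk_model()].
#' @param truncate_sd Optionally restrict the genotype support to
#'   `2np ± truncate_sd` binomial standard deviations before summing
#'   (default `Inf`, the full exact support). Exposed for sensitivity
#'   analysis; the mass outside the retained range is simply dropped.
#' @return The heritability \eqn{H^2_{01}} (non-negative scalar; bounded by 1
#'   for models whose risks stay in \[0, 1\]).
#' @examples
#' m <- risk_model("probit", K = 0.01, n = 1000, p = 0.3, h2l = 0.5)
#' heritability_risk_scale(m)
#' @export
heritability_risk_scale <- function(model, truncate_sd = Inf) {
  stopifnot(inherits(model, "risk_model"))
  n <- model$n; p <- model$p
  x <- 0:(2L * n)
  if (is.finite(truncate_sd)) {
    mu <- 2 * n * p
    sd <- sqrt(2 * n * p * (1 - p))
    x <- x[x >= mu - truncate_sd * sd & x <= mu + truncate_sd * sd]
  }
  lq <- dbinom(x, 2L * n, p, log = TRUE)
  lg <- log_risk(model, x)
  eg <- exp(logsumexp(lq + lg))
  eg2 <- exp(logsumexp(lq + 2 * lg))
  (eg2 - eg^2) / (model$K * (1 - model$K))
}

#' Where the unconstrained multiplicative model breaks down
#'
#' The unconstrained model's risk \eqn{f_n \tau^x} exceeds 1 once
#' \eqn{x > -\ln f_n / \ln \tau}. This reports the largest risk-allele count
#' whose risk is still a probability, the exact binomial mass of the
#' population above it, and whether the constraint would bind anywhere on the
#' support.
#'
#' @param model A calibrated [risk_model()] of kind `"risch"`.
#' @return A one-row tibble: `threshold_x` (largest `x` with
#'   \eqn{g_x \le 1}; equals `2n` when risks never exceed 1, including the
#'   null model `tau = 1`), `mass_above` (exact binomial probability of
#'   carrying more than `threshold_x` risk alleles) and `constraint_active`.
#' @examples
#' m <- risk_model("risch", K = 0.1, n = 1000, p = 0.1, tau = 1.1)
#' impossible_risk_report(m)
#' @export
impossible_risk_report <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  if (model$kind != "risch") {
    abort("`impossible_risk_report()` applies to the unconstrained 'risch' model.")
  }
  n2 <- 2L * model$n
  lf <- log(model$baseline[["f_n"]])
  if (model$tau <= 1 || lf + n2 * log(model$tau) <= 0) {
    thr <- n2
  } else {
    # largest integer x with lf + x log(tau) <= 0
    thr <- floor(-lf / log(model$tau))
    if (lf + thr * log(model$tau) > 0) thr <- thr - 1L # guard fp rounding
    thr <- as.integer(thr)
  }
  tibble::tibble(
    threshold_x = thr,
    mass_above = pbinom(thr, n2, model$p, lower.tail = FALSE),
    constraint_active = thr < n2
  )
}

#' Tabulate risk functions of several models on a shared genotype range
#'
#' Produces the data behind risk-function plots: for each risk-allele count,
#' the population probability of that count, the proportion of the population
#' carrying that many or more risk alleles, and each model's risk \eqn{g_x}.
#' All models must share `(n, p)` so the x-axis means the same thing.
#'
#' @param models A list of calibrated [risk_model()] objects (possibly named;
#'   unnamed entries are labelled by their kind).
#' @param x_range Integer vector of counts to tabulate. Default: the mean
#'   `2np` plus/minus 4 binomial standard deviations, clipped to `0:(2n)` --
#'   essentially everyone in the population.
#' @return A tibble with columns `x`, `q`, `cum_ge` and one risk column per
#'   model.
#' @examples
#' bs <- benchmark_set(K = 0.1, n = 100, p = 0.3, h2l = 0.5)
#' risk_function_table(bs$models[c("crisch", "probit")])
#' @export
risk_function_table <- function(models, x_range = NULL) {
  if (inherits(models, "risk_model")) models <- list(models)
  stopifnot(length(models) >= 1L, all(purrr::map_lgl(models, inherits, "risk_model")))
  n <- models[[1]]$n; p <- models[[1]]$p
  same <- purrr::map_lgl(models, ~ .x$n == n && .x$p == p)
  if (!all(same)) abort("all models must share the same (n, p).")
  if (is.null(x_range)) {
    mu <- 2 * n * p; sd <- sqrt(2 * n * p * (1 - p))
    x_range <- max(0L, floor(mu - 4 * sd)):min(2L * n, ceiling(mu + 4 * sd))
  }
  if (any(x_range < 0 | x_range > 2L * n)) abort("`x_range` outside 0..2n.")
  nms <- names(models)
  if (is.null(nms)) nms <- rep("", length(models))
  blank <- !nzchar(nms)
  nms[blank] <- purrr::map_chr(models[blank], "kind")
  names(models) <- make.unique(nms)
  out <- tibble::tibble(
    x = as.integer(x_range),
    q = exp(dbinom(x_range, 2L * n, p, log = TRUE)),
    cum_ge = pbinom(x_range - 1L, 2L * n, p, lower.tail = FALSE)
  )
  for (nm in names(models)) out[[nm]] <- risk(models[[nm]], x_range)
  out
}

# log(sum(exp(lx))) without overflow
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}
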