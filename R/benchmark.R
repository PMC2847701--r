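#' Per-allele relative risk implied by a probit model
#'
#' The effect size benchmark used to place all models on a common footing:
#' the relative risk of one extra risk allele at the population mean
#' genotype, \eqn{\tau = g_{2np+1} / g_{2np}}, computed from the calibrated
#' probit risk function. When `2np` is not an integer the anchor pair is
#' `(round(2np), round(2np) + 1)`: the benchmark is a local slope at the
#' mean.
#'
#' @param model A calibrated [risk_model()] of kind `"probit"`.
#' @return The benchmark \eqn{\tau \ge 1} (exactly 1 when `h2l = 0`).
#' @examples
#' m <- risk_model("probit", K = 0.01, n = 1000, p = 0.3, h2l = 0.5)
#' tau_from_probit(m) # ~1.19
#' @export
tau_from_probit <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  if (model$kind != "probit") abort("`tau_from_probit()` needs a probit model.")
  if (model$h2l == 0) return(1)
  m <- as.integer(round(2 * model$n * model$p))
  if (m + 1L > 2L * model$n) abort("anchor point 2np + 1 outside the support.")
  exp(diff(log_risk(model, c(m, m + 1L))))
}

#' Build the four models matched on prevalence and per-allele effect
#'
#' The comparison procedure: a probit (liability-threshold) model is built
#' from `(K, n, p, h2l)`; its local per-allele relative risk at the mean
#' genotype ([tau_from_probit()]) becomes the effect size \eqn{\tau} fed to
#' the unconstrained multiplicative, constrained multiplicative and odds
#' models (for the odds model the per-allele odds factor \eqn{\gamma} is set
#' equal to \eqn{\tau}). All four models then share `(K, n, p)` and are
#' individually calibrated so mean risk equals `K`.
#'
#' @inheritParams risk_model
#' @return An object of class `"benchmark_set"`: a list with `models` (named
#'   list `risch`, `crisch`, `odds`, `probit`), `tau_benchmark`, and the
#'   shared parameters. `tidy()` returns one row per model with its
#'   risk-scale heritability and analytic \eqn{\lambda_{MZ}}.
#' @examples
#' bs <- benchmark_set(K = 0.01, n = 1000, p = 0.3, h2l = 0.5)
#' bs$tau_benchmark
#' tidy(bs)
#' @export
benchmark_set <- function(K, n, p, h2l) {
  probit <- risk_model("probit", K = K, n = n, p = p, h2l = h2l)
  tau <- tau_from_probit(probit)
  structure(
    list(
      models = list(
        risch  = risk_model("risch",  K = K, n = n, p = p, tau = tau),
        crisch = risk_model("crisch", K = K, n = n, p = p, tau = tau),
        odds   = risk_model("odds",   K = K, n = n, p = p, tau = tau),
        probit = probit
      ),
      tau_benchmark = tau, K = K, n = n, p = p, h2l = h2l
    ),
    class = "benchmark_set"
  )
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf(
    "<benchmark_set: K = %g, n = %d, p = %g, h2l = %g, benchmark tau = %.4f>\n",
    x$K, x$n, x$p, x$h2l, x$tau_benchmark))
  print(tidy(x))
  invisible(x)
}

#' @rdname benchmark_set
#' @param x A `benchmark_set` object.
#' @param ... Unused.
#' @method tidy benchmark_set
#' @export
tidy.benchmark_set <- function(x, ...) {
  purrr::map_dfr(names(x$models), function(kind) {
    m <- x$models[[kind]]
    tibble::tibble(
      kind = kind, K = x$K, n = x$n, p = x$p, h2l = x$h2l,
      tau = x$tau_benchmark,
      h2_01 = heritability_risk_scale(m),
      lambda_mz = lambda_mz_exact(m)
    )
  })
}

#' Run the model comparison over a parameter grid
#'
#' Builds a [benchmark_set()] for every combination of the supplied
#' prevalences, locus numbers, allele frequencies and liability
#' heritabilities, and returns a long-format table of risk-scale
#' heritabilities and analytic MZ recurrence risks, one row per parameter
#' combination per model. Deterministic.
#'
#' @param K,n,p,h2l Numeric vectors of parameter values; the grid is their
#'   Cartesian product.
#' @return A tibble with columns `K`, `n`, `p`, `h2l`, `tau` (the benchmark
#'   effect for that combination), `kind`, `h2_01`, `lambda_mz`.
#' @examples
#' comparison_grid(K = 0.1, n = c(100, 1000), p = 0.3, h2l = 0.5)
#' @export
comparison_grid <- function(K, n, p, h2l) {
  if (!length(K) || !length(n) || !length(p) || !length(h2l)) {
    abort("all grid dimensions must be non-empty.")
  }
  grid <- tidyr::expand_grid(K = K, n = n, p = p, h2l = h2l)
  purrr::pmap_dfr(grid, function(K, n, p, h2l) {
    tidy(benchmark_set(K = K, n = n, p = p, h2l = h2l))
  }) |>
    dplyr::relocate("K", "n", "p", "h2l", "tau", "kind")
}

#' Effect size matching a target MZ recurrence risk
#'
#' Inverts a model family: finds the per-allele effect (`tau` for the
#' multiplicative and odds kinds, `h2l` for probit) whose calibrated model
#' has analytic \eqn{\lambda_{MZ}} ([lambda_mz_exact()]) equal to
#' `target_lambda_mz`, by bracketed bisection on the effect. \eqn{\lambda_{MZ}}
#' is increasing in the effect for every kind, and cannot exceed \eqn{1/K}.
#'
#' @inheritParams risk_model
#' @param kind Model kind to invert.
#' @param target_lambda_mz Target in \eqn{(1, 1/K)}.
#' @param tol Relative tolerance on the recovered \eqn{\lambda_{MZ}}.
#' @return The effect parameter (named `tau` or `h2l`).
#' @examples
#' solve_effect_for_lambda("probit", K = 0.05, n = 200, p = 0.3,
#'                         target_lambda_mz = 5)
#' @export
solve_effect_for_lambda <- function(kind = c("risch", "crisch", "odds", "probit"),
                                    K, n, p, target_lambda_mz, tol = 1e-6) {
  kind <- match.arg(kind)
  check_prob(K, "K")
  if (target_lambda_mz == 1) {
    return(if (kind == "probit") c(h2l = 0) else c(tau = 1))
  }
  if (target_lambda_mz < 1 || target_lambda_mz >= 1 / K) {
    abort(sprintf(
      "`target_lambda_mz` must lie in [1, 1/K) = [1, %g): lambda_MZ is capped at 1/K.",
      1 / K))
  }
  lam_at <- function(eff) {
    m <- if (kind == "probit") {
      risk_model("probit", K = K, n = n, p = p, h2l = eff)
    } else {
      risk_model(kind, K = K, n = n, p = p, tau = eff)
    }
    lambda_mz_exact(m) - target_lambda_mz
  }
  if (kind == "probit") {
    lo <- 1e-8; hi <- 1 - 1e-8
    if (lam_at(hi) < 0) {
      abort(sprintf(
        "target lambda_MZ = %g unattainable for probit at these (K, n, p); maximum is %g (at h2l near 1; absolute bound 1/K = %g).",
        target_lambda_mz, lam_at(hi) + target_lambda_mz, 1 / K))
    }
  } else {
    lo <- 1 + 1e-10
    hi <- 1.5
    while (lam_at(hi) < 0 && hi < 1e4) hi <- hi^2
    if (lam_at(hi) < 0) {
      abort(sprintf(
        "target lambda_MZ = %g unattainable for %s at these (K, n, p) (absolute bound 1/K = %g).",
        target_lambda_mz, kind, 1 / K))
    }
  }
  eff <- uniroot(lam_at, c(lo, hi), tol = .Machine$double.eps^0.5,
                 maxiter = 200L)$root
  if (abs(lam_at(eff)) > tol * target_lambda_mz) {
    eff <- uniroot(lam_at, c(lo, hi), tol = .Machine$double.eps^0.75,
                   maxiter = 500L)$root
  }
  setNames(eff, if (kind == "probit") "h2l" else "tau")
}
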