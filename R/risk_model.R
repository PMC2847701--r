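#' Construct and calibrate a multi-locus disease risk model
#'
#' Builds one of four models of how per-locus genetic risks combine into an
#' individual's probability of disease \eqn{g_x}, given a count \eqn{x} of risk
#' alleles out of \eqn{2n}. Every model is calibrated so that the population
#' mean risk over the exact Binomial(2n, p) distribution of risk-allele counts
#' equals the disease prevalence \eqn{K}.
#'
#' The four kinds are:
#' \describe{
#'   \item{`risch`}{multiplicative on the risk scale, \eqn{g_x = f_n \tau^x}
#'     with the closed-form baseline \eqn{f_n = K/(1+p(\tau-1))^{2n}}. Risks
#'     are deliberately unconstrained and may exceed 1; see
#'     [impossible_risk_report()].}
#'   \item{`crisch`}{the constrained variant, \eqn{g_x = \min(f_n \tau^x, 1)},
#'     with \eqn{f_n} solved numerically so the capped risks still average to
#'     \eqn{K}.}
#'   \item{`odds`}{multiplicative on the odds scale,
#'     \eqn{g_x/(1-g_x) = \gamma^x C_n}, with \eqn{C_n} solved numerically.
#'     The per-allele odds factor \eqn{\gamma} is supplied through `tau`.}
#'   \item{`probit`}{the liability-threshold model: disease occurs when a
#'     standard-normal liability exceeds a threshold \eqn{t}. The genetic value
#'     of an individual with \eqn{x} risk alleles is \eqn{u_x = (x - 2np)a}
#'     with \eqn{a = \sqrt{h^2_l / (2np(1-p))}} so the genetic variance on the
#'     liability scale equals `h2l`, and
#'     \eqn{g_x = \Phi((u_x - t)/\sqrt{1-h^2_l})}. The threshold is solved
#'     numerically (starting from \eqn{\Phi^{-1}(1-K)}) so that the population
#'     mean risk over the discrete genotype distribution equals \eqn{K}
#'     exactly; the nominal normal quantile is retained in `t_nominal`.}
#' }
#'
#' @param kind One of `"risch"`, `"crisch"`, `"odds"`, `"probit"`.
#' @param K Disease prevalence, in (0, 1).
#' @param n Number of contributing biallelic risk loci (positive integer).
#' @param p Risk-allele frequency shared by all loci, in (0, 1).
#' @param tau Per-allele relative risk (`risch`/`crisch`) or per-allele odds
#'   factor (`odds`); `tau = 1` is the null model. Ignored for `probit`.
#' @param h2l Heritability on the liability scale, in \[0, 1), for `probit`
#'   only.
#'
#' @return An object of class `"risk_model"`: a list with the configuration,
#'   the solved baseline constant (`f_n`, `C_n`, or `c(a, t)`), and the
#'   calibration residual `|E(g) - K|`.
#'
#' @examples
#' m <- risk_model("crisch", K = 0.01, n = 1000, p = 0.3, tau = 1.2)
#' m
#' risk(m, c(500, 600, 700))
#' glance(m)
#' @seealso [risk()], [lambda_mz_exact()], [heritability_risk_scale()]
#' @export
risk_model <- function(kind = c("risch", "crisch", "odds", "probit"),
                       K, n, p, tau = NULL, h2l = NULL) {
  kind <- match.arg(kind)
  check_prob(K, "K")
  check_prob(p, "p")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer.", class = "multirisk_invalid")
  }
  n <- as.integer(round(n))

  if (kind == "probit") {
    if (is.null(h2l)) abort("`h2l` is required for the probit model.")
    if (!is.null(tau)) abort("`tau` does not apply to the probit model; use `h2l`.")
    if (!is.numeric(h2l) || length(h2l) != 1L || h2l < 0 || h2l >= 1) {
      abort("`h2l` must be a single value in [0, 1).", class = "multirisk_invalid")
    }
    par <- probit_params(K, n, p, h2l)
    baseline <- c(a = unname(par[["a"]]), t = unname(par[["t"]]))
    t_nominal <- attr(par, "t_nominal")
  } else {
    if (is.null(tau)) abort(sprintf("`tau` is required for the %s model.", kind))
    if (!is.null(h2l)) abort("`h2l` applies to the probit model only; use `tau`.")
    if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
      abort("`tau` must be a single positive value.", class = "multirisk_invalid")
    }
    baseline <- switch(kind,
      risch  = c(f_n = risch_baseline(K, n, p, tau)),
      crisch = c(f_n = crisch_calibrate(K, n, p, tau)),
      odds   = c(C_n = odds_calibrate(K, n, p, tau))
    )
    t_nominal <- NULL
  }

  model <- structure(
    list(kind = kind, K = K, n = n, p = p, tau = tau, h2l = h2l,
         baseline = baseline, t_nominal = t_nominal, residual = NA_real_),
    class = "risk_model"
  )
  x <- 0:(2L * n)
  eg <- sum(exp(dbinom(x, 2L * n, p, log = TRUE) + log_risk(model, x)))
  model$residual <- abs(eg - K)
  if (model$residual > 1e-8 * K) {
    abort(sprintf("calibration failed for %s model: |E(g) - K| = %.3e", kind,
                  model$residual), class = "multirisk_solver")
  }
  model
}

#' Closed-form baseline risk of the unconstrained multiplicative model
#'
#' \eqn{f_n = K / (1 + p(\tau - 1))^{2n}}, the probability of disease for an
#' individual carrying only wild-type alleles at all `n` loci. Evaluated on
#' the log scale so large `n` does not underflow. With this constant the exact
#' binomial expectation of \eqn{f_n \tau^x} equals `K`.
#'
#' @inheritParams risk_model
#' @return The baseline probability \eqn{f_n} (a positive scalar, possibly
#'   much smaller than double-precision underflow-free ranges would suggest).
#' @export
risch_baseline <- function(K, n, p, tau) {
  check_prob(K, "K")
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be positive.")
  exp(log(K) - 2 * n * log1p(p * (tau - 1)))
}

#' Calibrate the constrained multiplicative model
#'
#' Solves \eqn{\sum_x q_x \min(f_n \tau^x, 1) = K} for \eqn{f_n} over the
#' exact binomial support by bracketed root finding on \eqn{\log f_n}. The
#' bracket \eqn{[\log f_n^{(risch)}, 0]} is exact: capping removes probability
#' mass, so the constrained baseline can only be larger than the closed-form
#' unconstrained one.
#'
#' @inheritParams risk_model
#' @return The solved baseline \eqn{f_n}.
#' @export
crisch_calibrate <- function(K, n, p, tau) {
  check_prob(K, "K"); check_prob(p, "p")
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be positive.")
  if (tau == 1) return(K)
  x <- 0:(2L * n)
  lq <- dbinom(x, 2L * n, p, log = TRUE)
  ltau <- log(tau)
  lf_risch <- log(K) - 2 * n * log1p(p * (tau - 1))
  if (lf_risch + 2 * n * ltau <= 0) return(exp(lf_risch)) # constraint inactive
  fn <- function(lf) sum(exp(lq + pmin(lf + x * ltau, 0))) - K
  sol <- solve_root(fn, lower = lf_risch, upper = 0,
                    what = "CRisch baseline f_n")
  exp(sol)
}

#' Calibrate the odds (logit) model
#'
#' Solves \eqn{\sum_x q_x \, \gamma^x C_n / (1 + \gamma^x C_n) = K} for the
#' baseline odds \eqn{C_n}. The bracket
#' \eqn{[\gamma^{-2n} K/(1-K),\; K/(1-K)]} is exact for \eqn{\gamma \ge 1}:
#' at the upper end every genotype has risk at least `K`, at the lower end at
#' most `K`. For \eqn{\gamma < 1} the bracket is mirrored.
#'
#' @inheritParams risk_model
#' @param tau The per-allele odds factor \eqn{\gamma}.
#' @return The solved baseline odds \eqn{C_n} (odds of disease for an
#'   all-wild-type individual).
#' @export
odds_calibrate <- function(K, n, p, tau) {
  check_prob(K, "K"); check_prob(p, "p")
  if (!is.numeric(tau) || tau <= 0) abort("`tau` (odds factor gamma) must be positive.")
  if (tau == 1) return(K / (1 - K))
  x <- 0:(2L * n)
  lq <- dbinom(x, 2L * n, p, log = TRUE)
  lgam <- log(tau)
  lC0 <- log(K / (1 - K))
  br <- sort(c(lC0 - 2 * n * lgam, lC0))
  fn <- function(lC) sum(exp(lq + plogis(x * lgam + lC, log.p = TRUE))) - K
  sol <- solve_root(fn, lower = br[1], upper = br[2],
                    what = "odds baseline C_n")
  exp(sol)
}

#' Liability-scale parameters of the probit model
#'
#' Returns the per-allele liability effect
#' \eqn{a = \sqrt{h^2_l / (2np(1-p))}} -- chosen so the binomial genetic
#' variance on the liability scale equals `h2l` with total phenotypic
#' variance 1 -- and the disease threshold `t`. The threshold starts at the
#' normal quantile \eqn{\Phi^{-1}(1-K)} and is then adjusted numerically so
#' that the mean risk over the exact discrete genotype distribution equals
#' `K`; for moderate `n` the adjustment is tiny but it is what makes the
#' probit model satisfy the same calibration identity as the other models.
#'
#' @inheritParams risk_model
#' @return Named numeric vector `c(a = , t = )` with attribute `"t_nominal"`
#'   holding \eqn{\Phi^{-1}(1-K)}.
#' @export
probit_params <- function(K, n, p, h2l) {
  check_prob(K, "K"); check_prob(p, "p")
  if (!is.numeric(h2l) || h2l < 0 || h2l >= 1) abort("`h2l` must be in [0, 1).")
  t_nom <- qnorm(1 - K)
  a <- sqrt(h2l / (2 * n * p * (1 - p)))
  if (h2l == 0) {
    out <- c(a = 0, t = t_nom)
    attr(out, "t_nominal") <- t_nom
    return(out)
  }
  x <- 0:(2L * n)
  q <- exp(dbinom(x, 2L * n, p, log = TRUE))
  u <- (x - 2 * n * p) * a
  sd_res <- sqrt(1 - h2l)
  fn <- function(t) sum(q * pnorm((u - t) / sd_res)) - K
  # E(g) is strictly decreasing in t; the nominal quantile is within O(1/n)
  t_cal <- solve_root(fn, lower = t_nom - 6, upper = t_nom + 6,
                      what = "probit threshold t")
  out <- c(a = a, t = t_cal)
  attr(out, "t_nominal") <- t_nom
  out
}

#' Genetic risk of disease given a risk-allele count
#'
#' Evaluates the model's risk function \eqn{g_x} at integer risk-allele counts
#' `x` in `0:(2n)`. For the unconstrained `risch` model the value may exceed
#' 1 -- this is a deliberate property of that model, diagnosed by
#' [impossible_risk_report()].
#'
#' @param model A calibrated [risk_model()].
#' @param x Integer vector of risk-allele counts in `0:(2n)`.
#' @return Numeric vector of risks, same length as `x`.
#' @export
risk <- function(model, x) {
  stopifnot(inherits(model, "risk_model"))
  if (any(x < 0 | x > 2 * model$n | x != round(x))) {
    abort(sprintf("`x` must be integer counts in 0..%d.", 2 * model$n))
  }
  exp(log_risk(model, x))
}

# log g_x; the stable workhorse behind risk(), heritability and lambda sums
log_risk <- function(model, x) {
  b <- model$baseline
  switch(model$kind,
    risch  = log(b[["f_n"]]) + x * log(model$tau),
    crisch = pmin(log(b[["f_n"]]) + x * log(model$tau), 0),
    odds   = plogis(x * log(model$tau) + log(b[["C_n"]]), log.p = TRUE),
    probit = {
      if (model$h2l == 0) return(rep(pnorm(-b[["t"]], log.p = TRUE), length(x)))
      u <- (x - 2 * model$n * model$p) * b[["a"]]
      pnorm((u - b[["t"]]) / sqrt(1 - model$h2l), log.p = TRUE)
    }
  )
}

# effect-size value of a model (tau for the multiplicative/odds kinds,
# h2l for probit)
effect_of <- function(model) {
  if (model$kind == "probit") model$h2l else model$tau
}

#' @export
print.risk_model <- function(x, ...) {
  eff <- if (x$kind == "probit") {
    sprintf("h2l = %g", x$h2l)
  } else {
    sprintf("%s = %g", if (x$kind == "odds") "gamma" else "tau", x$tau)
  }
  cat(sprintf("<risk_model: %s>  K = %g, n = %d, p = %g, %s\n",
              x$kind, x$K, x$n, x$p, eff))
  b <- x$baseline
  cat("  baseline:", paste(sprintf("%s = %.6g", names(b), b), collapse = ", "),
      "\n")
  cat(sprintf("  calibration residual |E(g) - K| = %.2e\n", x$residual))
  invisible(x)
}

#' @rdname risk_model
#' @param x A `risk_model` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, K = x$K, n = x$n, p = x$p,
    effect = effect_of(x),
    effect_type = if (x$kind == "probit") "h2l" else "tau",
    baseline = list(x$baseline),
    residual = x$residual
  )
}

#' @rdname risk_model
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, K = x$K,
    h2_01 = heritability_risk_scale(x),
    lambda_mz = lambda_mz_exact(x),
    residual = x$residual
  )
}

# ---- shared numeric helpers -------------------------------------------------

check_prob <- function(v, name) {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
    abort(sprintf("`%s` must be a single probability strictly in (0, 1).", name),
          class = "multirisk_invalid")
  }
  invisible(v)
}

# bracketed root solve with diagnostics on failure
solve_root <- function(fn, lower, upper, what,
                       tol = .Machine$double.eps^0.75) {
  flo <- fn(lower); fhi <- fn(upper)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    abort(sprintf(
      "root finding for %s failed: f(%.6g) = %.3e, f(%.6g) = %.3e do not bracket 0.",
      what, lower, flo, upper, fhi), class = "multirisk_solver")
  }
  uniroot(fn, c(lower, upper), f.lower = flo, f.upper = fhi,
          tol = tol, maxiter = 200L)$root
}
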