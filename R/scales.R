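#' Liability-threshold quantities for a given prevalence
#'
#' The standard normal machinery of the liability model: threshold
#' \eqn{t = \Phi^{-1}(1-K)}, the normal density at the threshold
#' \eqn{z = \phi(t)}, and the mean liability of the affected group
#' \eqn{i = z/K} (the selection intensity of truncating the top `K` of a
#' standard normal).
#'
#' @param K Disease prevalence.
#' @return A one-row tibble with columns `K`, `t`, `z`, `i`.
#' @examples
#' liability_quantities(0.05) # t = 1.645
#' @export
liability_quantities <- function(K) {
  check_prob(K, "K")
  t <- qnorm(1 - K)
  z <- dnorm(t)
  tibble::tibble(K = K, t = t, z = z, i = z / K)
}

#' Liability-scale to risk-scale heritability (Robertson transformation)
#'
#' Converts narrow-sense heritability on the liability scale to the risk
#' (0/1) scale: \eqn{h^2_{01} = h^2_l \, z^2 / (K(1-K))}, where `z` is the
#' standard normal density at the threshold. Its maximum over `K` is
#' \eqn{2/\pi \approx 0.64}, attained at `K = 0.5` with `h2l = 1`.
#'
#' @param h2l Heritability on the liability scale, in \[0, 1\].
#' @param K Disease prevalence.
#' @return Narrow-sense heritability on the risk scale.
#' @examples
#' robertson_h2_01(1, 0.5) # 2/pi = 0.6366
#' @export
robertson_h2_01 <- function(h2l, K) {
  check_prob(K, "K")
  if (any(h2l < 0 | h2l > 1)) abort("`h2l` must be in [0, 1].")
  z <- dnorm(qnorm(1 - K))
  h2l * z^2 / (K * (1 - K))
}

#' Odds ratios implied by a single multiplicative-risk locus
#'
#' For one locus with per-allele relative risk `tau`, the three genotype
#' penetrances are \eqn{f, \tau f, \tau^2 f} with the baseline solved from
#' \eqn{E(g) = K} at `n = 1`: \eqn{f = K/(1+p(\tau-1))^2}. The implied
#' odds ratios are
#' \deqn{OR_{het} = \tau (1-f) / (1-\tau f), \quad
#'       OR_{hom} = \tau^2 (1-f) / (1-\tau^2 f),}
#' and `hom_over_het_sq` \eqn{= OR_{hom}/OR_{het}^2} measures how far the
#' multiplicative-risk locus departs from multiplicative odds (for which the
#' ratio is exactly 1). As the penetrance \eqn{f \to 0} odds ratios and
#' relative risks coincide.
#'
#' @param K Disease prevalence.
#' @param p Risk-allele frequency.
#' @param tau Per-allele relative risk.
#' @return A one-row tibble: `f`, `or_het`, `or_hom`, `hom_over_het_sq`.
#' @examples
#' single_locus_or(K = 0.1, p = 0.1, tau = 2)      # ratio 1.13
#' single_locus_or(K = 0.01, p = 0.1, tau = 1.05)  # ratio 1.00003
#' @export
single_locus_or <- function(K, p, tau) {
  check_prob(K, "K"); check_prob(p, "p")
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be positive.")
  f <- K / (1 + p * (tau - 1))^2
  if (tau^2 * f >= 1) {
    abort(sprintf(
      "homozygote penetrance tau^2 f = %.3f is not below 1; no finite odds ratio.",
      tau^2 * f))
  }
  or_het <- tau * (1 - f) / (1 - tau * f)
  or_hom <- tau^2 * (1 - f) / (1 - tau^2 * f)
  tibble::tibble(f = f, or_het = or_het, or_hom = or_hom,
                 hom_over_het_sq = or_hom / or_het^2)
}

#' Scaled per-allele variance under the unconstrained multiplicative model
#'
#' The contribution of a single risk allele to the genetic variance on the
#' risk scale, scaled by \eqn{K^2}:
#' \deqn{v = p(1-p)(\tau-1)^2 / [1 + p(\tau-1)]^2,}
#' with total scaled variance proportional to \eqn{nv}.
#'
#' @param p Risk-allele frequency.
#' @param tau Per-allele relative risk.
#' @return The scaled per-allele variance `v`.
#' @seealso [total_variance_approx()] for the small-`tau` approximation.
#' @examples
#' per_allele_variance(0.3, 1.2)
#' @export
per_allele_variance <- function(p, tau) {
  check_prob(p, "p")
  if (any(tau <= 0)) abort("`tau` must be positive.")
  p * (1 - p) * (tau - 1)^2 / (1 + p * (tau - 1))^2
}

#' Small-effect approximation to the total scaled variance
#'
#' For \eqn{\tau \to 1}, \eqn{nv \approx n p (1-p) (\tau-1)^2}, the familiar
#' expression used to apportion variance to a single locus.
#'
#' @param n Number of loci.
#' @param p Risk-allele frequency.
#' @param tau Per-allele relative risk.
#' @return Approximate total scaled variance \eqn{nv}.
#' @export
total_variance_approx <- function(n, p, tau) {
  n * p * (1 - p) * (tau - 1)^2
}

#' Marginal single-locus relative risk under the liability model
#'
#' When only one risk locus is in the statistical model, all other loci fold
#' into the residual liability variance (which then approaches the full
#' phenotypic variance of 1), and the estimated per-allele relative risk is
#' \deqn{\tau_{marginal} = \Phi(a - t) / \Phi(-t),}
#' as opposed to the conditional effect \eqn{g_{2np+1}/g_{2np}} at the mean
#' genetic background ([tau_from_probit()]). The marginal effect is the
#' smaller of the two for `h2l > 0`.
#'
#' @param a Per-allele liability effect (standard deviation units).
#' @param K Disease prevalence.
#' @return The marginal relative risk.
#' @examples
#' marginal_tau_probit(0.0345, 0.01) # ~1.10
#' @export
marginal_tau_probit <- function(a, K) {
  check_prob(K, "K")
  t <- qnorm(1 - K)
  pnorm(a - t) / pnorm(-t)
}

#' Liability-scale heritability implied by MZ concordance
#'
#' Inverts a bivariate liability model for MZ twins: with a fully shared
#' genetic liability \eqn{G \sim N(0, h^2_l)} and independent residuals of
#' variance \eqn{1 - h^2_l}, the probability that both twins are affected is
#' \deqn{P_{11}(h^2_l) = E_G\big[\Phi\{(G - t)/\sqrt{1-h^2_l}\}^2\big],}
#' and the function solves \eqn{P_{11} = \lambda_{MZ} K^2} for \eqn{h^2_l}.
#' This treats all twin resemblance as additive on the liability scale; it
#' is offered as a descriptive helper, not an estimator with known sampling
#' properties.
#'
#' @param lambda_mz MZ recurrence risk ratio, in \eqn{(1, 1/K)}.
#' @param K Disease prevalence.
#' @return The implied liability-scale heritability in (0, 1).
#' @export
liability_h2_from_mz_concordance <- function(lambda_mz, K) {
  check_prob(K, "K")
  if (lambda_mz <= 1 || lambda_mz >= 1 / K) {
    abort("`lambda_mz` must lie strictly between 1 and 1/K.")
  }
  t <- qnorm(1 - K)
  p11 <- function(h2) {
    s <- sqrt(h2); r <- sqrt(1 - h2)
    integrate(function(u) dnorm(u) * pnorm((s * u - t) / r)^2,
              -Inf, Inf, rel.tol = 1e-10)$value
  }
  target <- lambda_mz * K^2
  solve_root(function(h2) p11(h2) - target, lower = 1e-8, upper = 1 - 1e-8,
             what = "liability h2 from MZ concordance")
}
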