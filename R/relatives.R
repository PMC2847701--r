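#' Exact recurrence risk ratio for monozygotic twins
#'
#' MZ twins share their entire genotype, so the probability that both are
#' affected is \eqn{E(g^2)} and the recurrence risk ratio is
#' \deqn{\lambda_{MZ} = \sum_x q_x g_x^2 / K^2 = 1 + Var(g)/K^2,}
#' evaluated over the exact binomial genotype support.
#'
#' @param model A calibrated [risk_model()].
#' @return \eqn{\lambda_{MZ}} (a scalar \eqn{\ge 1}; bounded above by
#'   \eqn{1/K} for models whose risks stay in \[0, 1\]).
#' @examples
#' m <- risk_model("probit", K = 0.01, n = 1000, p = 0.3, h2l = 0.5)
#' lambda_mz_exact(m)
#' @export
lambda_mz_exact <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  x <- 0:(2L * model$n)
  lq <- dbinom(x, 2L * model$n, model$p, log = TRUE)
  exp(logsumexp(lq + 2 * log_risk(model, x)) - 2 * log(model$K))
}

#' Exact recurrence risk ratio for full siblings
#'
#' For exchangeable independent loci the two parents jointly carry `F` loci
#' where the transmitting parent is homozygous for the risk allele and `H`
#' loci where it is heterozygous, with
#' \eqn{(F, H) \sim} Multinomial\eqn{(2n; p^2, 2p(1-p), (1-p)^2)} (counting
#' each parent's `n` loci once for its transmission to a child). Conditional
#' on `(F, H)` the risk-allele counts of the two siblings are independent and
#' identically distributed as \eqn{F + Binomial(H, 1/2)}, so
#' \deqn{\lambda_{Sib} = E_{F,H}\big[ m(F,H)^2 \big] / K^2, \quad
#'       m(F,H) = E[g_{F + Binomial(H,1/2)}].}
#' The double sum is evaluated over all `(F, H)` cells whose joint log
#' probability exceeds machine-level mass (`tol`); the retained mass is
#' reported as an attribute.
#'
#' @param model A calibrated [risk_model()].
#' @param tol Per-cell probability floor; cells below `tol * 1e-10` of the
#'   modal cell are dropped. The default retains mass 1 to ~1e-12.
#' @return \eqn{\lambda_{Sib}} as a bare scalar. If the retained genotype
#'   mass falls short of 1 by more than 1e-9 a warning is raised.
#' @examples
#' m <- risk_model("probit", K = 0.05, n = 50, p = 0.3, h2l = 0.5)
#' lambda_sib_exact(m)
#' @export
lambda_sib_exact <- function(model, tol = 1e-12) {
  stopifnot(inherits(model, "risk_model"))
  n <- model$n; p <- model$p; K <- model$K
  g <- exp(log_risk(model, 0:(2L * n)))
  g <- pmin(g, 1) # joint probabilities need proper probabilities
  n2 <- 2L * n
  pF <- p^2; pH <- 2 * p * (1 - p)
  mF <- n2 * pF; sF <- sqrt(n2 * pF * (1 - pF))
  mH <- n2 * pH; sH <- sqrt(n2 * pH * (1 - pH))
  Fr <- max(0L, floor(mF - 8 * sF)):min(n2, ceiling(mF + 8 * sF))
  Hr <- max(0L, floor(mH - 8 * sH)):min(n2, ceiling(mH + 8 * sH))
  lcut <- log(tol) - 10
  tot <- 0; mass <- 0
  lmult <- function(F_, H_) {
    lgamma(n2 + 1) - lgamma(F_ + 1) - lgamma(H_ + 1) - lgamma(n2 - F_ - H_ + 1) +
      F_ * log(pF) + H_ * log(pH) + (n2 - F_ - H_) * log1p(-pF - pH)
  }
  for (H_ in Hr) {
    jw <- dbinom(0:H_, H_, 0.5)
    lp <- lmult(Fr, H_)
    keep <- which(lp > lcut & (Fr + H_) <= n2)
    if (!length(keep)) next
    for (i in keep) {
      F_ <- Fr[i]
      m <- sum(jw * g[F_ + 0:H_ + 1L])
      w <- exp(lp[i])
      tot <- tot + w * m^2
      mass <- mass + w
    }
  }
  if (mass < 1 - 1e-9) {
    warn(sprintf("lambda_sib_exact retained genotype mass %.12f < 1", mass))
  }
  tot / K^2
}

#' Simulate three-generation families under a risk model
#'
#' Gene-dropping simulation used to estimate recurrence risks to relatives.
#' Each family comprises a focal grandparent, two parents (one of whom is the
#' grandparent's child), two full siblings, and a monozygotic co-twin of the
#' first sibling. Genotypes follow exact Mendelian segregation at `n`
#' independent exchangeable loci; disease status is drawn independently per
#' individual as Bernoulli(\eqn{g_x}) given the risk-allele count `x` (no
#' shared environment).
#'
#' Because loci are exchangeable, individuals are represented by counts of
#' loci per genotype configuration rather than per-locus arrays: each family
#' draws one multinomial split of the `n` loci over the 27 joint
#' (grandparent genotype, parent-1 genotype, parent-2 genotype)
#' configurations, and transmissions to children are pooled binomial splits
#' (a heterozygous parent transmits the risk allele with probability 1/2).
#' This is distributionally exact and O(1) in `n` per family; correctness is
#' pinned against brute-force enumeration at small `n` in the test suite.
#'
#' @param model A calibrated [risk_model()].
#' @param n_families Number of independent families (default 1e5).
#' @param seed Integer seed; the whole sample is reproducible given
#'   `(seed, n_families)`. The caller's RNG state is left untouched.
#' @return An object of class `"family_sample"`: a list with the `model`,
#'   `n_families`, `seed`, a `tallies` tibble (one row per relative-pair
#'   kind: proband/relative affected counts), and `prevalence`, the realized
#'   disease frequency per generation.
#' @seealso [estimate_lambdas()]
#' @export
simulate_families <- function(model, n_families = 1e5, seed = 1L) {
  stopifnot(inherits(model, "risk_model"))
  if (!is.numeric(n_families) || n_families < 1e3) {
    abort("`n_families` must be at least 1000 for stable tallies.")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  nf <- as.integer(n_families)
  n <- model$n; p <- model$p
  g <- pmin(exp(log_risk(model, 0:(2L * n))), 1)

  # seed locally, restoring whatever RNG state the caller had
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  # transmitted-allele probability by genotype 0,1,2
  trans <- c(0, 0.5, 1)
  # joint per-locus configuration: grandparent g1; parent1 = allele from g1 +
  # allele from the (marginalised) other grandparent; parent2 from HWE
  cfg <- expand.grid(g1 = 0:2, G1 = 0:2, G2 = 0:2)
  p_G1_given_g1 <- function(g1, G1) {
    pa <- trans[g1 + 1] # maternal-path allele
    conv <- c((1 - pa) * (1 - p), pa * (1 - p) + (1 - pa) * p, pa * p)
    conv[G1 + 1]
  }
  cfg$prob <- hwe[cfg$g1 + 1] *
    mapply(p_G1_given_g1, cfg$g1, cfg$G1) *
    hwe[cfg$G2 + 1]

  # sequential conditional-binomial multinomial split, vectorised over families
  counts <- matrix(0L, nrow = nf, ncol = nrow(cfg))
  remaining <- rep.int(n, nf)
  p_left <- 1
  for (j in seq_len(nrow(cfg) - 1L)) {
    pr <- min(1, max(0, cfg$prob[j] / p_left))
    counts[, j] <- rbinom(nf, remaining, pr)
    remaining <- remaining - counts[, j]
    p_left <- p_left - cfg$prob[j]
  }
  counts[, nrow(cfg)] <- remaining

  x_gp <- as.vector(counts %*% cfg$g1)
  x_p1 <- as.vector(counts %*% cfg$G1)
  x_p2 <- as.vector(counts %*% cfg$G2)
  # pooled transmission counts: homozygous loci transmit deterministically,
  # heterozygous loci are fair binomial splits per child
  fix_ <- as.vector(counts %*% ((cfg$G1 == 2) + (cfg$G2 == 2)))
  het1 <- as.vector(counts %*% (cfg$G1 == 1))
  het2 <- as.vector(counts %*% (cfg$G2 == 1))
  child <- function() fix_ + rbinom(nf, het1, 0.5) + rbinom(nf, het2, 0.5)
  x_c1 <- child()
  x_c2 <- child()
  x_tw <- x_c1 # MZ co-twin duplicates sibling 1's genotype

  aff <- function(x) runif(nf) < g[x + 1L]
  a_gp <- aff(x_gp); a_p1 <- aff(x_p1); a_p2 <- aff(x_p2)
  a_c1 <- aff(x_c1); a_c2 <- aff(x_c2); a_tw <- aff(x_tw)

  pair <- function(label, r, u, pro, rel, rel_gen) {
    tibble::tibble(
      pair = label, r = r, u = u,
      n_probands = sum(pro), n_both = sum(pro & rel),
      relative_generation = rel_gen
    )
  }
  tallies <- dplyr::bind_rows(
    pair("MZ",  1,   1,    a_c1, a_tw, "children"),
    pair("Sib", 0.5, 0.25, a_c1, a_c2, "children"),
    pair("OP",  0.5, 0,    a_p1, a_c1, "children"),
    pair("OG",  0.25, 0,   a_gp, a_c1, "children")
  )
  prevalence <- tibble::tibble(
    generation = c("grandparents", "parents", "children"),
    # the co-twin is excluded from the children's prevalence: its genotype
    # duplicates sibling 1 and would double-weight those families
    prevalence = c(mean(a_gp), mean(c(a_p1, a_p2)), mean(c(a_c1, a_c2))),
    n = c(nf, 2L * nf, 2L * nf)
  )
  structure(
    list(model = model, n_families = nf, seed = as.integer(seed),
         tallies = tallies, prevalence = prevalence,
         mean_offspring_count = mean(x_c1),
         sib_count_correlation = stats::cor(x_c1, x_c2)),
    class = "family_sample"
  )
}

#' @export
print.family_sample <- function(x, ...) {
  cat(sprintf("<family_sample: %d families, %s model, seed %d>\n",
              x$n_families, x$model$kind, x$seed))
  print(x$tallies)
  invisible(x)
}

#' Recurrence risk ratios from a simulated family sample
#'
#' For each relative-pair kind, \eqn{\lambda_R} is the disease risk among
#' relatives of affected probands divided by the realized prevalence of the
#' relative's generation (using the realized rather than nominal prevalence
#' cancels finite-sample drift; both are reported). Standard errors are
#' binomial on the conditional risk, divided by the same prevalence.
#'
#' @param sample A [simulate_families()] result.
#' @return An object of class `"relative_risk_estimates"`: `lambdas` (tibble
#'   with `pair`, `lambda`, `se`, counts), `h2_broad` (broad-sense risk-scale
#'   heritability from \eqn{\lambda_{MZ}}), `h2_narrow` (narrow-sense, from
#'   \eqn{4(\lambda_{OG}-1)K/(1-K)}), and the realized `prevalence` table.
#'   `tidy()` returns the lambda table, `glance()` a one-row summary.
#' @examples
#' m <- risk_model("probit", K = 0.05, n = 100, p = 0.3, h2l = 0.5)
#' fs <- simulate_families(m, n_families = 5e3, seed = 7)
#' est <- estimate_lambdas(fs)
#' tidy(est)
#' @export
estimate_lambdas <- function(sample) {
  stopifnot(inherits(sample, "family_sample"))
  tl <- sample$tallies
  if (any(tl$n_probands == 0)) {
    abort("no affected probands for at least one pair kind; increase `n_families`.")
  }
  prev <- setNames(sample$prevalence$prevalence, sample$prevalence$generation)
  lam <- tl |>
    dplyr::mutate(
      risk_given_proband = .data$n_both / .data$n_probands,
      prevalence_ref = prev[.data$relative_generation],
      lambda = .data$risk_given_proband / .data$prevalence_ref,
      se = sqrt(.data$risk_given_proband * (1 - .data$risk_given_proband) /
                  .data$n_probands) / .data$prevalence_ref
    )
  K <- sample$model$K
  # sampling noise can push estimates just past their theoretical bounds;
  # clamp before converting to heritabilities
  lmz <- min(max(lam$lambda[lam$pair == "MZ"], 1), 1 / K)
  log_ <- max(lam$lambda[lam$pair == "OG"], 1)
  structure(
    list(
      lambdas = lam,
      h2_broad = h2_01_from_lambda_mz(lmz, K),
      h2_narrow = narrow_h2_from_lambda_og(log_, K),
      prevalence = sample$prevalence,
      model = sample$model
    ),
    class = "relative_risk_estimates"
  )
}

#' @export
print.relative_risk_estimates <- function(x, ...) {
  cat("<relative_risk_estimates>\n")
  print(dplyr::select(x$lambdas, "pair", "lambda", "se", "n_probands", "n_both"))
  cat(sprintf("  h2_01 broad (from lambda_MZ): %.3f   narrow (from lambda_OG): %.3f\n",
              x$h2_broad, x$h2_narrow))
  invisible(x)
}

#' @rdname estimate_lambdas
#' @param x A `relative_risk_estimates` object.
#' @param ... Unused.
#' @method tidy relative_risk_estimates
#' @export
tidy.relative_risk_estimates <- function(x, ...) x$lambdas

#' @rdname estimate_lambdas
#' @method glance relative_risk_estimates
#' @export
glance.relative_risk_estimates <- function(x, ...) {
  lam <- setNames(x$lambdas$lambda, x$lambdas$pair)
  tibble::tibble(
    lambda_mz = lam[["MZ"]], lambda_sib = lam[["Sib"]],
    lambda_op = lam[["OP"]], lambda_og = lam[["OG"]],
    h2_broad = x$h2_broad, h2_narrow = x$h2_narrow,
    prevalence_children = x$prevalence$prevalence[
      x$prevalence$generation == "children"]
  )
}

#' Broad-sense risk-scale heritability from the MZ recurrence risk
#'
#' Under the variance-component identity for MZ twins,
#' \eqn{Var_G = (\lambda_{MZ} - 1) K^2}, so
#' \deqn{H^2_{01} = (\lambda_{MZ} - 1) K / (1 - K).}
#'
#' @param lambda_mz MZ recurrence risk ratio, in \[1, 1/K\].
#' @param K Disease prevalence.
#' @return Heritability on the 0/1 risk scale.
#' @examples
#' h2_01_from_lambda_mz(600, 0.001) # 0.60
#' @export
h2_01_from_lambda_mz <- function(lambda_mz, K) {
  check_prob(K, "K")
  if (any(lambda_mz < 1, na.rm = TRUE)) abort("`lambda_mz` must be >= 1.")
  if (any(lambda_mz > 1 / K + 1e-9, na.rm = TRUE)) {
    abort(sprintf("`lambda_mz` cannot exceed 1/K = %g.", 1 / K))
  }
  (lambda_mz - 1) * K / (1 - K)
}

#' Narrow-sense risk-scale heritability from the grandparent-grandchild risk
#'
#' Grandparent-grandchild pairs share only additive variance (coefficient
#' 1/4), so \eqn{h^2_{01} \approx 4 (\lambda_{OG} - 1) K / (1 - K)}, an
#' estimate less contaminated by dominance than the parent-offspring
#' analogue.
#'
#' @param lambda_og Grandparent-grandchild recurrence risk ratio (\eqn{\ge 1}).
#' @param K Disease prevalence.
#' @return Narrow-sense heritability on the risk scale.
#' @export
narrow_h2_from_lambda_og <- function(lambda_og, K) {
  check_prob(K, "K")
  if (any(lambda_og < 1, na.rm = TRUE)) abort("`lambda_og` must be >= 1.")
  4 * (lambda_og - 1) * K / (1 - K)
}

#' Diagnostic ratios of recurrence risks
#'
#' Three ratios used to interrogate the architecture of a disease:
#' `mz_over_sib_sq` (\eqn{\lambda_{MZ}/\lambda_{Sib}^2}; equals 1 under an
#' unconstrained multiplicative model), `excess_ratio`
#' (\eqn{(\lambda_{MZ}-1)/(\lambda_{Sib}-1)}; 2 under purely additive
#' variance, larger when epistatic variance on the risk scale matters) and,
#' when \eqn{\lambda_{OP}} is supplied, `dominance_ratio`
#' (\eqn{(\lambda_{Sib}-1)/(\lambda_{OP}-1)}; above 1 indicates dominance).
#'
#' @param lambda_mz,lambda_sib,lambda_op Recurrence risk ratios (\eqn{\ge 1});
#'   `lambda_op` optional.
#' @return A one-row tibble with the three ratios (`NA` where undefined,
#'   e.g. `excess_ratio` at \eqn{\lambda_{Sib} = 1}).
#' @examples
#' ratio_diagnostics(52.1, 8.6, 10) # schizophrenia-like
#' @export
ratio_diagnostics <- function(lambda_mz, lambda_sib, lambda_op = NULL) {
  if (any(c(lambda_mz, lambda_sib, lambda_op) < 1, na.rm = TRUE)) {
    abort("lambda values must be >= 1.")
  }
  tibble::tibble(
    mz_over_sib_sq = lambda_mz / lambda_sib^2,
    excess_ratio = ifelse(lambda_sib > 1,
                          (lambda_mz - 1) / (lambda_sib - 1), NA_real_),
    dominance_ratio = if (is.null(lambda_op)) {
      NA_real_
    } else {
      ifelse(!is.na(lambda_op) & lambda_op > 1,
             (lambda_sib - 1) / (lambda_op - 1), NA_real_)
    }
  )
}
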