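test_that("analytic MZ recurrence matches the null, printed and bounded cases", {
  null <- risk_model("odds", K = 0.1, n = 50, p = 0.2, tau = 1)
  expect_equal(lambda_mz_exact(null), 1, tolerance = 1e-10)

  bs <- benchmark_set(K = 0.01, n = 1000, p = 0.3, h2l = 0.5)
  expect_equal(lambda_mz_exact(bs$models$probit), 13.0, tolerance = 0.02)
  expect_equal(lambda_mz_exact(bs$models$crisch), 52, tolerance = 0.02)
  expect_equal(lambda_mz_exact(bs$models$odds), 35, tolerance = 0.02)
  # lambda_MZ can never exceed 1/K for proper risk functions
  for (kind in c("crisch", "odds", "probit")) {
    expect_lte(lambda_mz_exact(bs$models[[kind]]), 1 / 0.01)
  }
})

test_that("analytic sibling recurrence agrees with brute-force enumeration", {
  for (kind in c("crisch", "odds", "probit")) {
    for (n in 1:3) {
      m <- if (kind == "probit") {
        risk_model(kind, K = 0.2, n = n, p = 0.3, h2l = 0.5)
      } else {
        risk_model(kind, K = 0.2, n = n, p = 0.3, tau = 2.5)
      }
      bf <- brute_force_lambdas(m)
      expect_equal(lambda_sib_exact(m), bf$lambda_sib, tolerance = 1e-9,
                   ignore_attr = TRUE, info = paste(kind, n))
      expect_equal(lambda_mz_exact(m), bf$lambda_mz, tolerance = 1e-9,
                   info = paste(kind, n))
    }
  }
})

test_that("family simulation conserves Mendelian structure", {
  m <- risk_model("crisch", K = 0.05, n = 100, p = 0.3, tau = 1.3)
  fs <- simulate_families(m, n_families = 2e4, seed = 31)
  # offspring mean allele count = 2np, within 3 SEs
  se_mean <- sqrt(2 * 100 * 0.3 * 0.7 / 2e4)
  expect_lt(abs(fs$mean_offspring_count - 60), 3 * se_mean)
  # sib genotype correlation ~ 1/2
  expect_lt(abs(fs$sib_count_correlation - 0.5), 3 / sqrt(2e4))
  # realized prevalences near K in every generation
  expect_true(all(abs(fs$prevalence$prevalence - 0.05) <
                    5 * sqrt(0.05 * 0.95 / fs$prevalence$n)))
  expect_error(simulate_families(m, n_families = 10), "1000")
})

test_that("simulation is reproducible under a fixed seed and leaves the RNG alone", {
  m <- risk_model("odds", K = 0.1, n = 50, p = 0.2, tau = 1.5)
  set.seed(777)
  before <- runif(1)
  set.seed(777)
  fs1 <- simulate_families(m, n_families = 5e3, seed = 9)
  after <- runif(1)
  expect_identical(before, after) # caller RNG stream untouched
  fs2 <- simulate_families(m, n_families = 5e3, seed = 9)
  expect_identical(fs1$tallies, fs2$tallies)
  fs3 <- simulate_families(m, n_families = 5e3, seed = 10)
  expect_false(identical(fs1$tallies, fs3$tallies))
})

test_that("simulated recurrence risks agree with analytic and enumeration oracles", {
  # null model: every lambda is 1
  null <- risk_model("crisch", K = 0.2, n = 20, p = 0.3, tau = 1)
  sl <- sim_lambdas(null, 3e4, seed = 21)
  for (pr in c("MZ", "Sib", "OP", "OG")) {
    expect_lt(abs(sl$lambda[[pr]] - 1), 3 * sl$se[[pr]])
  }

  # moderate probit model: MZ and Sib against the exact sums
  pm <- risk_model("probit", K = 0.05, n = 100, p = 0.3, h2l = 0.6)
  sl <- sim_lambdas(pm, 1e5, seed = 22)
  expect_lt(abs(sl$lambda[["MZ"]] - lambda_mz_exact(pm)), 3 * sl$se[["MZ"]])
  expect_lt(abs(sl$lambda[["Sib"]] - lambda_sib_exact(pm)), 3 * sl$se[["Sib"]])
  # ordering MZ >= Sib >= OP within noise
  expect_gt(sl$lambda[["MZ"]] + 3 * sl$se[["MZ"]], sl$lambda[["Sib"]])
  expect_gt(sl$lambda[["Sib"]] + 3 * (sl$se[["Sib"]] + sl$se[["OP"]]),
            sl$lambda[["OP"]])
  expect_lte(sl$lambda[["MZ"]], 1 / sl$est$prevalence$prevalence[3])

  # tiny-n case against the brute-force pedigree enumeration
  m2 <- risk_model("crisch", K = 0.2, n = 2, p = 0.3, tau = 2.5)
  bf <- brute_force_lambdas(m2)
  sl2 <- sim_lambdas(m2, 1e5, seed = 23)
  expect_lt(abs(sl2$lambda[["Sib"]] - bf$lambda_sib), 3 * sl2$se[["Sib"]])
  expect_lt(abs(sl2$lambda[["OP"]] - bf$lambda_op), 3 * sl2$se[["OP"]])
})

test_that("MZ-vs-sib-squared ratio separates low from high heritability", {
  # near-multiplicative at small h2l
  lo <- benchmark_set(K = 0.01, n = 200, p = 0.3, h2l = 0.1)$models$probit
  expect_equal(lambda_mz_exact(lo) / lambda_sib_exact(lo)^2, 1,
               tolerance = 0.05, ignore_attr = TRUE)
  # clearly below 1 for rare disease with substantial heritability
  hi <- benchmark_set(K = 0.01, n = 200, p = 0.3, h2l = 0.5)$models$probit
  sl <- sim_lambdas(hi, 1e5, seed = 41)
  ratio <- sl$lambda[["MZ"]] / sl$lambda[["Sib"]]^2
  se_ratio <- ratio * sqrt((sl$se[["MZ"]] / sl$lambda[["MZ"]])^2 +
                             (2 * sl$se[["Sib"]] / sl$lambda[["Sib"]])^2)
  expect_lt(ratio + 3 * se_ratio, 1)
})

test_that("effect sizes round-trip through simulated MZ recurrence estimates", {
  true_tau <- 1.4
  m <- risk_model("crisch", K = 0.05, n = 100, p = 0.3, tau = true_tau)
  sl <- sim_lambdas(m, 1e5, seed = 55)
  est_tau <- solve_effect_for_lambda("crisch", K = 0.05, n = 100, p = 0.3,
                                     target_lambda_mz = sl$lambda[["MZ"]])
  # propagate the MZ sampling error through the inverse map numerically
  d_tau <- diff(vapply(sl$lambda[["MZ"]] + c(0, sl$se[["MZ"]]), function(l) {
    unname(solve_effect_for_lambda("crisch", 0.05, 100, 0.3,
                                   target_lambda_mz = l))
  }, numeric(1)))
  expect_lt(abs(unname(est_tau) - true_tau), 2 * abs(d_tau))
})

test_that("lambda-based heritability estimators reproduce the reference values", {
  expect_equal(round(h2_01_from_lambda_mz(600, 0.001), 2), 0.60)
  expect_equal(round(h2_01_from_lambda_mz(630, 0.001), 2), 0.63)
  expect_equal(h2_01_from_lambda_mz(1, 0.1), 0)
  expect_error(h2_01_from_lambda_mz(20, 0.1), "1/K")
  expect_equal(narrow_h2_from_lambda_og(1, 0.3), 0)
  expect_error(narrow_h2_from_lambda_og(0.5, 0.3), ">= 1")
})

test_that("recurrence-ratio diagnostics reproduce the reference table values", {
  d <- ratio_diagnostics(52.1, 8.6, 10)
  expect_equal(round(d$excess_ratio, 1), 6.7)
  expect_equal(round(d$mz_over_sib_sq, 1), 0.7)
  expect_equal(round(d$dominance_ratio, 1), 0.8)
  d2 <- ratio_diagnostics(60, 7)
  expect_equal(round(d2$mz_over_sib_sq, 1), 1.2)
  expect_equal(round(d2$excess_ratio, 0), 10)
  expect_true(is.na(d2$dominance_ratio))
  # multiplicative identity reference point
  expect_equal(ratio_diagnostics(25, 5)$mz_over_sib_sq, 1)
  # undefined excess ratio at lambda_sib = 1
  expect_true(is.na(ratio_diagnostics(2, 1)$excess_ratio))
  expect_error(ratio_diagnostics(0.5, 2), ">= 1")
})
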