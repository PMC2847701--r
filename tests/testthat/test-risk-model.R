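test_that("unconstrained multiplicative baseline matches its closed form", {
  # p = 0: no risk alleles anywhere, baseline is the prevalence itself
  expect_equal(risch_baseline(K = 0.1, n = 1, p = 0, tau = 2), 0.1)
  # single-locus case, hand-checkable
  expect_equal(risch_baseline(K = 0.01, n = 1, p = 0.1, tau = 1.05),
               0.01 / 1.005^2, tolerance = 1e-12)
  # deep-underflow regime; reference value from 40-digit arithmetic
  expect_equal(risch_baseline(K = 0.1, n = 1000, p = 0.1, tau = 1.1),
               2.276420221040085e-10, tolerance = 1e-12)
  expect_error(risch_baseline(0.1, 10, 0.1, tau = -1), "positive")
})

test_that("every model kind calibrates to the prevalence on the exact support", {
  cases <- tidyr::expand_grid(
    kind = c("risch", "crisch", "odds", "probit"),
    K = c(0.3, 0.05, 0.005),
    n = c(5, 80),
    p = c(0.1, 0.45)
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    m <- if (cs$kind == "probit") {
      risk_model("probit", K = cs$K, n = cs$n, p = cs$p, h2l = 0.4)
    } else {
      risk_model(cs$kind, K = cs$K, n = cs$n, p = cs$p, tau = 1.3)
    }
    x <- 0:(2 * cs$n)
    eg <- sum(dbinom(x, 2 * cs$n, cs$p) * risk(m, x))
    expect_lt(abs(eg - cs$K), 1e-8 * cs$K)
    expect_lt(m$residual, 1e-8 * cs$K)
    if (cs$kind != "risch") {
      g <- risk(m, x)
      expect_true(all(g >= 0 & g <= 1))
    }
  }
})

test_that("constrained model reduces to the unconstrained one when no risk caps", {
  # small effect, low prevalence: max risk stays below 1 across the support
  expect_lt(risch_baseline(0.001, 100, 0.3, 1.05) * 1.05^200, 1)
  expect_identical(crisch_calibrate(0.001, 100, 0.3, 1.05),
                   risch_baseline(0.001, 100, 0.3, 1.05))
  # capping active: the constrained baseline must rise above the closed form
  f_c <- crisch_calibrate(0.1, 1000, 0.1, 1.1)
  f_u <- risch_baseline(0.1, 1000, 0.1, 1.1)
  expect_gt(f_c, f_u)
  # and the capped expectation still hits K
  x <- 0:2000
  expect_equal(sum(dbinom(x, 2000, 0.1) * pmin(f_c * 1.1^x, 1)), 0.1,
               tolerance = 1e-9)
})

test_that("odds model null case and calibration identity", {
  expect_equal(odds_calibrate(0.3, 50, 0.2, tau = 1), 0.3 / 0.7)
  C <- odds_calibrate(0.5, 10, 0.5, tau = 1.1)
  x <- 0:20
  g <- 1.1^x * C / (1 + 1.1^x * C)
  expect_equal(sum(dbinom(x, 20, 0.5) * g), 0.5, tolerance = 1e-9)
  # solved at sharper parameters too
  C2 <- odds_calibrate(0.01, 1000, 0.3, tau = 1.2)
  m <- risk_model("odds", K = 0.01, n = 1000, p = 0.3, tau = 1.2)
  expect_equal(unname(m$baseline[["C_n"]]), C2)
})

test_that("probit parameters: nominal threshold, liability effect and null limit", {
  par <- probit_params(K = 0.05, n = 100, p = 0.3, h2l = 0.3)
  expect_equal(round(attr(par, "t_nominal"), 3), 1.645)
  # calibrated threshold stays within a hair of the nominal quantile
  expect_lt(abs(par[["t"]] - attr(par, "t_nominal")), 0.05)
  expect_equal(unname(probit_params(0.01, 1000, 0.3, 0.5)[["a"]]),
               sqrt(0.5 / 420), tolerance = 1e-12)
  # h2l -> 0: no genetic effect, flat risk function equal to K
  m0 <- risk_model("probit", K = 0.07, n = 50, p = 0.2, h2l = 0)
  expect_equal(unname(m0$baseline[["a"]]), 0)
  expect_equal(risk(m0, c(0, 10, 100)), rep(0.07, 3), tolerance = 1e-12)
  expect_error(probit_params(0.05, 100, 0.3, h2l = 1.2), "0, 1")
})

test_that("risk function values and local slope of the probit model", {
  m <- risk_model("crisch", K = 0.01, n = 1000, p = 0.3, tau = 1.2)
  expect_equal(risk(m, 0), unname(m$baseline[["f_n"]]))
  pm <- risk_model("probit", K = 0.01, n = 1000, p = 0.3, h2l = 0.5)
  # risk at the mean genotype: liability exceedance of t in residual sd units
  expect_equal(risk(pm, 600), pnorm(-pm$baseline[["t"]] / sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(risk(pm, 600), 5.0e-4, tolerance = 0.05)
  # one-allele slope at the mean ~ 1.19
  expect_equal(risk(pm, 601) / risk(pm, 600), 1.19, tolerance = 0.005)
  expect_error(risk(pm, 2001), "0\\.\\.2000")
  expect_error(risk(pm, -1), "0\\.\\.2000")
})

test_that("risk functions are nondecreasing for positive effects and flat under the null", {
  n <- 40; x <- 0:80
  for (kind in c("risch", "crisch", "odds", "probit")) {
    m <- if (kind == "probit") {
      risk_model(kind, K = 0.05, n = n, p = 0.25, h2l = 0.6)
    } else {
      risk_model(kind, K = 0.05, n = n, p = 0.25, tau = 1.4)
    }
    expect_true(all(diff(risk(m, x)) >= 0), info = kind)
    m_null <- if (kind == "probit") {
      risk_model(kind, K = 0.05, n = n, p = 0.25, h2l = 0)
    } else {
      risk_model(kind, K = 0.05, n = n, p = 0.25, tau = 1)
    }
    expect_equal(risk(m_null, x), rep(0.05, length(x)), tolerance = 1e-10,
                 info = kind)
  }
})

test_that("unconstrained-model moments match their closed forms at small n", {
  for (n in c(3, 10, 20)) {
    K <- 0.02; p <- 0.2; tau <- 1.5
    m <- risk_model("risch", K = K, n = n, p = p, tau = tau)
    x <- 0:(2 * n)
    q <- dbinom(x, 2 * n, p)
    g <- risk(m, x)
    expect_equal(sum(q * g), K, tolerance = 1e-10)
    eg2_closed <- K^2 * (1 + p * (tau^2 - 1))^(2 * n) /
      (1 + p * (tau - 1))^(4 * n)
    expect_equal(sum(q * g^2), eg2_closed, tolerance = 1e-10)
  }
})

test_that("model constructor rejects ill-formed configurations", {
  expect_error(risk_model("crisch", K = 0, n = 10, p = 0.3, tau = 1.2), "(0, 1)")
  expect_error(risk_model("crisch", K = 0.1, n = 0, p = 0.3, tau = 1.2), "positive integer")
  expect_error(risk_model("crisch", K = 0.1, n = 10, p = 0.3), "tau")
  expect_error(risk_model("probit", K = 0.1, n = 10, p = 0.3, tau = 1.2), "h2l")
  expect_error(risk_model("probit", K = 0.1, n = 10, p = 0.3, h2l = 1), "\\[0, 1\\)")
  expect_error(risk_model("crisch", K = 0.1, n = 10, p = 0.3, tau = 1.2, h2l = 0.5),
               "probit")
})

test_that("tidy and glance expose the calibration as one-row tibbles", {
  m <- risk_model("odds", K = 0.05, n = 30, p = 0.2, tau = 1.3)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_identical(td$effect_type, "tau")
  gl <- glance(m)
  expect_true(all(c("h2_01", "lambda_mz", "residual") %in% names(gl)))
  expect_gte(gl$lambda_mz, 1)
})
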