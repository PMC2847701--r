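# Brute-force recurrence-risk oracles for tiny locus numbers (n <= 3), by
# exhaustive enumeration of both parents' per-locus genotypes. Deliberately
# naive (O(9^n) parent states) and fully independent of the package's
# exchangeable-locus machinery.

# per-locus pmf of the allele count a child receives from parents with
# genotypes (gm, gf): sum of two independent Mendelian transmissions
child_locus_pmf <- function(gm, gf) {
  pm <- gm / 2; pf <- gf / 2
  c((1 - pm) * (1 - pf),
    pm * (1 - pf) + (1 - pm) * pf,
    pm * pf)
}

brute_force_lambdas <- function(model) {
  n <- model$n; p <- model$p; K <- model$K
  g <- pmin(risk(model, 0:(2 * n)), 1)
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  geno_vecs <- as.matrix(expand.grid(rep(list(0:2), n)))
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      idx <- i + seq_along(b) - 1
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  both_sib <- 0; both_op <- 0
  for (i in seq_len(nrow(geno_vecs))) {
    gm <- geno_vecs[i, ]
    pmother <- prod(hwe[gm + 1])
    xm <- sum(gm)
    for (j in seq_len(nrow(geno_vecs))) {
      gf <- geno_vecs[j, ]
      w <- pmother * prod(hwe[gf + 1])
      pmf <- 1
      for (l in seq_len(n)) pmf <- conv(pmf, child_locus_pmf(gm[l], gf[l]))
      m <- sum(pmf * g[seq_along(pmf)])      # E[g(child) | parents]
      both_sib <- both_sib + w * m^2         # sibs conditionally independent
      both_op <- both_op + w * g[xm + 1] * m # parent (mother) and child
    }
  }
  q <- dbinom(0:(2 * n), 2 * n, p)
  list(lambda_sib = both_sib / K^2,
       lambda_op = both_op / K^2,
       lambda_mz = sum(q * g^2) / K^2)
}

# convenience: simulated lambda estimates with their SEs as a named list
sim_lambdas <- function(model, n_families, seed) {
  est <- estimate_lambdas(simulate_families(model, n_families, seed))
  lam <- est$lambdas
  list(lambda = setNames(lam$lambda, lam$pair),
       se = setNames(lam$se, lam$pair),
       est = est)
}
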