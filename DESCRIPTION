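Package: multirisk
Title: Multi-Locus Models of Genetic Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates and compares four multi-locus models of genetic disease
    risk (unconstrained multiplicative, constrained multiplicative, Odds/logit,
    and Probit/liability-threshold) against a target disease prevalence.
    Computes population risk functions and broad-sense heritability on the
    disease risk scale over the exact binomial distribution of risk-allele
    counts, recurrence risks to relatives (monozygotic twins, siblings,
    parent-offspring, grandparent-grandchild) both analytically and by
    Mendelian gene-dropping simulation of three-generation families, and the
    scale conversions linking per-allele relative risks, odds ratios and
    liability-scale heritability. Ships a reference table of observed
    prevalences and recurrence risks for common complex diseases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
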