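---
title: "Multi-locus models of genetic disease risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-locus models of genetic disease risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multirisk)
```

## The modelling problem

The genetic epidemiology of a complex disease is summarised by its
prevalence $K$ and by recurrence risk ratios $\lambda_R = K_R/K$: the risk
of disease in relatives of type $R$ of an affected proband, relative to the
population. Because an MZ co-twin shares the whole genotype,
$K_{MZ} \le 1$ forces $\lambda_{MZ} \le 1/K$, and $\lambda_{MZ}$ bounds the
total genetic contribution. Association studies describe the same disease
bottom-up: risk alleles of frequency $p$ with per-allele relative risk
$\tau$ (or odds factor $\gamma$) at each of $n$ loci. A *combining rule* is
needed to connect the two descriptions, and this package implements and
compares the four standard choices.

Throughout, loci are exchangeable (equal $p$ and equal effect), independent
and in Hardy–Weinberg equilibrium, so an individual is fully summarised by
the risk-allele count $x \sim \mathrm{Binomial}(2n, p)$ with probabilities
$q_x$. Mating is random, fertility unaffected by disease, and relatives
resemble each other only through their genes — no shared environment. The
risk function $g_x = P(\text{disease} \mid x)$ must satisfy the calibration
identity $\sum_x q_x g_x = K$.

## The four risk functions

* **Unconstrained multiplicative** (`risch`): $g_x = f_n \tau^x$ with the
  closed form $f_n = K/(1+p(\tau-1))^{2n}$. Mathematically convenient —
  moments are available in closed form — but nothing stops $g_x$ exceeding
  1. This is not a blemish to hide: quantifying the damage those
  "impossible risks" do is one of the package's purposes.
* **Constrained multiplicative** (`crisch`): $g_x = \min(f_n \tau^x, 1)$.
  Capping removes probability mass, so $f_n$ must be re-solved numerically
  to keep $E(g) = K$; the constrained $f_n$ always exceeds the closed form.
* **Odds / logit** (`odds`): $g_x/(1-g_x) = \gamma^x C_n$. $C_n$ is the
  baseline odds of an all-wild-type individual and has no closed form; it
  is solved numerically. (Writing the risk as $O/(1+O)$ with
  $O = \gamma^x C_n$ keeps $g_x$ in $[0,1]$ by construction.)
* **Probit / liability threshold** (`probit`): liability is a unit-variance
  normal; disease is liability above a threshold $t$. Genotype contributes
  $u_x = (x - 2np)\,a$ with $a = \sqrt{h^2_l / (2np(1-p))}$, chosen so the
  genetic variance on the liability scale equals $h^2_l$; the residual has
  variance $1 - h^2_l$, giving
  $g_x = \Phi\!\big((u_x - t)/\sqrt{1-h^2_l}\big)$.

### Numerical conventions

All calibrations are bracketed root solves with exact analytic brackets
(`uniroot` at tolerance $\approx 10^{-12}$, ≤ 200 iterations), on the *log*
of the baseline constant for the multiplicative and odds models so that
deep-underflow baselines (e.g. $f_n \sim 10^{-52}$ at $n = 1000$,
$\tau = 1.2$) remain representable. Risk functions are evaluated through
$\log g_x$ everywhere, and population sums use log-space accumulation, so
the unconstrained model's enormous tail terms ($q_x g_x^2$ with
$g_x \gg 1$ but $q_x$ astronomically small) are summed without overflow.
Sums always run over the full support $0..2n$; no normal approximation or
fixed-width truncation is used. A constructed model whose residual
$|E(g) - K|$ exceeds $10^{-8} K$ is an error, never a warning.

Two conventions deserve explicit statement:

* **Probit threshold.** The threshold is initialised at the normal quantile
  $\Phi^{-1}(1-K)$ and then adjusted numerically so that the *discrete*
  mixture $\sum_x q_x g_x$ equals $K$ exactly — the liability model's own
  definition of $t$ ("the proportion exceeding the threshold equals the
  prevalence") applied to the finite-$n$ genotype distribution rather than
  to its normal limit. The adjustment is $O(1/n)$ (at $K=0.01$, $n=1000$,
  $p=0.3$, $h^2_l=0.5$: 2.3314 vs the nominal 2.3263) but it is what makes
  all four models satisfy the same calibration identity; the nominal
  quantile is kept in the model object as `t_nominal`.
* **Breakdown threshold.** `impossible_risk_report()` reports the *largest
  integer* $x$ with $f_n\tau^x \le 1$ (i.e. $\lfloor -\ln f_n / \ln\tau
  \rfloor$, with a floating-point guard), so "risk exceeds 1 above
  $x = 232$" reads the way a geneticist would say it. The population mass
  above the threshold comes from the exact binomial survival function.

```{r breakdown}
m <- risk_model("risch", K = 0.1, n = 1000, p = 0.1, tau = 1.1)
impossible_risk_report(m)
```

For this canonical case the exact Eq-style heritability of the
unconstrained model is `r round(heritability_risk_scale(risk_model("risch",
K = 0.1, n = 1000, p = 0.1, tau = 1.1)), 3)` (the closed-form second moment
agrees to $10^{-9}$), and capping the impossible risks drops it below half
of that. `heritability_risk_scale()` also accepts `truncate_sd` for
sensitivity analysis on a clipped support, because summaries of this model
are sensitive to how much of the far tail one admits; the default is always
the full exact support.

## Benchmarking models against each other

Feeding the *same* $\tau$ to models with different combining rules is not
automatically fair. The package's comparison procedure therefore anchors on
the probit model: from $(K, n, p, h^2_l)$ it computes the benchmark effect
$\tau = g_{2np+1}/g_{2np}$ — the relative risk of one extra allele at the
population mean genotype — and feeds that $\tau$ (as $\gamma$ for the odds
model) to the other three. When $2np$ is not an integer the anchor pair is
$(\mathrm{round}(2np), \mathrm{round}(2np)+1)$: the benchmark is a local
slope at the mean, and rounding keeps it on the integer support.

```{r benchmark}
bs <- benchmark_set(K = 0.01, n = 1000, p = 0.3, h2l = 0.5)
tidy(bs)
```

The spread of `h2_01` and `lambda_mz` across rows is the substantive
result: at equal prevalence and equal single-allele effect, the constrained
multiplicative model concentrates far more variance on the risk scale than
the liability model, with the odds model in between.

Holding $(K, h^2_l)$ fixed, the risk-scale heritability depends only
weakly on how the liability variance is built up from loci. Measured over
$n \in \{100, 1000, 10000\}$, $p \in \{0.1, 0.3\}$ (keeping cells with
benchmark $\tau < 2$, the regime the models are intended for), the spread
of $H^2_{01}$ within a model is $\le 0.005$ at $h^2_l = 0.1$ for all
prevalences tested, growing to roughly $0.01$–$0.03$ at
$h^2_l \in \{0.5, 0.7\}$ — always an order of magnitude below the
separation *between* models. The test suite asserts the tight $\pm 0.01$
band at $(K = 0.01, h^2_l = 0.1)$ and the qualitative version (spread far
below between-model separation) at $h^2_l = 0.5$.

`solve_effect_for_lambda()` inverts the map: given a target
$\lambda_{MZ} \in (1, 1/K)$ it finds the $\tau$ (or $h^2_l$) whose
calibrated model reproduces it, by bisection on the effect; $\lambda_{MZ}$
is monotone in the effect for every kind. Only $\lambda_{MZ}$ is targeted —
it is analytic and fast; joint $(\lambda_{MZ}, \lambda_{Sib})$ fitting is
deliberately not attempted because the two are nearly collinear under any
one model and the inverse problem becomes ill-conditioned.

## Recurrence risks to relatives

Two quantities are exact sums. For MZ twins,
$\lambda_{MZ} = \sum_x q_x g_x^2 / K^2$. For siblings, exchangeability
gives a compact exact route: across the two parents' $2n$ transmitting
loci, let $F$ count loci where the transmitting parent is homozygous for
the risk allele and $H$ where it is heterozygous; then
$(F, H) \sim \mathrm{Multinomial}(2n;\, p^2,\, 2p(1-p),\, (1-p)^2)$ and,
conditional on $(F, H)$, each child's count is independently
$F + \mathrm{Binomial}(H, 1/2)$. Hence
$\lambda_{Sib} = E\big[\,m(F,H)^2\,\big]/K^2$ with
$m(F,H) = E[g_{F+\mathrm{Binomial}(H,1/2)}]$. The double sum drops $(F,H)$
cells below $10^{-12}$ relative mass (a machine-precision cutoff, reported
if it ever bites — not a distributional approximation).

Everything else comes from the gene-dropping simulation
(`simulate_families()`). Each family contains a focal grandparent, two
parents (one of them the grandparent's child), two full siblings, and an MZ
co-twin duplicating the first sibling's genotype; disease status is
Bernoulli($g_x$) independently per individual. The family structure — two
sibs plus a co-twin and one tracked grandparental line — is the minimal
pedigree yielding all four relative types ($\lambda_{MZ}$, $\lambda_{Sib}$,
$\lambda_{OP}$, $\lambda_{OG}$) from one pass, and is an assumption of this
package, not a fact about any particular study design.

Rather than per-locus arrays, each family draws one multinomial split of
its $n$ loci over the 27 joint (grandparent, parent 1, parent 2) genotype
configurations; parent and grandparent allele counts are then linear
functions of the 27 counts, and transmissions to children pool into two
Binomial$(\cdot, 1/2)$ draws per child (heterozygous loci) plus a
deterministic part (homozygous loci). For independent exchangeable loci
this is *distributionally exact*, and it is $O(1)$ in $n$ per family, so
$10^6$ families at $n = 1000$ take seconds. Correctness is pinned three
ways in the test suite: against brute-force enumeration of all parental
genotype and transmission combinations at $n \le 3$, against the analytic
$\lambda_{MZ}$ and $\lambda_{Sib}$ sums at realistic $n$, and through
Mendelian conservation checks (offspring mean $2np$, sib genotype
correlation $1/2$).

Estimates divide by the *realized* prevalence of the relative's generation
(children's prevalence computed from the two genuine siblings; the co-twin
is excluded as a genotype duplicate), which cancels finite-sample drift;
nominal and realized prevalences are both reported. Standard errors are
binomial on the conditional risk of the relative given an affected proband;
the denominator's sampling noise is ignored, which is conservative at the
sample sizes used. Default `n_families = 1e5` gives SEs of roughly 1 on a
$\lambda_{MZ}$ of 50 (always reported, never hidden); the acceptance script
uses $2 \times 10^6$ families so that integer-rounded summaries are stable
across seeds. A single integer seed governs the whole sample; the draw
order is fixed, runs are bit-reproducible on one platform, and the caller's
RNG state is restored afterwards.

From the estimates, two heritability summaries:
$H^2_{01} = (\lambda_{MZ}-1)K/(1-K)$ (broad sense — MZ covariance is the
full genetic variance on the risk scale) and
$h^2_{01} \approx 4(\lambda_{OG}-1)K/(1-K)$ (narrow sense —
grandparent–grandchild pairs share additive variance with coefficient 1/4
and no dominance). The latter still carries a small upward bias from
higher-order epistatic terms (coefficient $(1/4)^k$ for $k$-locus additive
interactions), visible in the tests as a systematic few-percent excess over
the Robertson prediction at high $h^2_l$; the Robertson cross-checks are
therefore asserted at small $h^2_l$, where the contamination vanishes, and
at $K = 0.5$, where the risk function is nearly linear around the mean.

## Scale conversions

`liability_quantities()` supplies the threshold machinery ($t$, the density
$z$ at the threshold, the affected-group mean liability $i = z/K$).
`robertson_h2_01()` converts liability-scale heritability to the risk
scale, $h^2_{01} = h^2_l\, z^2/(K(1-K))$, maximal at $2/\pi \approx 0.64$
for $K = 0.5$, $h^2_l = 1$. `single_locus_or()` gives the odds ratios
implied by one multiplicative-risk locus with baseline penetrance solved
from $E(g) = K$ at $n = 1$; the diagnostic $OR_{hom}/OR_{het}^2$ equals 1
exactly under multiplicative odds and exceeds 1 under multiplicative risk
(1.13 at $K{=}0.1, p{=}0.1, \tau{=}2$; 1.00003 at
$K{=}0.01, p{=}0.1, \tau{=}1.05$ — at small penetrance the distinction is
practically invisible). `marginal_tau_probit()` separates the effect of an
allele *conditional on the mean genetic background*
($g_{2np+1}/g_{2np}$) from the *marginal* effect when the one locus is
fitted alone and all others become residual variance,
$\Phi(a-t)/\Phi(-t)$; the marginal effect is always the smaller.
`liability_h2_from_mz_concordance()` inverts a shared-liability bivariate
normal model for MZ twins by one-dimensional quadrature; it is a
descriptive helper, with no claim about sampling properties.

## The observed-disease table

`load_table1()` ships prevalences and recurrence risks for 15 common
complex diseases together with the derived columns as printed in the source
compilation (`*_printed`), and `derive_columns()` recomputes those columns
from the raw $(K, \lambda_R)$ inputs: $H^2_{01}$ from Eq-1 style algebra,
the dominance ratio $(\lambda_{Sib}-1)/(\lambda_{OP}-1)$, the excess ratio
$(\lambda_{MZ}-1)/(\lambda_{Sib}-1)$ (2 under pure additivity; mostly $>2$
in the table), and $\lambda_{MZ}/\lambda_{Sib}^2$ (1 under unconstrained
multiplicativity; $<1$ for most low-prevalence diseases). The recomputed
$H^2_{01}$ matches the printed value at 2-decimal rounding for every
labelled row (0.11–0.63 across diseases); the one unlabelled source row
prints 0.24 where the printed inputs give 0.232, presumably an unrounded
prevalence upstream, and the tests hold that row to $\pm 0.01$ rather than
pretending exactness. One column of the source table (0.34–1.00) is
consistent with liability-scale heritability from MZ concordance; its
provenance is not certain enough to assert, so it is shipped as
`h2_liability_printed` and compared with nothing.

```{r table1}
derive_columns(load_table1())[, c("disease", "K", "lambda_mz", "h2_01",
                                  "excess_ratio", "mz_over_sib_sq")]
```

## What the synthetic families do and do not emulate

The simulation reproduces exactly the world the models describe:
independent exchangeable loci, random mating, purely genetic familial
resemblance, lifetime (not age-dependent) disease status, random
population sampling of probands. Passing tests therefore validate the
*computational machinery* — calibration, exact sums, Mendelian transmission
— not the biological realism of any model. Real diseases violate the
assumptions in known ways: shared family environment inflates all
$\lambda_R$ (so genetic interpretations are upper bounds), loci differ in
frequency and effect (inconsequential for the population summaries, which
depend on total variance, but consequential for any per-locus statement),
linkage and assortative mating induce genotype correlations the binomial
ignores, and ascertainment of probands is rarely random. Unequal per-locus
parameters, linkage, inbreeding and ascertainment corrections are
explicitly out of scope.

## Design choices made where the design was open

* The odds-model risk is computed as $O/(1+O)$; a printed form with
  $1 - \gamma^x C_n$ in the denominator is not a probability for large $x$
  and is treated as a sign slip.
* The probit threshold is calibrated on the discrete support (above);
  the per-allele liability effect uses the variance identity
  $a = \sqrt{h^2_l/(2np(1-p))}$ with total phenotypic variance 1.
* The odds model's $\gamma$ is identified with the benchmark $\tau$ when
  building matched sets: both are "the factor for one extra allele", and
  at the small per-allele effects of interest the distinction between risk
  ratio and odds factor at a single locus is negligible (the 1.00003 check
  above), while applying it consistently to all models keeps the
  benchmark interpretable.
* Null models are exact, not limiting: $\tau = 1$ (or $h^2_l = 0$) yields
  $g_x \equiv K$ in every kind, with the baselines taking their null values
  ($f_n = K$, $C_n = K/(1-K)$, $a = 0$).
* Acceptance-script problem sizes: exact sums at $n = 1000$ (support
  2001), simulation at $2 \times 10^6$ families — the sizes at which the
  quantities of interest have comfortably sub-rounding Monte-Carlo error.

## Known limitations

The $\lambda_{OG}$-based narrow-sense estimator is mildly epistasis-
contaminated (see above). `lambda_sib_exact()` is $O(n^2)$ in time and is
comfortable up to a few thousand loci but not $10^5$. The CLI's YAML config
reader renames a bare key `n` (which YAML 1.1 parses as a boolean) back to
`n`; users writing `"n":` quoted avoid the corner entirely. And all
heritabilities here are population quantities of a *model*; nothing in this
package estimates anything from individual-level data.
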