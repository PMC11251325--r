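---
title: "Planning test-negative vaccine effectiveness studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning test-negative vaccine effectiveness studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnddesign)
```

## The design problem

In a test-negative design (TND), patients who seek care for a syndromic
illness are tested for the vaccine-targeted pathogen; test-positives act
as cases and test-negatives as controls, and vaccine effectiveness (VE)
is estimated as one minus the odds ratio of vaccination between the two
groups. The design is passive: investigators fix neither the number of
cases nor the case:control ratio — only the total number of tests
accrued can realistically be budgeted. This package provides the
hypothesis tests, sample size formulas and a study simulator for
planning such studies, with particular attention to the sparse-data
regime of highly effective vaccines (VE at or above 90%), where the
vaccinated test-positive cell of the 2x2 table is frequently zero.

All methods operate on the familiar table with cells $a$ (vaccinated
test-positive), $b$ (vaccinated test-negative), $c$ (unvaccinated
test-positive), $d$ (unvaccinated test-negative), $n = a+b+c+d$, and on
one-sided hypotheses $H_0: OR \ge \theta_0$ vs $H_1: OR < \theta_0$
(by default $\theta_0 = 1$, i.e. testing VE > 0).

## Scenario parameters

A scenario (`tnd_design()`) is described by:

* `ve` — vaccine effectiveness under the alternative, in $[0,1)$. The
  vaccine model is all-or-none: a fraction `ve` of vaccinees is
  completely protected, the rest are as susceptible as the unvaccinated.
* `coverage` ($p_N$) — the fraction vaccinated among test-negatives,
  which under the core TND assumption (no vaccine effect on
  test-negative illness) proxies population coverage. Strictly inside
  $(0,1)$.
* `lambda_i`, `lambda_n` (per day) and `tau` (days) — constant hazards
  of test-positive and test-negative illness and the study period;
  equivalently the cumulative hazards `Lambda_I` $=\lambda_I\tau$,
  `Lambda_N` $=\lambda_N\tau$ may be given directly. An individual can
  test positive at most once (short-term immunity) but can test negative
  repeatedly. Defaults in the examples below are $\lambda_I = 0.001$,
  $\lambda_N = 0.002$, $\tau = 100$ — roughly a 10% seasonal attack
  proportion for the target pathogen and two syndromic episodes per ten
  person-seasons from other causes.
* `alpha` — one-sided level, default 0.025; `power`, default 0.8;
  `theta0`, default 1.

Two quantities derive from these. The expected fraction vaccinated
among test-positives,
$$p_I = \frac{p_N(1-\mathrm{VE})}{1 - p_N\,\mathrm{VE}},$$
satisfies the exact identity
$\frac{p_I/(1-p_I)}{p_N/(1-p_N)} = 1-\mathrm{VE}$, and the expected
percent positivity
$$\pi = \frac{(1-p_N \mathrm{VE})(1-e^{-\Lambda_I})}
             {(1-p_N \mathrm{VE})(1-e^{-\Lambda_I}) + \Lambda_N}.$$
Where surveillance data give a direct estimate of positivity, `pi` can
be supplied instead of the hazards (the two input paths are mutually
exclusive, and a `pi`-only scenario cannot be simulated because the
event processes are then under-determined).

## The three tests

The standard Wald statistic divides the log odds ratio (minus
$\ln\theta_0$) by its delta-method standard error
$\sqrt{1/a+1/b+1/c+1/d}$; any zero cell makes it intractable, and
`wald_test()` reports that as a flagged non-rejection rather than an
error, because in a power calculation an unanalysable study is a failed
study. The continuity-corrected version adds $\delta$ (default the
Yates value 0.5) to every cell and is always tractable, at the price of
bias in the point estimate (see the bias scan below). The score test
uses the score and information of the simple logistic regression of
test result on vaccination status evaluated under the null; pooling
under the null means a single zero cell is harmless and only a zero
margin is intractable. At $\theta_0 = 1$ it has the closed form
$$T_S = \frac{(ad-bc)\sqrt{n}}{\sqrt{(a+c)(b+d)(a+b)(c+d)}},$$
and for general $\theta_0$ the intercept is profiled out numerically:
the constrained score equation is solved by bracketed root finding
(`uniroot` on $[-50, 50]$ with interval extension, tolerance
$10^{-10}$) and the variance is the efficient information at that
optimum. The test suite checks the numerical path against the closed
form at $\theta_0 = 1$ and against a finite-difference likelihood
oracle at other nulls. All three tests reject when the statistic falls
below the lower-tail critical value $z_\alpha$; reported $p$-values
are lower-tail normal probabilities and are informational — the
decision uses the statistic directly.

```{r tests}
tb <- tnd_table(0, 30, 20, 50)
wald_test(tb)     # intractable: zero vaccinated test-positives
score_test(tb)    # still informative
```

## Sample sizes

Four calculators return the required *total number of tests*, always
rounded up (a fractional test is not actionable, and the ceiling
convention reproduces every cross-checked published value):

* `wald_sample_size()` — the classical Wald formula re-expressed in
  $(p_I, p_N, \pi)$.
* `wald_cc_sample_size()` — the continuity correction applied to the
  *unrounded* Wald size; rounding first would shift small designs by
  one test, and the unrounded convention follows the structure of the
  correction formula.
* `score_sample_size()` — $n_S = (Z_{1-\gamma}\sigma_1 +
  Z_{1-\alpha}\sigma_0)^2 / (p_I-p_N)^2$, with the null and alternative
  variances of $\hat p_I - \hat p_N$ from the logistic likelihood.
  This treats $\pi$ as fixed, as in a case-control study.
* `tnd_score_sample_size()` — the TND-adjusted size. In a TND the
  number of positives among $n$ tests is Binomial$(n, \pi)$, so the
  power of the score test is the binomial-weighted sum
  $$\sum_{k=0}^{n}\Phi\!\left(\frac{Z_\alpha\sigma_0 -
  (p_I-p_N)\sqrt n}{\tilde\sigma_1(k/n)}\right)\binom{n}{k}\pi^k
  (1-\pi)^{n-k},$$
  where $\tilde\sigma_1^2(\hat\pi) = p_I(1-p_I)/\hat\pi +
  p_N(1-p_N)/(1-\hat\pi) + 2p_Ip_N$ is the alternative variance under a
  multinomial law for the table. The adjusted size is the smallest $n$
  (grid search, step 1, starting at the case-control score size) whose
  weighted power reaches the target.

```{r sizes}
d <- tnd_design(ve = 0.95, coverage = 0.3,
                lambda_i = 0.001, lambda_n = 0.002, tau = 100)
sapply(list(wald = wald_sample_size, wald_cc = wald_cc_sample_size,
            score = score_sample_size, tnd = tnd_score_sample_size),
       function(f) f(d)$n)
```

Numerical choices inside `weighted_power()`: the null variance
$\sigma_0$ is held at the design $\pi$ (it is nearly flat in
$\hat\pi$), while $\tilde\sigma_1$ varies with $k/n$; the degenerate
terms $k = 0$ and $k = n$, where $\tilde\sigma_1$ diverges, are
assigned rejection probability zero — such a table has an empty margin
and cannot reject — and their binomial mass is below $10^{-9}$ at the
sizes of interest. Binomial weights come from `dbinom()`, which works
on the log scale and is stable to $n$ well past $10^4$.

## What the simulator emulates

`simulate_tables()` reproduces the planning model as a generative
process so that the closed-form calculators can be audited:

1. **Cohort.** A care-seeking source population of size $N$, computed
   by `source_population_size()` from the expected per-member cell
   counts $u_a = p_N(1-\mathrm{VE})(1-e^{-\Lambda_I})$,
   $u_b = p_N\Lambda_N$, $u_c = (1-p_N)(1-e^{-\Lambda_I})$,
   $u_d = (1-p_N)\Lambda_N$ as $N = \lceil n/\sum u\rceil$ — sized so
   that $n$ tests accrue in about one study period. Vaccination and
   all-or-none protection are assigned by exact counts (half-up
   rounding), matching the "randomly selected fraction" framing rather
   than per-individual Bernoulli draws.
2. **Events.** Per unprotected individual, one potential positive-test
   time drawn from Exp($\lambda_I$); per individual, a Poisson process
   of negative tests at rate $\lambda_N$, truncated to the first three
   arrivals (more than three similar syndromic episodes in a season is
   exceptional; under the default scenarios the truncation removes
   under 0.1% of the expected negative-test mass, and the discarded
   count is reported). Testing positive does not stop negative testing;
   test sensitivity and specificity are perfect.
3. **Sampling.** Both stopping rules are *count-based*, so the study
   duration is an output, not an input: the TND enrols the first $n$
   tests in time order (ties broken uniformly at random — continuous
   times make them measure-zero, but floating point does not), and the
   case-control design takes the first $\mathrm{round}(n\pi)$ positives
   as cases plus a simple random sample of negatives as controls.
   Because $N$ makes the expected event yield over one period equal
   $n$, about half of all replicates need slightly more than $\tau$
   days; events are therefore generated over an extended window
   (`horizon_factor` study periods, default 3) and the mean realised
   duration comes out at about $\tau$, as intended. Control sampling
   from the full negative-event pool is innocuous because vaccination
   coverage is constant in time, so the composition of negatives does
   not depend on the sampling window.
4. **Reproducibility.** A root seed draws one sub-seed per replicate,
   so any replicate can be regenerated in isolation; the rare
   case-control replicate without enough events redraws within its own
   stream and logs the redraw count.

The Monte-Carlo layer (`estimate_rejection_rate()`,
`zero_cell_frequency()`, `continuity_scan()`) wraps this into power,
type-I error (simulated at the null boundary VE $= 1-\theta_0$ with
$n$ taken as given), zero-cell frequency, and the bias/SE scan of the
continuity correction over $\delta\in[0,2]$, where the true log odds
ratio is $\ln(1-\mathrm{VE})$ by the identity above. The default is
100,000 replicates; the package's own test suite runs its end-to-end
checks at 10,000 replicates, and its distributional spot-checks at
300–5,000 replicates, judging estimates against three Monte-Carlo
standard errors — sizes chosen so the full suite runs in about a
minute while keeping the checks sharp enough to catch implementation
errors of practical magnitude.

```{r mc}
summary_74 <- estimate_rejection_rate(d, "tnd", "score", n = 74,
                                      reps = 2000, seed = 1)
summary_74
```

## What the simulator does *not* emulate

The generator matches the planning model, not field reality: constant
hazards and coverage (no seasonality, no rollout during the study), no
waning and no leaky protection, no confounders, no differential
health-care-seeking by vaccination status, perfect diagnostics, and
independence of the two illness processes (an individual can in
principle contribute a positive and a negative test in the same
period, as two separate care visits). Agreement between the simulator
and the formulas therefore validates the calculators *given* the
model; it does not certify performance under confounding or
measurement error, which require covariate-adjusted analyses outside
this package's scope.

One known discrepancy with published simulation results is documented
here deliberately: under this generative model the expected number of
vaccinated test-positives in the high-VE, low-coverage reference
scenario (VE 95%, coverage 10%, $n = 228$) is
$E[a] = n\pi p_I \approx 0.38$, which bounds the zero-cell probability
below by $1 - E[a] \approx 0.62$ (Markov's inequality) — the package
simulates about 0.67 for both designs, and published TND values as
low as 0.61 are not reachable by *any* generator with that expected
cell count. The corresponding case-control frequency (about 0.68)
reproduces well.

## Degenerate inputs and tie-breaks

Proportion parameters are validated strictly inside their open
intervals wherever a division occurs; boundary values raise classed
`tnd_invalid_parameter` errors instead of returning infinities.
Intractable statistics are flagged outcomes (`tractable = FALSE`),
never `NaN`; the distinct condition classes `tnd_intractable`,
`tnd_undefined_variance`, `tnd_insufficient_events`,
`tnd_no_solution` and `tnd_numeric_failure` let callers and the
command-line interface map failures to exit codes (2 for validation,
3 for numeric failure). Sample-size and population-size rounding is
always *up*; event-count rounding (cases in the case-control sampler,
cohort assignment counts) is half-up, so the reference case-control
scenario at $n = 228$, $\pi \approx 0.301$ fixes 69 cases.
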