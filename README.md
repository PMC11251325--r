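# tnddesign

Design and analysis tools for **test-negative design (TND)** vaccine
effectiveness studies.

In a TND, patients presenting with a common syndrome (e.g. influenza-like
illness) are tested for the vaccine-targeted pathogen. Test-positives serve
as cases, test-negatives as controls, and vaccine effectiveness (VE) is
estimated as one minus the odds ratio of vaccination from the 2x2 table

|              | test+ | test− |
|--------------|-------|-------|
| vaccinated   | a     | b     |
| unvaccinated | c     | d     |

so that VE = 1 − ad/(bc). Unlike a classical case-control study, a TND
cannot fix the number of cases or the case:control ratio in advance — only
the **total number of tests** n = a+b+c+d can be budgeted, and the split
between positives and negatives is random. For highly effective vaccines
(VE ≥ 90%) the vaccinated test-positive cell `a` is often zero, which makes
the usual Wald test of the odds ratio intractable. This package addresses
both problems. It is aimed at epidemiologists and biostatisticians planning
TND studies (influenza, RSV, rotavirus, COVID-19 VE surveillance).

## What it provides

* **Tests of H0: OR ≥ θ0 vs H1: OR < θ0** (one-sided): the standard Wald
  test (`wald_test()`), a continuity-corrected Wald test that adds δ = 0.5
  to every cell (`wald_cc_test()`), and a logistic score test
  (`score_test()`) that stays tractable with a single zero cell and has
  the closed form `(ad − bc)√n / √((a+c)(b+d)(a+b)(c+d))` at θ0 = 1.
* **Sample sizes** (total tests, always rounded up): Wald
  (`wald_sample_size()`), continuity-corrected Wald
  (`wald_cc_sample_size()`), case-control score (`score_sample_size()`),
  and a TND-adjusted score size (`tnd_score_sample_size()`) that treats
  the number of positives as Binomial(n, π) and averages power over it
  with exact binomial weights.
* **A study simulator** (`simulate_tables()`): an all-or-none vaccine in
  a care-seeking cohort with constant hazards of target and non-target
  illness, sampled either as a TND (first n tests) or as a case-control
  study with a fixed case count — plus Monte-Carlo wrappers for power,
  type-I error, zero-cell frequency and continuity-correction bias
  (`estimate_rejection_rate()`, `zero_cell_frequency()`,
  `continuity_scan()`).
* **A command-line interface** (`inst/cli/tnddesign.R`) and CSV/JSON
  scenario and result I/O (`read_scenarios()`, `write_results()`).

The methods vignette (`vignettes/tnd-design-methods.Rmd`) derives the
formulas and documents every modelling and numerical choice.

## Worked example

Plan a study of a 95%-effective vaccine at 30% coverage, with hazards of
0.001/day (target pathogen) and 0.002/day (other causes of the syndrome)
over a 100-day season:

```r
library(tnddesign)

d <- tnd_design(ve = 0.95, coverage = 0.3,
                lambda_i = 0.001, lambda_n = 0.002, tau = 100)
d
#> Test-negative design scenario
#>   VE = 0.95, coverage p_N = 0.3, theta0 = 1
#>   Lambda_I = 0.1, Lambda_N = 0.2 (tau = 100 days)
#>   alpha = 0.025 (one-sided), power = 0.8
#>   derived: p_I = 0.020979, pi = 0.25385

wald_sample_size(d)
#> wald sample size: n = 74 total tests (unrounded 73.9510)

tnd_score_sample_size(d)   # accounts for the random positive:negative split
#> tnd_score sample size: n = 75 total tests (unrounded 75.0000)
#>   achieved power (binomial-weighted): 0.8023
```

Analyse a realised table with a zero cell — the Wald test fails, the
score test does not:

```r
tb <- tnd_table(0, 30, 20, 50)

wald_test(tb)
#> wald test of H0: OR >= 1 vs H1: OR < 1 (one-sided alpha = 0.025)
#>   intractable (zero cell or margin); H0 not rejected

score_test(tb)
#> score test of H0: OR >= 1 vs H1: OR < 1 (one-sided alpha = 0.025)
#>   statistic = -3.2733, p = 0.0005316, reject H0: TRUE
```

Check the planned design by simulation:

```r
estimate_rejection_rate(d, "tnd", "score", n = 74, reps = 2000, seed = 1)
#> Monte-Carlo power (score, tnd): 0.8415 (MC se 0.008166, 2000 replicates, seed 1)
```

The same operations are available from the shell:

```sh
Rscript inst/cli/tnddesign.R samplesize --method tnd-score \
    --ve 0.95 --coverage 0.3 --lambda-i 0.001 --lambda-n 0.002 --tau 100
Rscript inst/cli/tnddesign.R test --a 0 --b 30 --c 20 --d 50 --method score
```

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "tnddesign", load_package = "installed")'
```

The suite (~1 minute) covers exact reproduction of reference sample
sizes, agreement of the numerical score test with a finite-difference
likelihood oracle, simulator calibration against the closed-form
expectations, type-I error control across a coverage grid, and
round-trip I/O.

## License

MIT (see `LICENSE`).
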