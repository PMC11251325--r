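# Reference scenarios used throughout the suite: constant hazards
# lambda_I = 0.001/day, lambda_N = 0.002/day over a 100-day period
# (Lambda_I = 0.1, Lambda_N = 0.2), one-sided alpha = 0.025, power 80%.
ref_design <- function(ve = 0.95, coverage = 0.3, ...) {
  tnd_design(ve = ve, coverage = coverage,
             lambda_i = 0.001, lambda_n = 0.002, tau = 100, ...)
}

# grid of scenarios for property-style checks
scenario_grid <- expand.grid(ve = c(0.3, 0.5, 0.7, 0.9, 0.95),
                             coverage = c(0.1, 0.3, 0.5, 0.7, 0.9))
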