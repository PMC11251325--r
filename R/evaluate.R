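new_mc_summary <- function(quantity, rate, reps, seed, extra = list()) {
  structure(c(list(
    quantity = quantity,
    rate = rate,
    reps = reps,
    mc_se = sqrt(rate * (1 - rate) / reps),
    seed = seed
  ), extra), class = "tnd_mc_summary")
}

#' @export
print.tnd_mc_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo %s: %.4f (MC se %.4g, %d replicates, seed %d)\n",
              x$quantity, x$rate, x$mc_se, x$reps, x$seed))
  invisible(x)
}

#' Monte-Carlo rejection rate (power or type-I error)
#'
#' Simulates replicate studies and applies one of the three tests,
#' returning the proportion of replicates that reject the null. In
#' `mode = "power"` the data are generated at the scenario's vaccine
#' effectiveness; in `mode = "type1"` they are generated at the null
#' boundary `ve = 1 - theta0` (no effect when `theta0 = 1`) with the same
#' hazards and coverage, and `n` is used as given.
#'
#' Intractable Wald replicates (a zero cell) count as non-rejections
#' unless `wald_fallback = TRUE`, in which case they are re-tested with
#' the continuity-corrected statistic at `delta`.
#'
#' @param design A [tnd_design()] built from hazards.
#' @param study `"tnd"` or `"case_control"`.
#' @param test `"wald"`, `"wald_cc"` or `"score"`.
#' @param n Total tests per replicate.
#' @param reps Number of replicates (default 1e5).
#' @param seed Root RNG seed.
#' @param mode `"power"` or `"type1"`.
#' @param wald_fallback For `test = "wald"`: substitute the corrected
#'   statistic when the standard one is intractable.
#' @param delta Continuity correction used by `"wald_cc"` and the
#'   fallback.
#' @return A `tnd_mc_summary` with the rejection `rate`, its Monte-Carlo
#'   standard error, and the replicate tables in `$tables`.
#' @export
estimate_rejection_rate <- function(design, study = c("tnd", "case_control"),
                                    test = c("score", "wald", "wald_cc"),
                                    n, reps = 1e5, seed,
                                    mode = c("power", "type1"),
                                    wald_fallback = FALSE, delta = 0.5) {
  stopifnot(inherits(design, "tnd_design"))
  study <- match.arg(study)
  test <- match.arg(test)
  mode <- match.arg(mode)
  if (reps < 100) stop_invalid("reps must be at least 100")

  sim_design <- design
  if (mode == "type1") {
    ve0 <- max(0, 1 - design$theta0)
    sim_design <- tnd_design(ve = ve0, coverage = design$coverage,
                             lambda_i = design$lambda_i,
                             lambda_n = design$lambda_n, tau = design$tau,
                             Lambda_I = if (is.null(design$lambda_i)) design$Lambda_I,
                             Lambda_N = if (is.null(design$lambda_i)) design$Lambda_N,
                             theta0 = design$theta0, alpha = design$alpha,
                             power = design$power)
  }
  tabs <- simulate_tables(sim_design, study, n, reps, seed)
  stat <- switch(test,
    wald = wald_stat_vec(tabs$a, tabs$b, tabs$c, tabs$d, design$theta0),
    wald_cc = wald_cc_stat_vec(tabs$a, tabs$b, tabs$c, tabs$d, design$theta0, delta),
    score = score_stat_vec(tabs$a, tabs$b, tabs$c, tabs$d, design$theta0))
  if (test == "wald" && wald_fallback) {
    bad <- is.na(stat)
    stat[bad] <- wald_cc_stat_vec(tabs$a[bad], tabs$b[bad], tabs$c[bad],
                                  tabs$d[bad], design$theta0, delta)
  }
  crit <- stats::qnorm(design$alpha)
  reject <- !is.na(stat) & stat < crit
  new_mc_summary(paste0(mode, " (", test, ", ", study, ")"),
                 mean(reject), reps, seed,
                 extra = list(test = test, study = study, mode = mode,
                              n = n, tables = tabs))
}

#' Monte-Carlo frequency of zero vaccinated test-positives
#'
#' Proportion of simulated replicates in which the vaccinated
#' test-positive cell `a` is zero — the configuration that makes the
#' standard Wald statistic intractable, common under high vaccine
#' effectiveness with low coverage.
#'
#' @inheritParams estimate_rejection_rate
#' @return A `tnd_mc_summary` with the zero-cell `rate`.
#' @export
zero_cell_frequency <- function(design, study = c("tnd", "case_control"),
                                n, reps = 1e5, seed) {
  stopifnot(inherits(design, "tnd_design"))
  study <- match.arg(study)
  if (reps < 100) stop_invalid("reps must be at least 100")
  tabs <- simulate_tables(design, study, n, reps, seed)
  new_mc_summary(paste0("zero-cell frequency (", study, ")"),
                 mean(tabs$a == 0), reps, seed,
                 extra = list(study = study, n = n, tables = tabs))
}

#' Bias/standard-error scan of the continuity correction
#'
#' Scans a grid of continuity corrections and reports, at each `delta`,
#' the mean bias of the corrected log odds ratio relative to the true
#' value \eqn{\ln(1 - VE)} and the standard deviation of the estimates
#' across replicates. At `delta = 0` the estimator is intractable in any
#' replicate with a zero cell; such grid points are flagged and returned
#' as `NA`.
#'
#' @inheritParams estimate_rejection_rate
#' @param deltas Grid of corrections, within `[0, 2]`.
#' @return A `tnd_bias_scan`: data.frame with `delta`, `bias`, `se`,
#'   `intractable`; attribute `n_zero_cell` counts replicates with a zero
#'   cell.
#' @export
continuity_scan <- function(design, study = c("tnd", "case_control"),
                            n, deltas = seq(0, 2, by = 0.1),
                            reps = 1e5, seed) {
  stopifnot(inherits(design, "tnd_design"))
  study <- match.arg(study)
  if (any(deltas < 0) || any(deltas > 2))
    stop_invalid("deltas must lie in [0, 2]")
  if (reps < 100) stop_invalid("reps must be at least 100")
  tabs <- simulate_tables(design, study, n, reps, seed)
  true_lor <- log(1 - design$ve)
  any_zero <- tabs$a == 0 | tabs$b == 0 | tabs$c == 0 | tabs$d == 0
  res <- lapply(deltas, function(dl) {
    if (dl == 0 && any(any_zero))
      return(c(bias = NA_real_, se = NA_real_, intractable = 1))
    lor <- log((tabs$a + dl) * (tabs$d + dl) /
                 ((tabs$b + dl) * (tabs$c + dl)))
    c(bias = mean(lor) - true_lor, se = stats::sd(lor), intractable = 0)
  })
  out <- data.frame(delta = deltas, do.call(rbind, res))
  out$intractable <- as.logical(out$intractable)
  attr(out, "n_zero_cell") <- sum(any_zero)
  attr(out, "scenario") <- attr(tabs, "scenario")
  class(out) <- c("tnd_bias_scan", "data.frame")
  out
}
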