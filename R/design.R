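#' @keywords internal
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("tnd_invalid_parameter", "error")))
}

#' Expected fraction vaccinated among test-positives
#'
#' Under a test-negative design the fraction vaccinated among test-negative
#' patients, `p_N`, proxies the vaccination coverage of the source
#' population. For an all-or-none vaccine with effectiveness `VE`, the
#' expected fraction vaccinated among test-positive patients is
#' \deqn{p_I = \frac{p_N (1 - VE)}{1 - p_N \, VE}.}
#' The implied odds ratio \eqn{[p_I/(1-p_I)] / [p_N/(1-p_N)]} equals
#' \eqn{1 - VE} exactly.
#'
#' @param coverage Vaccination coverage among test-negatives (`p_N`),
#'   strictly between 0 and 1.
#' @param ve Vaccine effectiveness, in `[0, 1]`.
#' @return The expected proportion vaccinated among test-positives.
#' @examples
#' vacc_frac_positives(0.3, 0.95)
#' @export
vacc_frac_positives <- function(coverage, ve) {
  if (any(coverage <= 0) || any(coverage >= 1))
    stop_invalid("coverage must lie strictly in (0, 1)")
  if (any(ve < 0) || any(ve > 1))
    stop_invalid("ve must lie in [0, 1]")
  coverage * (1 - ve) / (1 - coverage * ve)
}

#' Expected percent positivity
#'
#' Expected fraction of test-positive results among all tests,
#' \deqn{\pi = \frac{(1 - p_N VE)(1 - e^{-\Lambda_I})}
#'                  {(1 - p_N VE)(1 - e^{-\Lambda_I}) + \Lambda_N},}
#' where \eqn{\Lambda_I} is the cumulative hazard of test-positive illness
#' among the unvaccinated (at most one positive test per person) and
#' \eqn{\Lambda_N} the cumulative hazard of test-negative illness (a
#' recurrent process unaffected by vaccination). Where surveillance data
#' give a direct estimate of percent positivity, that value may be used in
#' place of this approximation (see [tnd_design()]).
#'
#' @inheritParams vacc_frac_positives
#' @param Lambda_I Cumulative hazard of test-positive illness over the
#'   study period, `>= 0`.
#' @param Lambda_N Cumulative hazard of test-negative illness over the
#'   study period, `>= 0`. Not both hazards may be zero.
#' @return Expected proportion of positives among all tests.
#' @examples
#' percent_positivity(0.3, 0.95, Lambda_I = 0.1, Lambda_N = 0.2)
#' @export
percent_positivity <- function(coverage, ve, Lambda_I, Lambda_N) {
  if (any(Lambda_I < 0) || any(Lambda_N < 0))
    stop_invalid("cumulative hazards must be non-negative")
  if (any(Lambda_I == 0 & Lambda_N == 0))
    stop_invalid("at least one of Lambda_I, Lambda_N must be positive")
  if (any(coverage <= 0) || any(coverage >= 1))
    stop_invalid("coverage must lie strictly in (0, 1)")
  if (any(ve < 0) || any(ve > 1))
    stop_invalid("ve must lie in [0, 1]")
  pos <- (1 - coverage * ve) * (1 - exp(-Lambda_I))
  pos / (pos + Lambda_N)
}

#' Null and alternative variance components of the score statistic
#'
#' Variances of the score-test numerator \eqn{\hat p_I - \hat p_N} (scaled
#' by the total number of tests) under the null hypothesis of no vaccine
#' effect and under the alternative, derived from the likelihood of a
#' simple logistic regression of test result on vaccination status:
#' \deqn{\sigma_0^2 = \frac{[\pi p_I + (1-\pi) p_N]
#'       [\pi(1-p_I) + (1-\pi)(1-p_N)]}{\pi (1-\pi)}}
#' \deqn{\sigma_1^2 = \frac{p_I p_N (1-p_I)(1-p_N)}
#'       {\pi(1-\pi) [\pi p_I (1-p_I) + (1-\pi) p_N (1-p_N)]}.}
#'
#' @param p_i Expected fraction vaccinated among test-positives.
#' @param p_n Expected fraction vaccinated among test-negatives.
#' @param pi Expected percent positivity, strictly in (0, 1).
#' @return Named numeric vector with components `sigma0_sq` and
#'   `sigma1_sq`.
#' @export
score_variances <- function(p_i, p_n, pi) {
  if (any(pi <= 0) || any(pi >= 1))
    stop_invalid("pi must lie strictly in (0, 1)")
  if (any(p_i < 0) || any(p_i > 1) || any(p_n < 0) || any(p_n > 1))
    stop_invalid("p_i and p_n must lie in [0, 1]")
  pbar <- pi * p_i + (1 - pi) * p_n
  qbar <- pi * (1 - p_i) + (1 - pi) * (1 - p_n)
  s0 <- pbar * qbar / (pi * (1 - pi))
  s1 <- p_i * p_n * (1 - p_i) * (1 - p_n) /
    (pi * (1 - pi) * (pi * p_i * (1 - p_i) + (1 - pi) * p_n * (1 - p_n)))
  c(sigma0_sq = s0, sigma1_sq = s1)
}

#' Multinomial alternative variance of the score numerator
#'
#' Variance of \eqn{\hat p_I - \hat p_N} under the alternative when the
#' four cell counts of a test-negative design follow a multinomial
#' distribution (both margins random), evaluated at an observed percent
#' positivity \eqn{\hat\pi}:
#' \deqn{\tilde\sigma_1^2(\hat\pi) = \frac{p_I(1-p_I)}{\hat\pi}
#'   + \frac{p_N(1-p_N)}{1-\hat\pi} + 2 p_I p_N.}
#' This is the variance term entering the binomial-weighted power sum of
#' [weighted_power()]. It diverges as \eqn{\hat\pi \to 0} or 1; such
#' degenerate tables cannot reject and are handled by the caller.
#'
#' @inheritParams score_variances
#' @param pi_hat Observed fraction of positives among all tests, strictly
#'   in (0, 1).
#' @return The variance \eqn{\tilde\sigma_1^2(\hat\pi)}.
#' @export
multinomial_variance <- function(p_i, p_n, pi_hat) {
  if (any(pi_hat <= 0) || any(pi_hat >= 1))
    stop(errorCondition(
      "pi_hat at 0 or 1: alternative variance is undefined",
      class = c("tnd_undefined_variance", "error")))
  p_i * (1 - p_i) / pi_hat + p_n * (1 - p_n) / (1 - pi_hat) + 2 * p_i * p_n
}

#' Specify a test-negative design scenario
#'
#' Collects the design parameters of a TND (or matched case-control)
#' vaccine effectiveness study and precomputes the derived quantities used
#' by the sample size calculators and the simulator: the expected fraction
#' vaccinated among positives (`p_i`), the expected percent positivity
#' (`pi`), and the null/alternative score variances.
#'
#' Cumulative hazards may be given either as per-day rates `lambda_i`,
#' `lambda_n` together with a study period `tau` (days), or directly as
#' `Lambda_I`, `Lambda_N`; the two parameterisations are mutually
#' exclusive. Alternatively percent positivity may be supplied directly as
#' `pi` (e.g. from historical surveillance); a design built from `pi`
#' alone supports the sample size calculators but not event simulation,
#' and supplying both `pi` and hazards is an error.
#'
#' @param ve Vaccine effectiveness under the alternative, in `[0, 1)`.
#' @param coverage Vaccination coverage among test-negatives (`p_N`),
#'   strictly in (0, 1).
#' @param lambda_i,lambda_n Constant hazards (per day) of test-positive
#'   and test-negative illness.
#' @param tau Study period in days.
#' @param Lambda_I,Lambda_N Cumulative hazards over the study period,
#'   alternative to `lambda_i`/`lambda_n`/`tau`.
#' @param pi Optional percent-positivity override; mutually exclusive with
#'   the hazard parameters.
#' @param theta0 Null odds ratio bound (default 1); the hypotheses are
#'   one-sided, H0: OR >= `theta0` versus H1: OR < `theta0`.
#' @param alpha One-sided significance level, in (0, 0.5).
#' @param power Desired power `1 - gamma`, in (0, 1).
#' @return An object of class `tnd_design`: a list with the supplied
#'   parameters plus `p_i`, `pi`, `sigma0_sq`, `sigma1_sq`.
#' @examples
#' d <- tnd_design(ve = 0.95, coverage = 0.3,
#'                 lambda_i = 0.001, lambda_n = 0.002, tau = 100)
#' d$pi
#' @export
tnd_design <- function(ve, coverage,
                       lambda_i = NULL, lambda_n = NULL, tau = NULL,
                       Lambda_I = NULL, Lambda_N = NULL, pi = NULL,
                       theta0 = 1, alpha = 0.025, power = 0.8) {
  if (length(ve) != 1 || is.na(ve) || ve < 0 || ve >= 1)
    stop_invalid("ve must be a single value in [0, 1)")
  if (length(coverage) != 1 || is.na(coverage) || coverage <= 0 || coverage >= 1)
    stop_invalid("coverage must be a single value in (0, 1)")
  if (theta0 <= 0) stop_invalid("theta0 must be positive")
  if (alpha <= 0 || alpha >= 0.5) stop_invalid("alpha must lie in (0, 0.5)")
  if (power <= 0 || power >= 1) stop_invalid("power must lie in (0, 1)")

  rate_path <- !is.null(lambda_i) || !is.null(lambda_n) || !is.null(tau)
  cum_path  <- !is.null(Lambda_I) || !is.null(Lambda_N)
  if (rate_path && cum_path)
    stop_invalid("supply hazards either as rates with tau or as cumulative ",
                 "hazards, not both")
  if (rate_path) {
    if (is.null(lambda_i) || is.null(lambda_n) || is.null(tau))
      stop_invalid("lambda_i, lambda_n and tau must be supplied together")
    if (lambda_i < 0 || lambda_n < 0 || tau <= 0)
      stop_invalid("hazards must be non-negative and tau positive")
    Lambda_I <- lambda_i * tau
    Lambda_N <- lambda_n * tau
  } else if (cum_path) {
    if (is.null(Lambda_I) || is.null(Lambda_N))
      stop_invalid("Lambda_I and Lambda_N must be supplied together")
    if (Lambda_I < 0 || Lambda_N < 0)
      stop_invalid("cumulative hazards must be non-negative")
    tau <- NULL
  }
  have_hazards <- rate_path || cum_path

  if (!is.null(pi)) {
    if (have_hazards)
      stop_invalid("pi override and hazards are mutually exclusive; ",
                   "supply exactly one")
    if (pi <= 0 || pi >= 1) stop_invalid("pi must lie strictly in (0, 1)")
  } else {
    if (!have_hazards)
      stop_invalid("supply either hazards (with tau) or pi")
    pi <- percent_positivity(coverage, ve, Lambda_I, Lambda_N)
  }

  p_i <- vacc_frac_positives(coverage, ve)
  vv <- score_variances(p_i, coverage, pi)
  structure(list(
    ve = ve, coverage = coverage,
    lambda_i = lambda_i, lambda_n = lambda_n, tau = tau,
    Lambda_I = Lambda_I, Lambda_N = Lambda_N,
    theta0 = theta0, alpha = alpha, power = power,
    p_i = p_i, pi = pi,
    sigma0_sq = unname(vv["sigma0_sq"]), sigma1_sq = unname(vv["sigma1_sq"])
  ), class = "tnd_design")
}

#' @export
print.tnd_design <- function(x, ...) {
  cat("Test-negative design scenario\n")
  cat(sprintf("  VE = %.3g, coverage p_N = %.3g, theta0 = %.3g\n",
              x$ve, x$coverage, x$theta0))
  if (!is.null(x$Lambda_I))
    cat(sprintf("  Lambda_I = %.4g, Lambda_N = %.4g%s\n", x$Lambda_I,
                x$Lambda_N,
                if (!is.null(x$tau)) sprintf(" (tau = %g days)", x$tau) else ""))
  cat(sprintf("  alpha = %.4g (one-sided), power = %.3g\n", x$alpha, x$power))
  cat(sprintf("  derived: p_I = %.5g, pi = %.5g\n", x$p_i, x$pi))
  invisible(x)
}

#' Expected cell counts per source-population member
#'
#' Expected counts of the four cells of the vaccination-by-test-result
#' table, per member of the care-seeking source population, over the full
#' study period:
#' \deqn{u_a = p_N(1-VE)(1-e^{-\Lambda_I}), \quad u_b = p_N \Lambda_N,}
#' \deqn{u_c = (1-p_N)(1-e^{-\Lambda_I}), \quad u_d = (1-p_N) \Lambda_N.}
#'
#' @param design A [tnd_design()] built from hazards.
#' @return Named numeric vector `c(a=, b=, c=, d=)`.
#' @export
unit_cell_counts <- function(design) {
  stopifnot(inherits(design, "tnd_design"))
  if (is.null(design$Lambda_I))
    stop_invalid("unit cell counts require hazards; this design was built ",
                 "from a pi override")
  p_n <- design$coverage
  inc <- 1 - exp(-design$Lambda_I)
  c(a = p_n * (1 - design$ve) * inc,
    b = p_n * design$Lambda_N,
    c = (1 - p_n) * inc,
    d = (1 - p_n) * design$Lambda_N)
}

#' Source population size for a target number of tests
#'
#' Size of the care-seeking source population required for a study to
#' accrue `n` tests in roughly one study period, obtained by dividing the
#' target sample size by the sum of expected per-member cell counts and
#' rounding up.
#'
#' @param n Target total number of tests, `>= 1`.
#' @param units Unit cell counts from [unit_cell_counts()].
#' @return Integer population size.
#' @export
source_population_size <- function(n, units) {
  if (n < 1) stop_invalid("n must be at least 1")
  s <- sum(units)
  if (!is.finite(s) || s <= 0)
    stop_invalid("unit cell counts must sum to a positive number")
  as.integer(ceiling(n / s))
}
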