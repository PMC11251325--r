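new_sample_size <- function(method, n, n_exact, design, achieved_power = NA_real_) {
  structure(list(method = method, n = as.integer(n), n_exact = n_exact,
                 achieved_power = achieved_power, design = design),
            class = "tnd_sample_size")
}

#' @export
print.tnd_sample_size <- function(x, ...) {
  cat(sprintf("%s sample size: n = %d total tests (unrounded %.4f)\n",
              x$method, x$n, x$n_exact))
  if (!is.na(x$achieved_power))
    cat(sprintf("  achieved power (binomial-weighted): %.4f\n",
                x$achieved_power))
  invisible(x)
}

# unrounded Wald size, shared with the continuity-corrected formula
wald_n_exact <- function(design) {
  p_i <- design$p_i; p_n <- design$coverage; pi <- design$pi
  if (p_i == p_n) stop_invalid("p_I equals p_N: no vaccine effect to detect")
  za <- stats::qnorm(1 - design$alpha)
  zg <- stats::qnorm(design$power)
  pbar <- pi * p_i + (1 - pi) * p_n
  (za * sqrt(pbar * (1 - pbar)) +
     zg * sqrt((1 - pi) * p_i * (1 - p_i) + pi * p_n * (1 - p_n)))^2 /
    (pi * (1 - pi) * (p_i - p_n)^2)
}

#' Standard Wald sample size
#'
#' Breslow-style sample size for the one-sided Wald test of the odds
#' ratio, re-expressed in TND parameters (`p_I`, `p_N`, percent
#' positivity `pi`):
#' \deqn{n_W = \frac{\{Z_{1-\alpha}\sqrt{\bar p (1-\bar p)} +
#'   Z_{1-\gamma}\sqrt{(1-\pi) p_I(1-p_I) + \pi p_N(1-p_N)}\}^2}
#'   {\pi(1-\pi)(p_I - p_N)^2},}
#' with \eqn{\bar p = \pi p_I + (1-\pi) p_N}. The result is rounded up to
#' the next integer number of tests.
#'
#' @param design A [tnd_design()]; `alpha` and target power are taken from
#'   it.
#' @return A `tnd_sample_size` object with integer `n` (total tests).
#' @examples
#' d <- tnd_design(0.95, 0.3, Lambda_I = 0.1, Lambda_N = 0.2)
#' wald_sample_size(d)$n  # 74
#' @export
wald_sample_size <- function(design) {
  stopifnot(inherits(design, "tnd_design"))
  nx <- wald_n_exact(design)
  new_sample_size("wald", ceiling(nx), nx, design)
}

#' Continuity-corrected (Fleiss) Wald sample size
#'
#' Fleiss' modification of the Wald sample size for use with Yates'
#' continuity correction, applied to the unrounded Wald size `n_W`:
#' \deqn{n_C = \frac{n_W}{4}\left\{1 + \sqrt{1 +
#'   \frac{2}{\pi(1-\pi)\, n_W\, |p_I - p_N|}}\right\}^2.}
#' Always at least as large as the Wald size.
#'
#' @inheritParams wald_sample_size
#' @return A `tnd_sample_size` object.
#' @export
wald_cc_sample_size <- function(design) {
  stopifnot(inherits(design, "tnd_design"))
  nw <- wald_n_exact(design)
  pi <- design$pi
  nx <- nw / 4 *
    (1 + sqrt(1 + 2 / (pi * (1 - pi) * nw * abs(design$p_i - design$coverage))))^2
  new_sample_size("wald_cc", ceiling(nx), nx, design)
}

#' Case-control score sample size
#'
#' Sample size matching the score test, using the null and alternative
#' variances of the score numerator from [score_variances()]:
#' \deqn{n_S = \frac{(Z_{1-\gamma}\sigma_1 + Z_{1-\alpha}\sigma_0)^2}
#'   {(p_I - p_N)^2}.}
#' This treats percent positivity as fixed, as in a case-control study
#' with a designed case:control ratio.
#'
#' @inheritParams wald_sample_size
#' @return A `tnd_sample_size` object.
#' @examples
#' d <- tnd_design(0.95, 0.3, Lambda_I = 0.1, Lambda_N = 0.2)
#' score_sample_size(d)$n  # 63
#' @export
score_sample_size <- function(design) {
  stopifnot(inherits(design, "tnd_design"))
  p_i <- design$p_i; p_n <- design$coverage
  if (p_i == p_n) stop_invalid("p_I equals p_N: no vaccine effect to detect")
  s0 <- sqrt(design$sigma0_sq)
  s1 <- sqrt(design$sigma1_sq)
  nx <- (stats::qnorm(design$power) * s1 +
           stats::qnorm(1 - design$alpha) * s0)^2 / (p_i - p_n)^2
  new_sample_size("score", ceiling(nx), nx, design)
}

#' Binomial-weighted power of the score test in a TND
#'
#' In a TND the number of test-positives among `n` tests is random; this
#' function averages the score test's rejection probability over the
#' binomial distribution of that count:
#' \deqn{1-\gamma(n) = \sum_{k=0}^{n}
#'   \Phi\!\left(\frac{Z_\alpha \sigma_0 - (p_I - p_N)\sqrt{n}}
#'               {\tilde\sigma_1(k/n)}\right)
#'   \binom{n}{k} \pi^k (1-\pi)^{n-k},}
#' with the null variance \eqn{\sigma_0} held at the design percent
#' positivity (it is roughly constant in \eqn{\hat\pi}) and the
#' alternative variance \eqn{\tilde\sigma_1} from
#' [multinomial_variance()] at each realised \eqn{\hat\pi = k/n}. The
#' degenerate tables `k = 0` and `k = n` cannot reject and contribute
#' zero rejection probability.
#'
#' @param n Total number of tests.
#' @param design A [tnd_design()].
#' @return Power in `[0, 1]`.
#' @export
weighted_power <- function(n, design) {
  stopifnot(inherits(design, "tnd_design"))
  if (n < 1 || n != round(n)) stop_invalid("n must be a positive integer")
  p_i <- design$p_i; p_n <- design$coverage; pi <- design$pi
  s0 <- sqrt(design$sigma0_sq)
  za <- stats::qnorm(design$alpha)
  if (n == 1) return(0)
  k <- seq_len(n - 1)
  s1t <- sqrt(multinomial_variance(p_i, p_n, k / n))
  sum(stats::pnorm((za * s0 - (p_i - p_n) * sqrt(n)) / s1t) *
        stats::dbinom(k, n, pi))
}

#' TND-adjusted score sample size
#'
#' The smallest total number of tests at which the binomial-weighted power
#' of [weighted_power()] reaches the design's target power, found by a
#' step-1 grid search upward from the case-control score sample size.
#' Intended for high vaccine effectiveness, where the random
#' positive:negative ratio of the TND erodes the power of the
#' case-control calculation.
#'
#' @inheritParams wald_sample_size
#' @param n_max Upper bound for the grid search; default 10 times the
#'   case-control score size.
#' @return A `tnd_sample_size` object; `achieved_power` holds the weighted
#'   power at the returned `n`.
#' @examples
#' d <- tnd_design(0.95, 0.3, Lambda_I = 0.1, Lambda_N = 0.2)
#' tnd_score_sample_size(d)$n  # 75
#' @export
tnd_score_sample_size <- function(design, n_max = NULL) {
  stopifnot(inherits(design, "tnd_design"))
  n0 <- score_sample_size(design)$n
  if (is.null(n_max)) n_max <- 10L * n0
  target <- design$power
  for (n in seq.int(n0, n_max)) {
    pw <- weighted_power(n, design)
    if (pw >= target)
      return(new_sample_size("tnd_score", n, as.numeric(n), design,
                             achieved_power = pw))
  }
  stop(errorCondition(
    sprintf("weighted power did not reach %.3f by n = %d (last power %.4f)",
            target, n_max, pw),
    class = c("tnd_no_solution", "error")))
}
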