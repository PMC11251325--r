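#' Construct a 2x2 vaccination-by-test-result table
#'
#' Cell counts follow the usual TND layout: `a` vaccinated test-positives,
#' `b` vaccinated test-negatives, `c` unvaccinated test-positives, `d`
#' unvaccinated test-negatives. The vaccine effectiveness estimate is
#' one minus the odds ratio `ad/(bc)`.
#'
#' @param a,b,c,d Non-negative integer cell counts; the total must be at
#'   least 1.
#' @return An object of class `tnd_table`.
#' @examples
#' tnd_table(2, 28, 25, 45)
#' @export
tnd_table <- function(a, b, c, d) {
  cells <- stats::setNames(as.numeric(c(a, b, c, d)), c("a", "b", "c", "d"))
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop_invalid("cell counts must be non-negative integers")
  if (sum(cells) < 1) stop_invalid("the table must contain at least one test")
  structure(as.list(cells), class = "tnd_table")
}

#' @export
print.tnd_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("vaccinated", "unvaccinated"),
                              c("test+", "test-")))
  print(m)
  invisible(x)
}

#' Log odds ratio with optional continuity correction
#'
#' Returns \eqn{\ln[(a+\delta)(d+\delta) / ((b+\delta)(c+\delta))]}. With
#' `delta = 0` the estimator is intractable when any cell is zero and a
#' condition of class `tnd_intractable` is signalled rather than a NaN
#' being returned.
#'
#' @param table A [tnd_table()].
#' @param delta Continuity correction added to each cell, `>= 0`
#'   (Yates' correction is 0.5).
#' @return The (corrected) log odds ratio.
#' @export
log_odds_ratio <- function(table, delta = 0) {
  stopifnot(inherits(table, "tnd_table"))
  if (delta < 0) stop_invalid("delta must be non-negative")
  if (delta == 0 && any(unlist(table) == 0))
    stop(errorCondition(
      "log odds ratio is intractable: zero cell with delta = 0",
      class = c("tnd_intractable", "error")))
  log((table$a + delta) * (table$d + delta) /
        ((table$b + delta) * (table$c + delta)))
}

new_tnd_test <- function(method, statistic, tractable, theta0, alpha) {
  reject <- isTRUE(tractable) && !is.na(statistic) &&
    statistic < stats::qnorm(alpha)
  structure(list(
    method = method,
    statistic = statistic,
    tractable = tractable,
    reject = reject,
    p_value = if (tractable) stats::pnorm(statistic) else NA_real_,
    theta0 = theta0,
    alpha = alpha
  ), class = "tnd_test")
}

#' @export
print.tnd_test <- function(x, ...) {
  cat(sprintf("%s test of H0: OR >= %g vs H1: OR < %g (one-sided alpha = %g)\n",
              x$method, x$theta0, x$theta0, x$alpha))
  if (x$tractable) {
    cat(sprintf("  statistic = %.4f, p = %.4g, reject H0: %s\n",
                x$statistic, x$p_value, x$reject))
  } else {
    cat("  intractable (zero cell or margin); H0 not rejected\n")
  }
  invisible(x)
}

#' Standard Wald test of the odds ratio
#'
#' One-sided Wald test of H0: OR >= `theta0` against H1: OR < `theta0`
#' using the delta-method variance of the log odds ratio,
#' \deqn{T_W = \frac{\ln(ad/bc) - \ln\theta_0}
#'                  {\sqrt{1/a + 1/b + 1/c + 1/d}}.}
#' With any zero cell the statistic is intractable; the result is flagged
#' and counts as a non-rejection.
#'
#' @param table A [tnd_table()].
#' @param theta0 Null odds ratio bound.
#' @param alpha One-sided significance level.
#' @return A `tnd_test` object with fields `statistic`, `tractable`,
#'   `reject`, `p_value`.
#' @examples
#' wald_test(tnd_table(2, 28, 25, 45))
#' @export
wald_test <- function(table, theta0 = 1, alpha = 0.025) {
  stopifnot(inherits(table, "tnd_table"))
  cells <- unlist(table)
  if (any(cells == 0))
    return(new_tnd_test("wald", NA_real_, FALSE, theta0, alpha))
  stat <- (log(table$a * table$d / (table$b * table$c)) - log(theta0)) /
    sqrt(sum(1 / cells))
  new_tnd_test("wald", stat, TRUE, theta0, alpha)
}

#' Continuity-corrected Wald test of the odds ratio
#'
#' The Wald test of [wald_test()] after adding `delta` to every cell:
#' always tractable for `delta > 0`. The default `delta = 0.5` is Yates'
#' correction.
#'
#' @inheritParams wald_test
#' @param delta Continuity correction, `> 0`.
#' @return A `tnd_test` object.
#' @export
wald_cc_test <- function(table, theta0 = 1, alpha = 0.025, delta = 0.5) {
  stopifnot(inherits(table, "tnd_table"))
  if (delta <= 0) stop_invalid("delta must be positive")
  cells <- unlist(table) + delta
  stat <- (log(cells["a"] * cells["d"] / (cells["b"] * cells["c"])) -
             log(theta0)) / sqrt(sum(1 / cells))
  new_tnd_test("wald_cc", unname(stat), TRUE, theta0, alpha)
}

# Constrained intercept of the simple logistic model
# logit P(test+ | x) = b0 + x ln(theta0), x = vaccination indicator,
# solved from the score equation for b0. Monotone in b0, so the root is
# unique whenever both test-result margins are positive.
constrained_intercept <- function(a, b, c, d, theta0, tol = 1e-10) {
  m1 <- a + b   # vaccinated
  m0 <- c + d   # unvaccinated
  npos <- a + c
  g <- function(b0) {
    npos - m1 * stats::plogis(b0 + log(theta0)) - m0 * stats::plogis(b0)
  }
  r <- tryCatch(
    stats::uniroot(g, lower = -50, upper = 50, tol = tol, maxiter = 200,
                   extendInt = "downX"),
    error = function(e) stop(errorCondition(
      paste0("constrained logistic optimum did not converge: ",
             conditionMessage(e)),
      class = c("tnd_numeric_failure", "error"))))
  r$root
}

# Score statistic for general theta0 at the constrained optimum; the
# efficient information profiles out the intercept.
score_stat_general <- function(a, b, c, d, theta0) {
  b0 <- constrained_intercept(a, b, c, d, theta0)
  p1 <- stats::plogis(b0 + log(theta0))
  p0 <- stats::plogis(b0)
  m1 <- a + b
  m0 <- c + d
  U <- a - m1 * p1
  w1 <- m1 * p1 * (1 - p1)
  w0 <- m0 * p0 * (1 - p0)
  info <- w1 - w1^2 / (w1 + w0)
  U / sqrt(info)
}

#' Score test of the odds ratio
#'
#' One-sided score test of H0: OR >= `theta0` based on the likelihood of a
#' simple logistic regression of test result on vaccination status, with
#' the variance of the score evaluated under the null. Because the null
#' fit pools the two groups, the statistic remains tractable when a single
#' cell is zero, as long as all four margins are positive. For
#' `theta0 = 1` the statistic has the closed form
#' \deqn{T_S = \frac{(ad - bc)\sqrt{n}}{\sqrt{(a+c)(b+d)(a+b)(c+d)}}
#'     = \frac{\hat p_I - \hat p_N}{\hat\sigma_0 / \sqrt{n}};}
#' for general `theta0` the intercept is fixed at its constrained maximum
#' (one-dimensional root finding) and the variance comes from the
#' information matrix at that optimum.
#'
#' @inheritParams wald_test
#' @return A `tnd_test` object.
#' @examples
#' score_test(tnd_table(0, 30, 20, 50))  # tractable despite the zero cell
#' @export
score_test <- function(table, theta0 = 1, alpha = 0.025) {
  stopifnot(inherits(table, "tnd_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    return(new_tnd_test("score", NA_real_, FALSE, theta0, alpha))
  if (theta0 == 1) {
    n <- a + b + c + d
    stat <- (a * d - b * c) * sqrt(n) /
      sqrt(prod(as.numeric(margins)))
  } else {
    stat <- score_stat_general(a, b, c, d, theta0)
  }
  new_tnd_test("score", stat, TRUE, theta0, alpha)
}

# Vectorised statistics over replicate cell-count vectors; intractable
# entries come back NA. Used by the Monte-Carlo layer.
wald_stat_vec <- function(a, b, c, d, theta0 = 1) {
  stat <- (log(a * d / (b * c)) - log(theta0)) /
    sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  stat[a == 0 | b == 0 | c == 0 | d == 0] <- NA_real_
  stat
}

wald_cc_stat_vec <- function(a, b, c, d, theta0 = 1, delta = 0.5) {
  a <- a + delta; b <- b + delta; c <- c + delta; d <- d + delta
  (log(a * d / (b * c)) - log(theta0)) /
    sqrt(1 / a + 1 / b + 1 / c + 1 / d)
}

score_stat_vec <- function(a, b, c, d, theta0 = 1) {
  if (theta0 == 1) {
    n <- a + b + c + d
    stat <- (a * d - b * c) * sqrt(n) /
      sqrt((a + c) * (b + d) * (a + b) * (c + d))
  } else {
    stat <- mapply(function(a, b, c, d) {
      if (min(a + b, c + d, a + c, b + d) == 0) return(NA_real_)
      score_stat_general(a, b, c, d, theta0)
    }, a, b, c, d)
  }
  stat[(a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0] <- NA_real_
  stat
}
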