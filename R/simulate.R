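round_half_up <- function(x) floor(x + 0.5)

#' Build a vaccinated source-population cohort
#'
#' Assigns vaccination by exact count (`round(N * coverage)` individuals,
#' half rounded up) by simple random sampling, and all-or-none protection
#' to `round(n_vaccinated * ve)` of the vaccinated: protected individuals
#' cannot test positive, the remaining vaccinated share the unvaccinated
#' hazard.
#'
#' @param N Source population size, at least one vaccinated and one
#'   unvaccinated individual.
#' @param coverage Vaccination coverage, in (0, 1).
#' @param ve Vaccine effectiveness (all-or-none), in `[0, 1]`.
#' @param seed Optional RNG seed; if `NULL` the current RNG state is used.
#' @return An object of class `tnd_cohort`: list with `N` and logical
#'   vectors `vaccinated`, `protected`.
#' @export
build_cohort <- function(N, coverage, ve, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (N < 2) stop_invalid("N must be at least 2")
  n_vacc <- round_half_up(N * coverage)
  if (n_vacc < 1 || n_vacc > N - 1)
    stop_invalid("N too small to hold both vaccinated and unvaccinated ",
                 "individuals at this coverage")
  n_prot <- round_half_up(n_vacc * ve)
  vacc_idx <- sample.int(N, n_vacc)
  prot_idx <- if (n_prot > 0) vacc_idx[sample.int(n_vacc, n_prot)] else integer(0)
  vaccinated <- logical(N); vaccinated[vacc_idx] <- TRUE
  protected <- logical(N); protected[prot_idx] <- TRUE
  structure(list(N = N, vaccinated = vaccinated, protected = protected),
            class = "tnd_cohort")
}

#' Generate test events for a cohort
#'
#' Simulates the two illness processes over the study period `(0, tau]`:
#' each unprotected individual draws a single potential test-positive time
#' from an exponential distribution with rate `lambda_i`, kept if it falls
#' within the period (so the attack proportion is \eqn{1 - e^{-\Lambda_I}});
#' every individual accrues test-negative events as a homogeneous Poisson
#' process with rate `lambda_n`, truncated to the first `max_negatives`
#' arrivals. Testing positive does not remove an individual from the
#' test-negative process, and vaccination does not affect test-negative
#' illness.
#'
#' @param cohort A [build_cohort()] result.
#' @param lambda_i,lambda_n Constant hazards per day.
#' @param tau Study period in days.
#' @param max_negatives Maximum number of negative tests retained per
#'   individual (later arrivals are disregarded).
#' @param seed Optional RNG seed.
#' @return An object of class `tnd_events`: parallel vectors `id`, `time`,
#'   `positive`, `vaccinated`, plus `tau` and the count of disregarded
#'   negative events `n_truncated`.
#' @export
generate_test_events <- function(cohort, lambda_i, lambda_n, tau,
                                 max_negatives = 3, seed = NULL) {
  stopifnot(inherits(cohort, "tnd_cohort"))
  if (!is.null(seed)) set.seed(seed)
  if (lambda_i < 0 || lambda_n < 0 || tau <= 0)
    stop_invalid("hazards must be non-negative and tau positive")
  N <- cohort$N

  # positives: one potential event per unprotected individual
  at_risk <- which(!cohort$protected)
  if (lambda_i > 0 && length(at_risk)) {
    tp <- stats::rexp(length(at_risk), rate = lambda_i)
    keep <- tp <= tau
    pos_id <- at_risk[keep]
    pos_t <- tp[keep]
  } else {
    pos_id <- integer(0); pos_t <- numeric(0)
  }

  # negatives: Poisson process, first max_negatives arrivals kept
  n_trunc <- 0L
  if (lambda_n > 0) {
    k <- stats::rpois(N, lambda_n * tau)
    kk <- k[k > 0]
    neg_id <- rep.int(which(k > 0), kk)
    neg_t <- stats::runif(length(neg_id), 0, tau)
    if (any(kk > max_negatives)) {
      ends <- cumsum(kk)
      starts <- ends - kk + 1L
      over <- which(kk > max_negatives)
      drop <- unlist(lapply(over, function(j) {
        idx <- starts[j]:ends[j]
        idx[order(neg_t[idx])][-seq_len(max_negatives)]
      }))
      n_trunc <- length(drop)
      neg_id <- neg_id[-drop]
      neg_t <- neg_t[-drop]
    }
  } else {
    neg_id <- integer(0); neg_t <- numeric(0)
  }

  id <- c(pos_id, neg_id)
  structure(list(
    id = id,
    time = c(pos_t, neg_t),
    positive = rep(c(TRUE, FALSE), c(length(pos_id), length(neg_id))),
    vaccinated = cohort$vaccinated[id],
    tau = tau,
    n_truncated = n_trunc
  ), class = "tnd_events")
}

tabulate_study <- function(vaccinated, positive) {
  c(a = sum(vaccinated & positive),
    b = sum(vaccinated & !positive),
    c = sum(!vaccinated & positive),
    d = sum(!vaccinated & !positive))
}

new_sampled_study <- function(cells, design, duration, truncated = FALSE) {
  n <- sum(cells)
  structure(list(
    table = tnd_table(cells["a"], cells["b"], cells["c"], cells["d"]),
    design = design,
    realized_duration = duration,
    realized_pi = unname((cells["a"] + cells["c"]) / n),
    truncated = truncated
  ), class = "tnd_study")
}

#' Sample a test-negative design study from an event log
#'
#' Pools positive and negative test events, orders them in time (ties
#' broken uniformly at random) and enrols the first `n` tests, mirroring
#' the passive stopping rule of a TND: the total number of tests is fixed,
#' the positive:negative split is random. If fewer than `n` events occur
#' by the end of the period, all events are returned and the study is
#' flagged truncated.
#'
#' @param events A [generate_test_events()] log.
#' @param n Target total number of tests.
#' @return A `tnd_study`: list with `table` ([tnd_table()]), `design`,
#'   `realized_duration` (time of the last enrolled test), `realized_pi`
#'   and `truncated`.
#' @export
sample_tnd <- function(events, n) {
  stopifnot(inherits(events, "tnd_events"))
  if (n < 1) stop_invalid("n must be at least 1")
  m <- length(events$time)
  ord <- order(events$time, stats::runif(m))
  take <- ord[seq_len(min(n, m))]
  cells <- tabulate_study(events$vaccinated[take], events$positive[take])
  new_sampled_study(cells, "tnd",
                    duration = if (length(take)) max(events$time[take]) else 0,
                    truncated = m < n)
}

#' Sample a matched case-control study from an event log
#'
#' Fixes the case:control split at the design percent positivity: the
#' first `round(n * pi)` positive tests in time are the cases, and
#' `n - round(n * pi)` controls are drawn by simple random sampling
#' without replacement from all negative test events of the period.
#'
#' @param events A [generate_test_events()] log.
#' @param n Total study size.
#' @param pi Designed fraction of positives (cases) among the `n`.
#' @return A `tnd_study` (see [sample_tnd()]); its `realized_pi` is fixed
#'   at `round(n * pi) / n` by construction.
#' @export
sample_case_control <- function(events, n, pi) {
  stopifnot(inherits(events, "tnd_events"))
  if (n < 1) stop_invalid("n must be at least 1")
  if (pi <= 0 || pi >= 1) stop_invalid("pi must lie strictly in (0, 1)")
  n_pos <- round_half_up(n * pi)
  n_neg <- n - n_pos
  pos <- which(events$positive)
  neg <- which(!events$positive)
  if (length(pos) < n_pos || length(neg) < n_neg)
    stop(errorCondition(
      sprintf("insufficient events: need %d positives (have %d), %d negatives (have %d)",
              n_pos, length(pos), n_neg, length(neg)),
      class = c("tnd_insufficient_events", "error")))
  take_pos <- pos[order(events$time[pos])][seq_len(n_pos)]
  take_neg <- neg[sample.int(length(neg), n_neg)]
  take <- c(take_pos, take_neg)
  cells <- tabulate_study(events$vaccinated[take], events$positive[take])
  new_sampled_study(cells, "case_control",
                    duration = max(events$time[take]))
}

#' Simulate replicate 2x2 study tables
#'
#' Runs the full generative pipeline (cohort, event times, study sampling)
#' `reps` times. The source population is sized with
#' [source_population_size()] so that about `n` tests accrue in one study
#' period. Each replicate runs on its own seed derived from `seed`, so any
#' replicate is reproducible in isolation; case-control replicates with
#' insufficient events are redrawn within their stream (the redraw count
#' is recorded).
#'
#' Both stopping rules are count-based, so the realised study duration is
#' random (about one study period by construction of the population
#' size). Events are therefore generated over an observation window of
#' `horizon_factor` study periods, from which the samplers take what the
#' stopping rules dictate; a replicate is flagged truncated only in the
#' rare case that even the extended window holds fewer than `n` events.
#'
#' @param design A [tnd_design()] built from hazards.
#' @param study `"tnd"` or `"case_control"`.
#' @param n Total tests per replicate.
#' @param reps Number of replicates.
#' @param seed Root RNG seed.
#' @param n_source Optional source population size override.
#' @param horizon_factor Length of the event-generation window in study
#'   periods.
#' @return A data.frame with one row per replicate: `a`, `b`, `c`, `d`,
#'   `realized_pi`, `duration`, `truncated`, `redraws`. Attributes carry
#'   the scenario (`design`, `study`, `n`, `N`, `seed`).
#' @export
simulate_tables <- function(design, study = c("tnd", "case_control"),
                            n, reps, seed, n_source = NULL,
                            horizon_factor = 3) {
  stopifnot(inherits(design, "tnd_design"))
  study <- match.arg(study)
  if (is.null(design$lambda_i) && is.null(design$Lambda_I))
    stop_invalid("simulation requires a design built from hazards")
  tau <- if (!is.null(design$tau)) design$tau else 1
  lambda_i <- if (!is.null(design$lambda_i)) design$lambda_i else design$Lambda_I / tau
  lambda_n <- if (!is.null(design$lambda_n)) design$lambda_n else design$Lambda_N / tau
  if (is.null(n_source))
    n_source <- source_population_size(n, unit_cell_counts(design))

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  out <- matrix(0, nrow = reps, ncol = 8,
                dimnames = list(NULL, c("a", "b", "c", "d", "realized_pi",
                                        "duration", "truncated", "redraws")))
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    redraws <- 0L
    repeat {
      cohort <- build_cohort(n_source, design$coverage, design$ve)
      events <- generate_test_events(cohort, lambda_i, lambda_n,
                                     tau * horizon_factor)
      st <- if (study == "tnd") {
        sample_tnd(events, n)
      } else {
        tryCatch(sample_case_control(events, n, design$pi),
                 tnd_insufficient_events = function(e) NULL)
      }
      if (!is.null(st)) break
      redraws <- redraws + 1L
      if (redraws > 100L)
        stop(errorCondition(
          "case-control sampling failed in over 100 redraws; the source population is too small",
          class = c("tnd_numeric_failure", "error")))
    }
    tb <- st$table
    out[r, ] <- c(tb$a, tb$b, tb$c, tb$d, st$realized_pi,
                  st$realized_duration, as.integer(st$truncated), redraws)
  }
  out <- as.data.frame(out)
  out$truncated <- as.logical(out$truncated)
  attr(out, "scenario") <- list(design = design, study = study, n = n,
                                N = n_source, seed = seed, reps = reps)
  out
}
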