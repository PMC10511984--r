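#' One-step log-rank rate ratio for a two-arm comparison
#'
#' Intention-to-treat comparison of active versus control by the standard
#' log-rank method: at each distinct event time the expected number of
#' active-arm events and the hypergeometric variance are accumulated over
#' the risk sets (ties handled in aggregate per distinct time), giving
#' observed minus expected \eqn{O - E} and variance \eqn{V}. The one-step
#' estimator is \eqn{RR = \exp((O - E)/V)} with
#' \eqn{CI = \exp((O - E \pm z \sqrt{V})/V)} — the closed-form estimator
#' used in large streamlined trials, asymptotically equivalent to the Cox
#' partial-likelihood estimate.
#'
#' @param data data.frame with columns `arm` (`"active"`/`"control"`),
#'   `event` (logical or 0/1) and `time` (time at risk, >= 0; any unit).
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `rate_ratio`: `rr`, `ci` (length-2),
#'   `observed_minus_expected`, `variance`, `events_by_arm`,
#'   `person_time_by_arm`, `n_by_arm`.
#' @examples
#' d <- data.frame(arm = c("active", "active", "control", "control"),
#'                 event = c(TRUE, TRUE, TRUE, FALSE),
#'                 time = c(1, 2, 3, 4))
#' logrank_rr(d)
#' @export
logrank_rr <- function(data, conf_level = 0.95) {
  stopifnot(all(c("arm", "event", "time") %in% names(data)))
  arm <- as.character(data$arm)
  if (!all(arm %in% c("active", "control")))
    stop2("arm must be 'active' or 'control'")
  event <- as.logical(data$event)
  time <- as.numeric(data$time)
  if (any(time < 0)) stop2("negative time at risk")
  if (!any(event)) stop2("no events in either arm")

  ut <- sort(unique(time[event]))
  st <- sort(time)
  st_a <- sort(time[arm == "active"])
  # at risk at t = number with time >= t; findInterval(.., left.open) counts
  # strictly smaller elements
  n_tot <- length(st) - findInterval(ut, st, left.open = TRUE)
  n_act <- length(st_a) - findInterval(ut, st_a, left.open = TRUE)
  et <- time[event]
  d_tot <- as.numeric(table(factor(et, levels = ut)))
  d_act <- as.numeric(table(factor(et[arm[event] == "active"], levels = ut)))

  frac <- n_act / n_tot
  o <- sum(d_act)
  e <- sum(d_tot * frac)
  v <- sum(d_tot * frac * (1 - frac) *
             ifelse(n_tot > 1, (n_tot - d_tot) / (n_tot - 1), 0))
  if (v <= 0) {
    warning("log-rank variance is zero: rate ratio undefined", call. = FALSE)
    rr <- ci <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    rr <- exp((o - e) / v)
    ci <- exp((o - e + c(-1, 1) * z * sqrt(v)) / v)
  }
  structure(list(rr = rr, ci = ci, observed_minus_expected = o - e,
                 variance = v,
                 events_by_arm = c(active = o,
                                   control = sum(d_tot) - o),
                 person_time_by_arm = c(active = sum(time[arm == "active"]),
                                        control = sum(time[arm == "control"])),
                 n_by_arm = c(active = sum(arm == "active"),
                              control = sum(arm == "control")),
                 conf_level = conf_level),
            class = "rate_ratio")
}

#' @export
print.rate_ratio <- function(x, ...) {
  cat(sprintf(
    "Log-rank rate ratio (active vs control): %.2f (%.0f%% CI %.2f to %.2f)\n",
    x$rr, 100 * x$conf_level, x$ci[1], x$ci[2]))
  cat(sprintf("  events: %d vs %d; O-E = %.2f, V = %.2f\n",
              x$events_by_arm[["active"]], x$events_by_arm[["control"]],
              x$observed_minus_expected, x$variance))
  invisible(x)
}

#' Absolute treatment effect per 5000 person-years
#'
#' Difference of crude arm-specific event rates, scaled to events per
#' `per` person-years, with the mean standard error from the
#' independent-Poisson approximation for the arm-wise event counts:
#' \eqn{SE = per \cdot \sqrt{d_a / PY_a^2 + d_c / PY_c^2}}.
#'
#' @param data_active,data_control either data.frames with `event` and
#'   `time` columns (time in days unless `time_unit_days = 1`), or lists
#'   with elements `events` and `person_years`.
#' @param per person-year denominator of the reported excess (default
#'   5000).
#' @param time_unit_days days per unit of the `time` column (default
#'   365.25 converts day-scale times to person-years; it is a divisor, so
#'   pass 1 if `time` is already in years).
#' @return An object of class `absolute_effect`: `excess`, `se`, `per`,
#'   `rates_by_arm` (events per person-year), `events`, `person_years`.
#' @examples
#' absolute_excess(list(events = 314, person_years = 57000),
#'                 list(events = 245, person_years = 57000))
#' @export
absolute_excess <- function(data_active, data_control, per = 5000,
                            time_unit_days = 365.25) {
  summarise <- function(d) {
    if (is.data.frame(d))
      list(events = sum(as.logical(d$event)),
           person_years = sum(as.numeric(d$time)) / time_unit_days)
    else list(events = d$events, person_years = d$person_years)
  }
  a <- summarise(data_active); c_ <- summarise(data_control)
  if (a$person_years <= 0 || c_$person_years <= 0)
    stop2("zero person-years in an arm")
  ra <- a$events / a$person_years
  rc <- c_$events / c_$person_years
  structure(list(
    excess = per * (ra - rc),
    se = per * sqrt(a$events / a$person_years^2 +
                      c_$events / c_$person_years^2),
    per = per, rates_by_arm = c(active = ra, control = rc),
    events = c(active = a$events, control = c_$events),
    person_years = c(active = a$person_years, control = c_$person_years)),
    class = "absolute_effect")
}

#' @export
print.absolute_effect <- function(x, ...) {
  cat(sprintf("Absolute effect: %+.1f events per %d person-years (mean SE %.1f)\n",
              x$excess, x$per, x$se))
  cat(sprintf("  active %d events / %.0f py; control %d events / %.0f py\n",
              x$events[["active"]], x$person_years[["active"]],
              x$events[["control"]], x$person_years[["control"]]))
  invisible(x)
}

#' Bootstrap CI for the difference between two sources' rate ratios
#'
#' Resamples participants with replacement — keeping each participant's
#' records in both sources together, so within-participant correlation
#' between sources is preserved — recomputes both log-rank rate ratios per
#' replicate, and returns the percentile CI for the difference
#' (source A minus source B, on the rate-ratio scale). Replicates in which
#' either source has no events in some arm or zero log-rank variance are
#' skipped and counted; more than 10% skipped triggers a warning.
#'
#' @param outcomes_a,outcomes_b outcome tables from [derive_outcomes()]
#'   for the two sources, covering the same participants.
#' @param n_boot number of bootstrap replicates (>= 100; default 2000).
#' @param seed integer seed (mandatory, for reproducibility).
#' @param conf_level confidence level.
#' @return An object of class `rr_difference`: `difference`, `ci`,
#'   `rr_a`, `rr_b`, `n_boot`, `n_skipped`, `seed`.
#' @export
rr_difference_bootstrap <- function(outcomes_a, outcomes_b, n_boot = 2000,
                                    seed, conf_level = 0.95) {
  if (missing(seed)) stop2("seed is required")
  if (n_boot < 100) stop2("n_boot must be >= 100")
  a <- outcomes_a[order(outcomes_a$participant_id), ]
  b <- outcomes_b[order(outcomes_b$participant_id), ]
  if (nrow(a) != nrow(b) || !all(a$participant_id == b$participant_id))
    stop2("rr_difference_bootstrap: participant sets differ")
  n <- nrow(a)
  sa <- as_surv_data(a); sb <- as_surv_data(b)
  rr_a <- logrank_rr(sa, conf_level)$rr
  rr_b <- logrank_rr(sb, conf_level)$rr

  diffs <- rep(NA_real_, n_boot)
  with_seed(seed, {
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      da <- sa[idx, ]; db <- sb[idx, ]
      ok <- all(tapply(da$event, da$arm, sum) > 0) &&
        all(tapply(db$event, db$arm, sum) > 0) &&
        length(unique(da$arm)) == 2 && length(unique(db$arm)) == 2
      if (!ok) next
      ra <- suppressWarnings(logrank_rr(da, conf_level)$rr)
      rb <- suppressWarnings(logrank_rr(db, conf_level)$rr)
      if (is.na(ra) || is.na(rb)) next
      diffs[i] <- ra - rb
    }
  })
  n_skipped <- sum(is.na(diffs))
  if (n_skipped > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates skipped (degenerate resample)",
                    n_skipped, n_boot), call. = FALSE)
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2),
                               na.rm = TRUE, type = 6))
  structure(list(difference = rr_a - rr_b, ci = ci, rr_a = rr_a, rr_b = rr_b,
                 n_boot = n_boot, n_skipped = n_skipped, seed = seed,
                 conf_level = conf_level),
            class = "rr_difference")
}

#' @export
print.rr_difference <- function(x, ...) {
  cat(sprintf(
    "RR difference (A - B): %+.2f (%.0f%% bootstrap CI %+.2f to %+.2f)\n",
    x$difference, 100 * x$conf_level, x$ci[1], x$ci[2]))
  cat(sprintf("  RR A = %.2f, RR B = %.2f; %d replicates (%d skipped), seed %d\n",
              x$rr_a, x$rr_b, x$n_boot, x$n_skipped, x$seed))
  invisible(x)
}

#' Re-run the randomised comparison under each severity algorithm
#'
#' For every algorithm in the grid, classifies the cohort's routine
#' bleeding events, derives routine-source first-event outcomes and
#' computes the log-rank rate ratio. Rows are ordered by
#' [algorithm_strictness()], so the attenuation of the treatment effect as
#' severity restrictions are dropped reads top to bottom.
#'
#' @param cohort a `bleed_cohort` (or any list with `participants`,
#'   `hospital_episodes`, `death_records`).
#' @param algorithms list of [severity_algorithm()] objects (default
#'   [algorithm_grid()]).
#' @param code_map bleeding [bleed_code_map()].
#' @param outcome outcome name passed to [derive_outcomes()].
#' @return data.frame of class `algorithm_sweep`: one row per algorithm
#'   with `algorithm`, `strictness`, `rr`, `ci_lo`, `ci_hi`,
#'   `events_active`, `events_control`.
#' @export
algorithm_sweep <- function(cohort, algorithms = algorithm_grid(),
                            code_map = default_bleed_code_map(),
                            outcome = "any_major_bleed") {
  if (!length(algorithms)) stop2("empty algorithm grid")
  events <- extract_routine_bleeds(cohort$hospital_episodes,
                                   cohort$death_records, code_map)
  rows <- lapply(algorithms, function(alg) {
    cl <- classify_severity(events, alg)
    oc <- derive_outcomes(cl, cohort$participants, "routine", outcome)
    rr <- logrank_rr(as_surv_data(oc))
    data.frame(algorithm = alg$name,
               strictness = algorithm_strictness(alg),
               rr = rr$rr, ci_lo = rr$ci[1], ci_hi = rr$ci[2],
               events_active = rr$events_by_arm[["active"]],
               events_control = rr$events_by_arm[["control"]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strictness, out$algorithm), ]
  rownames(out) <- NULL
  class(out) <- c("algorithm_sweep", "data.frame")
  out
}
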