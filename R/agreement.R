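#' Two-by-two cross-classification of participants across data sources
#'
#' `bleed_crosstab()` builds the four-cell table directly from counts;
#' `cross_classify()` builds it from two per-participant outcome tables
#' covering the same cohort. Classification is by presence/absence of the
#' outcome in each source, irrespective of the relative timing of the
#' events (timing is examined separately by [timing_concordance()]).
#'
#' @param both participants with the outcome in both sources.
#' @param routine_only participants with the outcome in routine data only.
#' @param adjudicated_only participants with the outcome in adjudicated
#'   follow-up only.
#' @param neither participants with the outcome in neither source.
#' @return An object of class `bleed_crosstab` with the four counts and the
#'   total `n`.
#' @examples
#' tab <- bleed_crosstab(318, 281, 241, 14640)
#' kappa_stat(tab)
#' sens_spec(tab)
#' @export
bleed_crosstab <- function(both, routine_only, adjudicated_only, neither) {
  cells <- c(both = both, routine_only = routine_only,
             adjudicated_only = adjudicated_only, neither = neither)
  if (any(is.na(cells)) || any(cells < 0))
    stop2("crosstab cells must be non-negative counts")
  structure(list(both = both, routine_only = routine_only,
                 adjudicated_only = adjudicated_only, neither = neither,
                 n = sum(cells)),
            class = "bleed_crosstab")
}

#' @param routine_outcomes,adjudicated_outcomes per-participant outcome
#'   tables from [derive_outcomes()] for the two sources; must cover the
#'   same participant set.
#' @rdname bleed_crosstab
#' @export
cross_classify <- function(routine_outcomes, adjudicated_outcomes) {
  r <- routine_outcomes[order(routine_outcomes$participant_id), ]
  a <- adjudicated_outcomes[order(adjudicated_outcomes$participant_id), ]
  if (nrow(r) != nrow(a) || !all(r$participant_id == a$participant_id))
    stop2("cross_classify: the two outcome tables cover different participant sets")
  bleed_crosstab(sum(r$has_event & a$has_event),
                 sum(r$has_event & !a$has_event),
                 sum(!r$has_event & a$has_event),
                 sum(!r$has_event & !a$has_event))
}

#' @export
print.bleed_crosstab <- function(x, ...) {
  m <- matrix(c(x$both, x$routine_only, x$adjudicated_only, x$neither),
              2, 2, byrow = TRUE,
              dimnames = list(routine = c("event", "no event"),
                              adjudicated = c("event", "no event")))
  cat("Cross-classification of", x$n, "participants (routine rows,",
      "adjudicated columns)\n")
  print(m)
  invisible(x)
}

crosstab_props <- function(tab) {
  with(tab, {
    po <- (both + neither) / n
    p_routine <- (both + routine_only) / n
    p_adj <- (both + adjudicated_only) / n
    pe <- p_routine * p_adj + (1 - p_routine) * (1 - p_adj)
    list(po = po, pe = pe)
  })
}

#' Cohen's kappa for a two-source cross-classification
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' chance agreement \eqn{p_e} from the row/column margins. The 95% CI uses
#' Cohen's large-sample standard error
#' \eqn{\sqrt{p_o (1 - p_o) / (n (1 - p_e)^2)}} with a normal
#' approximation, the form that reproduces published agreement tables for
#' linked trial data; bounds are clipped to \eqn{[-1, 1]}. Degenerate
#' margins (\eqn{p_e = 1}) leave kappa undefined and are reported as `NA`
#' with a warning.
#'
#' @param table a [bleed_crosstab()].
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `kappa_stat`: `kappa`, `se`, `ci` (length-2),
#'   `n`.
#' @examples
#' kappa_stat(bleed_crosstab(318, 281, 241, 14640))  # 0.53 (0.49 to 0.57)
#' @export
kappa_stat <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "bleed_crosstab"))
  if (table$n == 0) stop2("kappa undefined for an empty table")
  p <- crosstab_props(table)
  if (1 - p$pe < .Machine$double.eps^0.5) {
    warning("kappa undefined: degenerate margins (chance agreement = 1)",
            call. = FALSE)
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          ci = c(NA_real_, NA_real_), n = table$n,
                          conf_level = conf_level),
                     class = "kappa_stat"))
  }
  k <- (p$po - p$pe) / (1 - p$pe)
  se <- sqrt(p$po * (1 - p$po) / (table$n * (1 - p$pe)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(k + c(-1, 1) * z * se, -1), 1)
  structure(list(kappa = k, se = se, ci = ci, n = table$n,
                 conf_level = conf_level),
            class = "kappa_stat")
}

#' @export
print.kappa_stat <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.2f (%.0f%% CI %.2f to %.2f), n = %d\n",
              round_half_up(x$kappa, 2), 100 * x$conf_level,
              round_half_up(x$ci[1], 2), round_half_up(x$ci[2], 2), x$n))
  invisible(x)
}

#' Sensitivity and specificity of routine-data ascertainment
#'
#' Treats adjudicated direct follow-up as the reference:
#' sensitivity = both / (both + adjudicated_only),
#' specificity = neither / (neither + routine_only). Default CIs are Wald
#' binomial intervals (clipped to \eqn{[0, 1]}), matching published linked
#' trial tables; Wilson and exact (Clopper-Pearson) intervals are available
#' as options. A zero denominator leaves the statistic `NA` with a warning.
#'
#' @param table a [bleed_crosstab()].
#' @param conf_level confidence level.
#' @param method `"wald"`, `"wilson"` or `"exact"`.
#' @return An object of class `sens_spec`: `sensitivity`, `specificity`,
#'   each a list with `estimate`, `ci`, `x` (numerator), `n` (denominator).
#' @examples
#' sens_spec(bleed_crosstab(318, 281, 241, 14640))  # 56.9% / 98.1%
#' @export
sens_spec <- function(table, conf_level = 0.95,
                      method = c("wald", "wilson", "exact")) {
  stopifnot(inherits(table, "bleed_crosstab"))
  method <- match.arg(method)
  one <- function(x, n, what) {
    if (n == 0) {
      warning(what, " undefined: zero reference denominator", call. = FALSE)
      return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                  x = x, n = n))
    }
    p <- x / n
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- switch(method,
                 wald = p + c(-1, 1) * z * sqrt(p * (1 - p) / n),
                 wilson = {
                   den <- 1 + z^2 / n
                   ctr <- (p + z^2 / (2 * n)) / den
                   hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
                   ctr + c(-1, 1) * hw
                 },
                 exact = as.numeric(stats::binom.test(
                   x, n, conf.level = conf_level)$conf.int))
    list(estimate = p, ci = pmin(pmax(ci, 0), 1), x = x, n = n)
  }
  structure(list(
    sensitivity = one(table$both, table$both + table$adjudicated_only,
                      "sensitivity"),
    specificity = one(table$neither, table$neither + table$routine_only,
                      "specificity"),
    conf_level = conf_level, method = method),
    class = "sens_spec")
}

#' @export
print.sens_spec <- function(x, ...) {
  f <- function(s, nm)
    cat(sprintf("%s: %s (%.0f%% CI %s to %s) [%d/%d]\n", nm,
                fmt_pct(s$estimate), 100 * x$conf_level, fmt_pct(s$ci[1]),
                fmt_pct(s$ci[2]), s$x, s$n))
  f(x$sensitivity, "Sensitivity")
  f(x$specificity, "Specificity")
  invisible(x)
}

#' Agreement summary for one outcome
#'
#' Convenience wrapper bundling [kappa_stat()] and [sens_spec()] for one
#' cross-classification, printed in the layout of a published agreement
#' table row.
#'
#' @inheritParams sens_spec
#' @return list of class `agreement_stats` with elements `table`, `kappa`,
#'   `sens_spec`.
#' @export
agreement_stats <- function(table, conf_level = 0.95,
                            method = c("wald", "wilson", "exact")) {
  structure(list(table = table,
                 kappa = kappa_stat(table, conf_level),
                 sens_spec = sens_spec(table, conf_level, method)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  with(x$table, cat(sprintf(
    "both %d | routine only %d | adjudicated only %d | neither %d (n = %d)\n",
    both, routine_only, adjudicated_only, neither, n)))
  print(x$sens_spec)
  print(x$kappa)
  invisible(x)
}

#' Timing concordance of first events seen in both sources
#'
#' Among participants with the outcome in *both* sources, the proportion
#' whose first-event dates differ by at most `window_days` (default 90).
#' Participants seen in one source only are ignored: this quantifies date
#' agreement, not capture.
#'
#' @param routine_outcomes,adjudicated_outcomes outcome tables from
#'   [derive_outcomes()] over the same participants.
#' @param window_days non-negative window in days.
#' @return list of class `timing_concordance`: `proportion` (`NA` when no
#'   participant is in both sources), `concordant`, `n_both`, `window_days`.
#' @export
timing_concordance <- function(routine_outcomes, adjudicated_outcomes,
                               window_days = 90) {
  stopifnot(window_days >= 0)
  r <- routine_outcomes[order(routine_outcomes$participant_id), ]
  a <- adjudicated_outcomes[order(adjudicated_outcomes$participant_id), ]
  if (nrow(r) != nrow(a) || !all(r$participant_id == a$participant_id))
    stop2("timing_concordance: participant sets differ")
  both <- r$has_event & a$has_event
  diffs <- abs(as.numeric(r$first_event_date[both]) -
                 as.numeric(a$first_event_date[both]))
  structure(list(
    proportion = if (sum(both)) mean(diffs <= window_days) else NA_real_,
    concordant = sum(diffs <= window_days), n_both = sum(both),
    window_days = window_days),
    class = "timing_concordance")
}

#' @export
print.timing_concordance <- function(x, ...) {
  if (is.na(x$proportion))
    cat("Timing concordance undefined: no participant with the outcome in both sources\n")
  else
    cat(sprintf(
      "First-event dates within %d days for %d of %d both-source participants (%s)\n",
      x$window_days, x$concordant, x$n_both, fmt_pct(x$proportion)))
  invisible(x)
}

#' Break down the discordant cells of a cross-classification
#'
#' Explains *why* the two sources disagree, participant by participant,
#' using the underlying records within `window_days` of the discordant
#' source's first event date. Each discordant participant is assigned to
#' exactly one sub-category by the first matching rule, so the splits
#' always sum to their cell totals.
#'
#' Adjudicated-only participants (rules in order): a routine bleeding-code
#' record is present within the window but did not qualify as major
#' (`bleed_code_not_major`); a hospital episode exists within the window
#' but carries no bleeding code (`hospitalised_no_bleed_code`); otherwise
#' `no_hospital_record`.
#'
#' Routine-only participants: a direct-follow-up major-bleed report within
#' the window was refuted on adjudication (`refuted_within_window`); a
#' minor bleed was reported within the window (`minor_within_window`); no
#' direct report of any kind within the window
#' (`no_hospitalisation_reported`); otherwise `other`.
#'
#' @param routine_outcomes,adjudicated_outcomes outcome tables from
#'   [derive_outcomes()] over the same participants.
#' @param routine_bleeds classified routine bleeding events
#'   ([classify_severity()] output) for the cohort, all severities.
#' @param hospital_episodes the full hospital-episode table.
#' @param direct_reports the direct follow-up report table.
#' @param window_days non-negative window in days (default 90).
#' @return list of class `discordance_breakdown` with integer vectors
#'   `adjudicated_only` and `routine_only` plus the window and cell totals.
#' @export
discordance_breakdown <- function(routine_outcomes, adjudicated_outcomes,
                                  routine_bleeds, hospital_episodes,
                                  direct_reports, window_days = 90) {
  stopifnot(window_days >= 0)
  r <- routine_outcomes[order(routine_outcomes$participant_id), ]
  a <- adjudicated_outcomes[order(adjudicated_outcomes$participant_id), ]
  if (nrow(r) != nrow(a) || !all(r$participant_id == a$participant_id))
    stop2("discordance_breakdown: participant sets differ")

  near <- function(dates, ref) abs(as.numeric(dates) - as.numeric(ref)) <=
    window_days

  adj_only <- which(!r$has_event & a$has_event)
  asplit <- c(bleed_code_not_major = 0L, hospitalised_no_bleed_code = 0L,
              no_hospital_record = 0L)
  for (i in adj_only) {
    pid <- r$participant_id[i]; ref <- a$first_event_date[i]
    bc <- routine_bleeds[routine_bleeds$participant_id == pid, ]
    if (nrow(bc) && any(near(bc$event_date, ref)))
      asplit["bleed_code_not_major"] <- asplit["bleed_code_not_major"] + 1L
    else {
      he <- hospital_episodes[hospital_episodes$participant_id == pid, ]
      if (nrow(he) && any(near(he$admission_date, ref)))
        asplit["hospitalised_no_bleed_code"] <-
          asplit["hospitalised_no_bleed_code"] + 1L
      else
        asplit["no_hospital_record"] <- asplit["no_hospital_record"] + 1L
    }
  }

  rt_only <- which(r$has_event & !a$has_event)
  rsplit <- c(refuted_within_window = 0L, minor_within_window = 0L,
              no_hospitalisation_reported = 0L, other = 0L)
  major_pre <- c("intracranial", "any_eye", "serious_gi", "other_major")
  for (i in rt_only) {
    pid <- r$participant_id[i]; ref <- r$first_event_date[i]
    dr <- direct_reports[direct_reports$participant_id == pid, ]
    dr <- dr[near(dr$report_date, ref), ]
    if (nrow(dr) && any(dr$pre_category %in% major_pre &
                          dr$post_category %in% c("minor", "no_bleed")))
      rsplit["refuted_within_window"] <- rsplit["refuted_within_window"] + 1L
    else if (nrow(dr) && any(dr$pre_category == "minor" |
                               dr$post_category == "minor"))
      rsplit["minor_within_window"] <- rsplit["minor_within_window"] + 1L
    else if (nrow(dr) == 0)
      rsplit["no_hospitalisation_reported"] <-
        rsplit["no_hospitalisation_reported"] + 1L
    else
      rsplit["other"] <- rsplit["other"] + 1L
  }

  structure(list(adjudicated_only = asplit, routine_only = rsplit,
                 n_adjudicated_only = length(adj_only),
                 n_routine_only = length(rt_only),
                 window_days = window_days),
            class = "discordance_breakdown")
}

#' @export
print.discordance_breakdown <- function(x, ...) {
  cat(sprintf("Discordance breakdown (window %d days)\n", x$window_days))
  cat(sprintf("  adjudicated-follow-up only (n = %d):\n", x$n_adjudicated_only))
  for (nm in names(x$adjudicated_only))
    cat(sprintf("    %-28s %d\n", nm, x$adjudicated_only[[nm]]))
  cat(sprintf("  routine data only (n = %d):\n", x$n_routine_only))
  for (nm in names(x$routine_only))
    cat(sprintf("    %-28s %d\n", nm, x$routine_only[[nm]]))
  invisible(x)
}
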