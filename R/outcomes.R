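.major_cats <- c("intracranial", "eye", "gastrointestinal", "other")

outcome_levels <- c("any_major_bleed", "intracranial", "eye",
                    "gastrointestinal", "other_major", "sve")

#' Reduce an event stream to per-participant first-event outcome records
#'
#' Collapses a source-specific event table to exactly one record per
#' participant for a given outcome: whether a qualifying event occurred,
#' the date of the first one, and the time at risk in days (to the first
#' event, or to censoring). Only events dated between randomisation and the
#' end of follow-up (both inclusive) count; events outside that window are
#' excluded with a warning naming how many, since they indicate a data
#' inconsistency. For the routine source, participants without routine-data
#' linkage are censored at day zero (`time_at_risk = 0`, no event), the
#' convention for the small unlinked fraction of a linked trial cohort.
#'
#' Source semantics:
#' \describe{
#'   \item{routine}{`events` is a classified table from
#'     [classify_severity()]; qualifying events are those with
#'     `severity == "major"` in the outcome's categories
#'     (`any_major_bleed` is the union of the four bleed categories).}
#'   \item{direct_pre}{`events` is a direct-report table; qualifying
#'     pre-adjudication categories are used, and *all* reported eye bleeds
#'     count towards the eye (and any-major) outcome, mirroring
#'     questionnaire follow-up where sight-threatening status is unknown
#'     before adjudication.}
#'   \item{direct_adj}{post-adjudication categories are used
#'     (`sight_threatening_eye` for the eye outcome).}
#' }
#'
#' @param events event table for the source (see Details).
#' @param participants participant table with `participant_id`, `arm`,
#'   `randomisation_date`, `end_of_followup`, `linked`.
#' @param source one of `"routine"`, `"direct_pre"`, `"direct_adj"`.
#' @param outcome one of `"any_major_bleed"`, `"intracranial"`, `"eye"`,
#'   `"gastrointestinal"`, `"other_major"`, `"sve"`.
#' @return data.frame with one row per participant (ordered by id):
#'   `participant_id`, `arm`, `source`, `outcome`, `has_event`,
#'   `first_event_date`, `time_at_risk` (days).
#' @export
derive_outcomes <- function(events, participants, source, outcome) {
  source <- match.arg(source, c("routine", "direct_pre", "direct_adj"))
  outcome <- match.arg(outcome, outcome_levels)
  stopifnot(is.data.frame(participants),
            all(c("participant_id", "arm", "randomisation_date",
                  "end_of_followup", "linked") %in% names(participants)))

  if (source == "routine") {
    datecol <- "event_date"
    if (nrow(events) > 0 && is.null(events$severity))
      stop2("routine events must be classified first (no severity column); ",
            "see classify_severity()")
    sel_cats <- switch(outcome,
                       any_major_bleed = .major_cats,
                       intracranial = "intracranial",
                       eye = "eye",
                       gastrointestinal = "gastrointestinal",
                       other_major = "other",
                       sve = "sve")
    keep <- events$severity == "major" & events$bleed_category %in% sel_cats
  } else {
    datecol <- "report_date"
    col <- if (source == "direct_pre") "pre_category" else "post_category"
    sel <- if (source == "direct_pre")
      switch(outcome,
             any_major_bleed = c("intracranial", "any_eye", "serious_gi",
                                 "other_major"),
             intracranial = "intracranial",
             eye = "any_eye",
             gastrointestinal = "serious_gi",
             other_major = "other_major",
             sve = "sve")
    else
      switch(outcome,
             any_major_bleed = c("intracranial", "sight_threatening_eye",
                                 "serious_gi", "other_major"),
             intracranial = "intracranial",
             eye = "sight_threatening_eye",
             gastrointestinal = "serious_gi",
             other_major = "other_major",
             sve = "sve")
    keep <- events[[col]] %in% sel
  }

  ev <- events[which(keep), c("participant_id", datecol)]
  names(ev) <- c("participant_id", "date")
  ev$participant_id <- as.character(ev$participant_id)

  pid <- as.character(participants$participant_id)
  unknown <- setdiff(ev$participant_id, pid)
  if (length(unknown))
    stop2("event references unknown participant: ",
          paste(utils::head(unknown, 5), collapse = ", "))

  idx <- match(ev$participant_id, pid)
  rand <- as.Date(participants$randomisation_date)[idx]
  eofu <- as.Date(participants$end_of_followup)[idx]
  inside <- ev$date >= rand & ev$date <= eofu
  if (any(!inside))
    warning("derive_outcomes: excluded ", sum(!inside),
            " event(s) dated outside the follow-up window", call. = FALSE)
  ev <- ev[inside, ]
  if (source == "routine") {
    lk <- participants$linked[match(ev$participant_id, pid)]
    ev <- ev[lk, ]
  }

  first <- if (nrow(ev))
    tapply(as.numeric(ev$date), ev$participant_id, min)
  else numeric(0)

  ord <- order(pid)
  out <- data.frame(
    participant_id = pid[ord],
    arm = as.character(participants$arm)[ord],
    source = source, outcome = outcome,
    has_event = FALSE,
    first_event_date = as.Date(NA),
    time_at_risk = as.numeric(as.Date(participants$end_of_followup)[ord] -
                                as.Date(participants$randomisation_date)[ord]))
  hit <- match(names(first), out$participant_id)
  out$has_event[hit] <- TRUE
  out$first_event_date[hit] <- as.Date(as.numeric(first),
                                       origin = "1970-01-01")
  out$time_at_risk[hit] <- as.numeric(out$first_event_date[hit]) -
    as.numeric(as.Date(participants$randomisation_date)[ord][hit])
  if (source == "routine") {
    unl <- !participants$linked[ord]
    out$has_event[unl] <- FALSE
    out$first_event_date[unl] <- as.Date(NA)
    out$time_at_risk[unl] <- 0
  }
  rownames(out) <- NULL
  out
}

#' Convert outcome records to arm/event/time survival format
#'
#' @param outcomes result of [derive_outcomes()].
#' @return data.frame with columns `arm`, `event`, `time` for
#'   [logrank_rr()].
#' @export
as_surv_data <- function(outcomes) {
  data.frame(arm = outcomes$arm, event = outcomes$has_event,
             time = outcomes$time_at_risk)
}
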