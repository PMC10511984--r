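#' Identify bleeding events in hospital-episode and death-registry records
#'
#' Scans episode-level hospital diagnoses and death-registry entries for
#' ICD-10 codes in a bleeding [bleed_code_map()] and returns one candidate
#' event per matching episode-diagnosis or death-record code. The event
#' date is the admission date (hospital) or the death date, the convention
#' used when the routine record replaces participant-reported timing.
#' Death-record codes qualify as *fatal* only in the underlying-cause
#' position; a bleeding code in contributory position yields a non-fatal
#' death-source event (which later classifies as minor). Severity is not
#' decided here: pass the result to [classify_severity()].
#'
#' Syntactically malformed code strings (not letter + two digits after
#' dot-stripping) are skipped with a [message()] stating how many were
#' dropped; valid codes simply absent from the map match nothing silently.
#'
#' @param episodes data.frame, one row per episode-diagnosis:
#'   `participant_id`, `admission_date`, `discharge_date`, `icd10_code`,
#'   `diagnostic_position` (1-based; 1 = primary diagnosis).
#' @param deaths data.frame, one row per death-record code:
#'   `participant_id`, `death_date`, `icd10_code`, `role`
#'   (`"underlying_cause"` or `"contributory"`).
#' @param code_map a [bleed_code_map()]; defaults to the shipped bleeding
#'   map.
#' @return data.frame of candidate events: `participant_id`, `event_date`,
#'   `bleed_category`, `subsite`, `source` (`"hospital"`/`"death"`),
#'   `diagnostic_position`, `overnight_stay` (calendar-day difference >= 1),
#'   `fatal`. Zero rows (with the full column set) for empty input.
#' @export
extract_routine_bleeds <- function(episodes, deaths,
                                   code_map = default_bleed_code_map()) {
  empty <- data.frame(participant_id = character(),
                      event_date = as.Date(character()),
                      bleed_category = character(),
                      subsite = character(),
                      source = character(),
                      diagnostic_position = integer(),
                      overnight_stay = logical(),
                      fatal = logical())
  out <- list()

  if (!is.null(episodes) && nrow(episodes) > 0) {
    stopifnot(all(c("participant_id", "admission_date", "discharge_date",
                    "icd10_code", "diagnostic_position") %in% names(episodes)))
    if (any(episodes$discharge_date < episodes$admission_date, na.rm = TRUE))
      stop2("episode with discharge_date before admission_date")
    if (any(episodes$diagnostic_position < 1, na.rm = TRUE))
      stop2("episode with diagnostic_position < 1")
    m <- match_icd10(episodes$icd10_code, code_map)
    if (any(m$malformed))
      message("extract_routine_bleeds: skipped ", sum(m$malformed),
              " malformed ICD-10 code string(s) in hospital episodes")
    hit <- which(!is.na(m$category))
    if (length(hit))
      out$hospital <- data.frame(
        participant_id = as.character(episodes$participant_id[hit]),
        event_date = as.Date(episodes$admission_date[hit]),
        bleed_category = m$category[hit],
        subsite = m$subsite[hit],
        source = "hospital",
        diagnostic_position = as.integer(episodes$diagnostic_position[hit]),
        overnight_stay = as.numeric(as.Date(episodes$discharge_date[hit]) -
                                      as.Date(episodes$admission_date[hit])) >= 1,
        fatal = FALSE)
  }

  if (!is.null(deaths) && nrow(deaths) > 0) {
    stopifnot(all(c("participant_id", "death_date", "icd10_code", "role")
                  %in% names(deaths)))
    if (!all(deaths$role %in% c("underlying_cause", "contributory")))
      stop2("death record role must be 'underlying_cause' or 'contributory'")
    m <- match_icd10(deaths$icd10_code, code_map)
    if (any(m$malformed))
      message("extract_routine_bleeds: skipped ", sum(m$malformed),
              " malformed ICD-10 code string(s) in death records")
    hit <- which(!is.na(m$category))
    if (length(hit))
      out$death <- data.frame(
        participant_id = as.character(deaths$participant_id[hit]),
        event_date = as.Date(deaths$death_date[hit]),
        bleed_category = m$category[hit],
        subsite = m$subsite[hit],
        source = "death",
        diagnostic_position = NA_integer_,
        overnight_stay = NA,
        fatal = deaths$role[hit] == "underlying_cause")
  }

  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(res$participant_id, res$event_date, res$source,
                   res$bleed_category, res$diagnostic_position,
                   res$overnight_stay), , drop = FALSE]
  rownames(res) <- NULL
  res
}
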