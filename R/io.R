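#' Write or read a simulated cohort as delimited text tables
#'
#' Serialises the five cohort tables to headered CSV files
#' (`participants.csv`, `true_events.csv`, `hospital_episodes.csv`,
#' `death_records.csv`, `direct_reports.csv`) with ISO-8601 dates, and
#' reads them back with date columns restored. Round-tripping preserves the
#' tables exactly.
#'
#' @param cohort a `bleed_cohort` from [simulate_cohort()].
#' @param dir directory to write to / read from (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a list with the five tables (no `config`).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("participants", "true_events", "hospital_episodes",
               "death_records", "direct_reports"))
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

.date_cols <- list(
  participants = c("randomisation_date", "end_of_followup"),
  true_events = "event_date",
  hospital_episodes = c("admission_date", "discharge_date"),
  death_records = "death_date",
  direct_reports = "report_date")

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- lapply(names(.date_cols), function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop2("missing cohort table: ", f)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    for (col in intersect(.date_cols[[nm]], names(d)))
      d[[col]] <- as.Date(d[[col]])
    d
  })
  names(out) <- names(.date_cols)
  out
}
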