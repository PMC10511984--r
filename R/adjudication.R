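.pre_levels <- c("intracranial", "any_eye", "serious_gi", "other_major",
                 "minor")
.post_levels <- c("intracranial", "sight_threatening_eye", "serious_gi",
                  "other_major", "minor", "no_bleed", "unadjudicated")
.diag_map <- c(intracranial = "intracranial",
               any_eye = "sight_threatening_eye",
               serious_gi = "serious_gi",
               other_major = "other_major",
               minor = "minor")

#' Cross-tabulate direct-participant reports before and after adjudication
#'
#' Counts participants by pre-adjudication versus post-adjudication bleed
#' category. Rows and columns each count only the *first* event per
#' participant in that pre-category (a participant reporting, say, a
#' gastrointestinal bleed and later an eye bleed contributes to both
#' rows). A separate participant-level summary counts each participant's
#' first report overall among the major pre-categories, which is what
#' overall confirmation/refutation rates are quoted on. Reports lacking a
#' post-category are tallied in an explicit `unadjudicated` column, never
#' dropped. "Confirmed" means the post-category equals the pre-category
#' (the matrix diagonal, with all eye bleeds mapping to
#' sight-threatening-eye); "refuted" means adjudicated minor or not a
#' bleed; recategorised-to-another-major moves are the remaining
#' off-diagonal cells.
#'
#' @param direct_reports data.frame with `participant_id`, `report_date`,
#'   `pre_category` (`"intracranial"`, `"any_eye"`, `"serious_gi"`,
#'   `"other_major"`, `"minor"`), `post_category` (`"intracranial"`,
#'   `"sight_threatening_eye"`, `"serious_gi"`, `"other_major"`,
#'   `"minor"`, `"no_bleed"`, or `NA` for unadjudicated), optionally
#'   `gi_subsite`.
#' @return An object of class `adjudication_crosstab`: `matrix` (pre rows
#'   x post columns), `row_totals`, `col_totals` (major post columns,
#'   including upgrades from non-major pre rows), and `participant_summary`
#'   (`n_reported`, `n_confirmed`, `n_recategorised`, `n_refuted`,
#'   `n_refuted_minor`, `n_refuted_no_bleed` over first-per-participant
#'   major-pre reports).
#' @export
adjudication_crosstab <- function(direct_reports) {
  stopifnot(is.data.frame(direct_reports),
            all(c("participant_id", "report_date", "pre_category",
                  "post_category") %in% names(direct_reports)))
  dr <- direct_reports
  dr <- dr[dr$pre_category %in% .pre_levels, , drop = FALSE]
  dr$post_category[is.na(dr$post_category)] <- "unadjudicated"
  bad <- !dr$post_category %in% .post_levels
  if (any(bad))
    stop2("unknown post_category: ",
          paste(unique(dr$post_category[bad]), collapse = ", "))

  # first report per (participant, pre-category)
  ord <- order(dr$participant_id, dr$pre_category, dr$report_date)
  dr <- dr[ord, ]
  first_cat <- dr[!duplicated(dr[c("participant_id", "pre_category")]), ]
  m <- table(factor(first_cat$pre_category, levels = .pre_levels),
             factor(first_cat$post_category, levels = .post_levels))
  m <- unclass(m)
  names(dimnames(m)) <- c("pre", "post")

  # first report per participant among major pre-categories
  majors <- dr[dr$pre_category != "minor", ]
  ord2 <- order(majors$participant_id, majors$report_date,
                majors$pre_category)
  majors <- majors[ord2, ]
  fp <- majors[!duplicated(majors$participant_id), ]
  confirmed <- fp$post_category == unname(.diag_map[fp$pre_category])
  refuted_minor <- fp$post_category == "minor"
  refuted_nb <- fp$post_category == "no_bleed"
  summary <- list(
    n_reported = nrow(fp),
    n_confirmed = sum(confirmed),
    n_recategorised = sum(!confirmed & !refuted_minor & !refuted_nb &
                            fp$post_category != "unadjudicated"),
    n_refuted = sum(refuted_minor | refuted_nb),
    n_refuted_minor = sum(refuted_minor),
    n_refuted_no_bleed = sum(refuted_nb))

  major_posts <- .post_levels[1:4]
  structure(list(matrix = m,
                 row_totals = rowSums(m),
                 col_totals = colSums(m)[major_posts],
                 participant_summary = summary),
            class = "adjudication_crosstab")
}

#' @export
print.adjudication_crosstab <- function(x, ...) {
  cat("Pre- vs post-adjudication cross-tabulation (first event per",
      "participant per pre-category)\n")
  print(cbind(x$matrix, total = x$row_totals))
  s <- x$participant_summary
  cat(sprintf(
    "Participant-level first reports (major pre-categories): %d reported, %d confirmed, %d refuted (%s; %d minor, %d no bleed)\n",
    s$n_reported, s$n_confirmed, s$n_refuted,
    fmt_pct(s$n_refuted / s$n_reported), s$n_refuted_minor,
    s$n_refuted_no_bleed))
  invisible(x)
}

#' Confirmation and refutation rates under adjudication
#'
#' Summarises an [adjudication_crosstab()]: the overall proportion of
#' participant-reported major bleeds refuted on adjudication (first report
#' per participant), per-pre-category confirmation proportions
#' (diagonal / row total; upgrade rows from non-major pre-categories are
#' excluded), and, when a gastrointestinal subsite table is supplied,
#' per-subsite confirmation proportions. All proportions are reported with
#' explicit numerators and denominators; a zero denominator gives `NA`
#' with a warning.
#'
#' @param crosstab an [adjudication_crosstab()].
#' @param gi_subsites optional data.frame with columns `subsite`,
#'   `confirmed`, `total` (see [reference_gi_subsites()]).
#' @return list of class `refutation_summary`: `overall` (list with
#'   `refuted`, `reported`, `proportion`, `refuted_minor`,
#'   `refuted_no_bleed`), `by_category` (data.frame), `by_gi_subsite`
#'   (data.frame or `NULL`).
#' @export
refutation_summary <- function(crosstab, gi_subsites = NULL) {
  stopifnot(inherits(crosstab, "adjudication_crosstab"))
  s <- crosstab$participant_summary
  overall <- list(refuted = s$n_refuted, reported = s$n_reported,
                  proportion = if (s$n_reported) s$n_refuted / s$n_reported
                  else NA_real_,
                  refuted_minor = s$n_refuted_minor,
                  refuted_no_bleed = s$n_refuted_no_bleed)
  if (!s$n_reported)
    warning("no major-pre reports: overall refutation undefined",
            call. = FALSE)

  major_pre <- .pre_levels[1:4]
  conf <- vapply(major_pre, function(p)
    crosstab$matrix[p, .diag_map[[p]]], numeric(1))
  tot <- crosstab$row_totals[major_pre]
  if (any(tot == 0))
    warning("zero reports in pre-category: ",
            paste(major_pre[tot == 0], collapse = ", "), call. = FALSE)
  by_cat <- data.frame(pre_category = major_pre,
                       confirmed = unname(conf), total = unname(tot),
                       proportion = unname(ifelse(tot > 0, conf / tot,
                                                  NA_real_)))

  by_gi <- NULL
  if (!is.null(gi_subsites)) {
    stopifnot(all(c("subsite", "confirmed", "total") %in% names(gi_subsites)))
    by_gi <- gi_subsites
    by_gi$proportion <- ifelse(by_gi$total > 0,
                               by_gi$confirmed / by_gi$total, NA_real_)
  }
  structure(list(overall = overall, by_category = by_cat,
                 by_gi_subsite = by_gi),
            class = "refutation_summary")
}

#' @export
print.refutation_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Refuted on adjudication: %s (%d/%d; %d minor, %d not a bleed)\n",
              fmt_pct(o$proportion), o$refuted, o$reported,
              o$refuted_minor, o$refuted_no_bleed))
  cat("Confirmation by pre-category:\n")
  for (i in seq_len(nrow(x$by_category)))
    with(x$by_category[i, ], cat(sprintf("  %-12s %s (%d/%d)\n",
                                         pre_category, fmt_pct(proportion),
                                         confirmed, total)))
  if (!is.null(x$by_gi_subsite)) {
    cat("Gastrointestinal confirmation by subsite:\n")
    for (i in seq_len(nrow(x$by_gi_subsite)))
      with(x$by_gi_subsite[i, ], cat(sprintf("  %-12s %s (%d/%d)\n",
                                             subsite, fmt_pct(proportion),
                                             confirmed, total)))
  }
  invisible(x)
}
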