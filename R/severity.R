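#' Rule-based severity algorithms for routine-data bleeding events
#'
#' A severity algorithm decides whether an extracted bleeding event counts
#' as *major* or *minor* from attributes available in routine data: the
#' diagnostic position of the bleeding code on the hospital episode and
#' whether the admission involved an overnight stay. Fatal events (a
#' bleeding code in underlying-cause position on the death record) are
#' always major when `fatal_always_major` is set, which it is in every
#' shipped preset.
#'
#' The `primary` preset is the pre-specified algorithm of the emulated
#' trial: intracranial and eye bleeding codes qualify in *any* diagnostic
#' position, while gastrointestinal and other bleeding codes must be in the
#' first (primary) position *and* the patient must have stayed at least one
#' night in hospital. `all_bleeds_major` applies no restriction at all.
#'
#' @param name label for the algorithm.
#' @param rules named list with one entry per bleed category
#'   (`intracranial`, `eye`, `gastrointestinal`, `other`), each a list with
#'   `position_scope` (`"any_position"` or `"primary_only"`) and
#'   `require_overnight` (logical). A permissive rule for the `sve`
#'   category (any position, no stay requirement) is added automatically so
#'   vascular-event extractions classify cleanly.
#' @param fatal_always_major logical; underlying-cause death-record events
#'   are major regardless of the per-category rules.
#' @return An object of class `severity_algorithm`.
#' @seealso [classify_severity()], [algorithm_grid()]
#' @export
severity_algorithm <- function(name, rules, fatal_always_major = TRUE) {
  cats <- c("intracranial", "eye", "gastrointestinal", "other")
  if (!setequal(intersect(names(rules), cats), cats))
    stop2("rules must cover each bleed category exactly once: ",
          paste(cats, collapse = ", "))
  for (cat in cats) {
    r <- rules[[cat]]
    if (!is.list(r) ||
        !r$position_scope %in% c("any_position", "primary_only") ||
        !is.logical(r$require_overnight))
      stop2("invalid rule for category '", cat, "'")
  }
  rules$sve <- list(position_scope = "any_position", require_overnight = FALSE)
  structure(list(name = name, rules = rules,
                 fatal_always_major = isTRUE(fatal_always_major)),
            class = "severity_algorithm")
}

rule2 <- function(scope, overnight) {
  list(position_scope = scope, require_overnight = overnight)
}

#' @rdname severity_algorithm
#' @export
primary_algorithm <- function() {
  severity_algorithm("primary", list(
    intracranial = rule2("any_position", FALSE),
    eye = rule2("any_position", FALSE),
    gastrointestinal = rule2("primary_only", TRUE),
    other = rule2("primary_only", TRUE)))
}

#' @rdname severity_algorithm
#' @export
all_bleeds_major_algorithm <- function() {
  severity_algorithm("all_bleeds_major", list(
    intracranial = rule2("any_position", FALSE),
    eye = rule2("any_position", FALSE),
    gastrointestinal = rule2("any_position", FALSE),
    other = rule2("any_position", FALSE)))
}

#' Number of active restrictions in a severity algorithm
#'
#' One point for each of: primary-position restriction on the
#' intracranial/eye pair, overnight-stay requirement on that pair, and the
#' same two components on the gastrointestinal/other pair. 0 for
#' `all_bleeds_major`; the grid is ordered by this score.
#'
#' @param algorithm a [severity_algorithm()].
#' @return integer strictness score.
#' @export
algorithm_strictness <- function(algorithm) {
  stopifnot(inherits(algorithm, "severity_algorithm"))
  r <- algorithm$rules
  sum(vapply(c("intracranial", "eye", "gastrointestinal", "other"),
             function(cat) {
               (r[[cat]]$position_scope == "primary_only") +
                 r[[cat]]$require_overnight
             }, numeric(1))) / 2
}

#' The grid of candidate severity algorithms
#'
#' Builds the 15 named rule bundles swept in sensitivity analyses: the full
#' factorial of \{any-position, primary-only\} x \{overnight not required,
#' required\} applied separately to the intracranial/eye pair and to the
#' gastrointestinal/other pair (16 combinations), minus the one incongruent
#' combination that restricts the severe intracranial/eye categories fully
#' while leaving gastrointestinal/other unrestricted. The grid includes
#' `all_bleeds_major` (no restrictions) and `primary` (the pre-specified
#' algorithm) and is ordered by increasing [algorithm_strictness()]. The
#' exact historical variants are not public, so the grid is a documented,
#' replaceable configuration.
#'
#' @return named list of 15 [severity_algorithm()] objects, least strict
#'   first.
#' @export
algorithm_grid <- function() {
  scopes <- c(any = "any_position", prim = "primary_only")
  stays <- c(`FALSE` = FALSE, `TRUE` = TRUE)
  grid <- list()
  for (a in names(scopes)) for (o1 in stays) for (p in names(scopes)) for (o2 in stays) {
    if (a == "prim" && o1 && p == "any" && !o2) next  # incongruent combo
    nm <- paste0("ie_", a, if (o1) "_stay" else "",
                 ".go_", p, if (o2) "_stay" else "")
    if (a == "any" && !o1 && p == "any" && !o2) nm <- "all_bleeds_major"
    if (a == "any" && !o1 && p == "prim" && o2) nm <- "primary"
    grid[[nm]] <- severity_algorithm(nm, list(
      intracranial = rule2(scopes[[a]], o1),
      eye = rule2(scopes[[a]], o1),
      gastrointestinal = rule2(scopes[[p]], o2),
      other = rule2(scopes[[p]], o2)))
  }
  grid[order(vapply(grid, algorithm_strictness, numeric(1)),
             names(grid))]
}

#' Classify extracted routine bleeding events as major or minor
#'
#' Applies a [severity_algorithm()] to events produced by
#' [extract_routine_bleeds()]. Death-source events are major if and only if
#' the bleeding code was the underlying cause (`fatal`) and the algorithm
#' sets `fatal_always_major`; contributory-position codes therefore classify
#' as minor. Hospital-source events are major when the diagnostic position
#' is within the category's scope and any required overnight stay is
#' present. Deterministic: the same event and algorithm always give the
#' same answer.
#'
#' @param events data.frame of routine events (from
#'   [extract_routine_bleeds()]), needing columns `bleed_category`,
#'   `source`, `diagnostic_position`, `overnight_stay`, `fatal`.
#' @param algorithm a [severity_algorithm()].
#' @return `events` with a `severity` column (`"major"`/`"minor"`) and a
#'   `severity_algorithm` attribute naming the rule bundle used.
#' @export
classify_severity <- function(events, algorithm) {
  stopifnot(inherits(algorithm, "severity_algorithm"), is.data.frame(events))
  n <- nrow(events)
  severity <- rep("minor", n)
  if (n > 0) {
    unknown <- setdiff(unique(events$bleed_category), names(algorithm$rules))
    if (length(unknown))
      stop2("algorithm '", algorithm$name, "' has no severity rule for ",
            "category: ", paste(unknown, collapse = ", "))
    is_death <- events$source == "death"
    severity[is_death & events$fatal & algorithm$fatal_always_major] <- "major"
    hosp <- which(!is_death)
    if (length(hosp)) {
      scope <- vapply(algorithm$rules, `[[`, "", "position_scope")
      need_stay <- vapply(algorithm$rules, `[[`, NA, "require_overnight")
      cat <- events$bleed_category[hosp]
      pos_ok <- scope[cat] == "any_position" |
        events$diagnostic_position[hosp] == 1L
      stay_ok <- !need_stay[cat] | events$overnight_stay[hosp]
      severity[hosp[pos_ok & stay_ok]] <- "major"
    }
  }
  events$severity <- severity
  attr(events, "severity_algorithm") <- algorithm$name
  events
}

#' @export
print.severity_algorithm <- function(x, ...) {
  cat("Severity algorithm:", x$name,
      sprintf("(strictness %.1f)\n", algorithm_strictness(x)))
  for (cat_ in c("intracranial", "eye", "gastrointestinal", "other")) {
    r <- x$rules[[cat_]]
    cat(sprintf("  %-16s %s%s\n", cat_,
                if (r$position_scope == "any_position") "any position"
                else "primary position only",
                if (r$require_overnight) " + overnight stay" else ""))
  }
  cat("  fatal (underlying cause on death record): ",
      if (x$fatal_always_major) "always major" else "per rules", "\n", sep = "")
  invisible(x)
}
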