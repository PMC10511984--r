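# Synthetic linked-trial cohort generator.
#
# Latent model: per participant, independent exponential times to first
# major bleed, first serious vascular event (SVE) and non-bleed death, with
# arm-specific hazards for the two outcomes; staggered uniform entry over
# the recruitment window and administrative censoring at a common calendar
# date. Each realised event is then pushed through imperfect, independent
# capture processes for the two data sources, which is what makes the
# downstream agreement analysis non-trivial.

# representative codes drawn from the shipped maps / filler lists
.sim_codes <- list(
  intracranial = c("I61.9", "I60.7", "I62.0", "S06.5"),
  eye = c("H35.6", "H43.1"),
  gastrointestinal = c("K92.2", "K92.0", "K25.0", "K26.4", "K62.5", "I85.0"),
  other = c("R04.0", "R04.2", "R31", "N95.0", "R58"),
  sve = c("I21.9", "I63.9", "I21.4", "G45.9"),
  filler = c("J18.9", "N39.0", "E11.9", "M54.5", "K35.8", "A41.9", "S72.0"),
  death_other = c("I25.1", "C80.9", "J44.9", "N18.5")
)

.pre_map <- c(intracranial = "intracranial", eye = "any_eye",
              gastrointestinal = "serious_gi", other = "other_major")
.post_map <- c(intracranial = "intracranial", eye = "sight_threatening_eye",
               gastrointestinal = "serious_gi", other = "other_major")

#' Simulate a linked randomised-trial cohort
#'
#' Generates the five tables the analysis pipeline consumes: a participant
#' randomisation table, a hospital-episode table (one row per
#' episode-diagnosis), a death-registry table, a direct-follow-up report
#' table, and the latent `true_events` table that records the ground truth
#' (useful for parameter-recovery tests, never available in real data).
#'
#' Capture model, per true major bleed and independently of the other
#' source: with probability `p_routine_capture` the bleed leaves a
#' *qualifying* routine record — a hospital episode whose code position and
#' length of stay satisfy the primary severity algorithm, or, when fatal, a
#' death record with the bleeding code as underlying cause. Otherwise the
#' bleed leaves, per `missed_split`, a hospital episode with a
#' non-qualifying bleeding code (gastrointestinal/other categories only —
#' any-position rules make a non-qualifying intracranial/eye code
#' impossible, so that mass folds into the next branch), a hospital episode
#' with no bleeding code, or no routine trace. With probability
#' `p_direct_capture` it is also reported by the participant
#' (adjudication-confirmed, recalled date jittered by
#' `report_error_sd_days`). Spurious reports refuted on adjudication arise
#' per participant with probability `p_false_report`; minor bleeds and
#' background non-bleed hospitalisations add realistic noise. Unlinked
#' participants (probability `p_unlinked`) have no routine records at all.
#'
#' Reproducible: identical configurations (including `seed`) give
#' byte-identical tables; the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return An object of class `bleed_cohort`: a list with elements
#'   `participants`, `true_events`, `hospital_episodes`, `death_records`,
#'   `direct_reports` (data.frames) and `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_participants = 500, seed = 42))
#' coh
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  id <- sprintf("P%06d", seq_len(n))
  arm <- ifelse(stats::runif(n) < cfg$allocation_ratio, "active", "control")
  linked <- stats::runif(n) >= cfg$p_unlinked

  entry <- floor(stats::runif(n, 0, cfg$recruit_years * 365.25))
  rand_date <- cfg$trial_start + entry
  admin_end <- cfg$trial_start +
    round((cfg$followup_years_mean + cfg$recruit_years / 2) * 365.25)
  admin_fu <- as.numeric(admin_end - rand_date)

  day <- 365.25
  t_death <- stats::rexp(n, cfg$death_hazard / day)
  rr_b <- ifelse(arm == "active", cfg$true_rr_bleed, 1)
  rr_s <- ifelse(arm == "active", cfg$true_rr_sve, 1)
  t_bleed <- stats::rexp(n, cfg$baseline_bleed_hazard * rr_b / day)
  t_sve <- stats::rexp(n, cfg$baseline_sve_hazard * rr_s / day)
  fatal_if <- stats::runif(n) < cfg$p_fatal_bleed

  cens0 <- pmin(admin_fu, t_death)
  bleed_in <- t_bleed <= cens0
  bleed_death <- bleed_in & fatal_if
  fu <- ifelse(bleed_death, t_bleed, cens0)
  other_death <- !bleed_death & t_death <= admin_fu
  died <- bleed_death | other_death
  day_end <- floor(fu)
  day_bleed <- floor(t_bleed)
  sve_in <- t_sve <= fu
  day_sve <- floor(t_sve)

  cats <- c("intracranial", "eye", "gastrointestinal", "other")
  bleed_cat <- sample(cats, n, replace = TRUE, prob = cfg$category_mix)

  has_minor <- stats::runif(n) < cfg$p_minor_bleed & day_end >= 1
  minor_w <- cfg$category_mix[3:4] / sum(cfg$category_mix[3:4])
  minor_cat <- sample(cats[3:4], n, replace = TRUE, prob = minor_w)
  day_minor <- floor(stats::runif(n, 0, pmax(fu, 1e-9)))

  participants <- data.frame(
    participant_id = id, arm = arm, randomisation_date = rand_date,
    end_of_followup = rand_date + day_end, died = died, linked = linked)

  ## latent truth ------------------------------------------------------------
  te <- list()
  mj <- which(bleed_in)
  if (length(mj))
    te$major <- data.frame(
      participant_id = id[mj], event_date = rand_date[mj] + day_bleed[mj],
      outcome_class = "major_bleed", bleed_category = bleed_cat[mj],
      fatal = bleed_death[mj])
  mn <- which(has_minor)
  if (length(mn))
    te$minor <- data.frame(
      participant_id = id[mn], event_date = rand_date[mn] + day_minor[mn],
      outcome_class = "minor_bleed", bleed_category = minor_cat[mn],
      fatal = FALSE)
  sv <- which(sve_in)
  if (length(sv))
    te$sve <- data.frame(
      participant_id = id[sv], event_date = rand_date[sv] + day_sve[sv],
      outcome_class = "sve", bleed_category = NA_character_, fatal = FALSE)
  true_events <- sim_rbind(te, data.frame(
    participant_id = character(), event_date = as.Date(character()),
    outcome_class = character(), bleed_category = character(),
    fatal = logical()))

  ## routine capture of major bleeds ----------------------------------------
  ep <- list(); dr <- list()
  u_cap <- stats::runif(n)
  captured <- bleed_in & linked & u_cap < cfg$p_routine_capture

  qi <- which(captured & !bleed_death)
  if (length(qi)) {
    hi_sev <- bleed_cat[qi] %in% cats[1:2]
    pos <- ifelse(hi_sev, sample(1:3, length(qi), replace = TRUE,
                                 prob = c(.6, .3, .1)), 1L)
    nights <- ifelse(hi_sev, stats::rpois(length(qi), 3),
                     1L + stats::rpois(length(qi), 2))
    ep$qual <- data.frame(
      participant_id = id[qi], admission_date = rand_date[qi] + day_bleed[qi],
      discharge_date = rand_date[qi] + day_bleed[qi] + nights,
      icd10_code = pick_code(bleed_cat[qi]),
      diagnostic_position = as.integer(pos))
  }
  fi <- which(captured & bleed_death)
  if (length(fi))
    dr$bleed <- data.frame(
      participant_id = id[fi], death_date = rand_date[fi] + day_bleed[fi],
      icd10_code = pick_code(bleed_cat[fi]), role = "underlying_cause")

  missed <- which(bleed_in & linked & !captured & !bleed_death)
  if (length(missed)) {
    pr <- c(cfg$missed_split, max(0, 1 - sum(cfg$missed_split)))
    branch <- sample(c("code_not_major", "no_code", "no_record", "no_record"),
                     length(missed), replace = TRUE, prob = pr)
    branch[branch == "code_not_major" & bleed_cat[missed] %in% cats[1:2]] <-
      "no_code"
    ci <- missed[branch == "code_not_major"]
    if (length(ci)) {
      sameday <- stats::runif(length(ci)) < 0.5
      ep$nonqual <- data.frame(
        participant_id = id[ci], admission_date = rand_date[ci] + day_bleed[ci],
        discharge_date = rand_date[ci] + day_bleed[ci] +
          ifelse(sameday, 0L, 1L + stats::rpois(length(ci), 1)),
        icd10_code = pick_code(bleed_cat[ci]),
        diagnostic_position = as.integer(ifelse(sameday, 1L,
                                                sample(2:4, length(ci),
                                                       replace = TRUE))))
    }
    ni <- missed[branch == "no_code"]
    if (length(ni))
      ep$nocode <- data.frame(
        participant_id = id[ni], admission_date = rand_date[ni] + day_bleed[ni],
        discharge_date = rand_date[ni] + day_bleed[ni] +
          stats::rpois(length(ni), 2),
        icd10_code = sample(.sim_codes$filler, length(ni), replace = TRUE),
        diagnostic_position = 1L)
  }
  fm <- which(bleed_in & linked & !captured & bleed_death)
  if (length(fm))
    dr$bleed_missed <- data.frame(
      participant_id = id[fm], death_date = rand_date[fm] + day_bleed[fm],
      icd10_code = "R99", role = "underlying_cause")

  ## minor bleed hospitalisations --------------------------------------------
  mh <- which(has_minor & linked & stats::runif(n) < cfg$p_minor_hosp)
  if (length(mh)) {
    sameday <- stats::runif(length(mh)) < 0.5
    ep$minor <- data.frame(
      participant_id = id[mh], admission_date = rand_date[mh] + day_minor[mh],
      discharge_date = rand_date[mh] + day_minor[mh] +
        ifelse(sameday, 0L, 1L + stats::rpois(length(mh), 1)),
      icd10_code = pick_code(minor_cat[mh]),
      diagnostic_position = as.integer(ifelse(sameday, 1L,
                                              sample(2:4, length(mh),
                                                     replace = TRUE))))
  }

  ## SVE routine capture ------------------------------------------------------
  sq <- which(sve_in & linked & stats::runif(n) < cfg$p_sve_routine_capture)
  if (length(sq))
    ep$sve <- data.frame(
      participant_id = id[sq], admission_date = rand_date[sq] + day_sve[sq],
      discharge_date = rand_date[sq] + day_sve[sq] +
        1L + stats::rpois(length(sq), 3),
      icd10_code = sample(.sim_codes$sve, length(sq), replace = TRUE),
      diagnostic_position = 1L)

  ## background hospitalisations ---------------------------------------------
  nbg <- stats::rpois(n, cfg$bg_hosp_rate * fu / day * linked)
  bi <- rep(seq_len(n), nbg)
  if (length(bi)) {
    ep$bg <- data.frame(
      participant_id = id[bi],
      admission_date = rand_date[bi] + floor(stats::runif(length(bi), 0, fu[bi])),
      discharge_date = as.Date(NA),
      icd10_code = sample(.sim_codes$filler, length(bi), replace = TRUE),
      diagnostic_position = 1L)
    ep$bg$discharge_date <- ep$bg$admission_date +
      sample(0:5, length(bi), replace = TRUE)
  }

  ## non-bleed death records ---------------------------------------------------
  od <- which(other_death & linked)
  if (length(od)) {
    dr$other <- data.frame(
      participant_id = id[od], death_date = rand_date[od] + day_end[od],
      icd10_code = sample(.sim_codes$death_other, length(od), replace = TRUE),
      role = "underlying_cause")
    cb <- od[stats::runif(length(od)) < cfg$p_contributory_bleed_code]
    if (length(cb))
      dr$contrib <- data.frame(
        participant_id = id[cb], death_date = rand_date[cb] + day_end[cb],
        icd10_code = "K92.2", role = "contributory")
  }

  hospital_episodes <- sim_rbind(ep, data.frame(
    participant_id = character(), admission_date = as.Date(character()),
    discharge_date = as.Date(character()), icd10_code = character(),
    diagnostic_position = integer()))
  death_records <- sim_rbind(dr, data.frame(
    participant_id = character(), death_date = as.Date(character()),
    icd10_code = character(), role = character()))

  ## direct follow-up reports ---------------------------------------------------
  rp <- list()
  di <- which(bleed_in & stats::runif(n) < cfg$p_direct_capture)
  if (length(di)) {
    jit <- round(stats::rnorm(length(di), 0, cfg$report_error_sd_days))
    d <- pmin(pmax(day_bleed[di] + jit, 0), day_end[di])
    gi <- bleed_cat[di] == "gastrointestinal"
    subsite <- rep(NA_character_, length(di))
    subsite[gi] <- sample(c("upper", "lower", "unspecified"), sum(gi),
                          replace = TRUE, prob = c(.5, .45, .05))
    rp$major <- data.frame(
      participant_id = id[di], report_date = rand_date[di] + d,
      pre_category = unname(.pre_map[bleed_cat[di]]),
      post_category = unname(.post_map[bleed_cat[di]]),
      gi_subsite = subsite)
  }
  mi <- which(has_minor & stats::runif(n) < cfg$p_direct_capture)
  if (length(mi)) {
    jit <- round(stats::rnorm(length(mi), 0, cfg$report_error_sd_days))
    rp$minor <- data.frame(
      participant_id = id[mi],
      report_date = rand_date[mi] + pmin(pmax(day_minor[mi] + jit, 0),
                                         day_end[mi]),
      pre_category = "minor", post_category = "minor",
      gi_subsite = NA_character_)
  }
  si <- which(stats::runif(n) < cfg$p_false_report & day_end >= 1)
  if (length(si)) {
    sc <- sample(cats, length(si), replace = TRUE, prob = cfg$spurious_mix)
    rp$spurious <- data.frame(
      participant_id = id[si],
      report_date = rand_date[si] + floor(stats::runif(length(si), 0, fu[si])),
      pre_category = unname(.pre_map[sc]),
      post_category = sample(c("minor", "no_bleed"), length(si),
                             replace = TRUE, prob = c(.7, .3)),
      gi_subsite = NA_character_)
  }
  sd_ <- which(sve_in & stats::runif(n) < cfg$p_sve_direct_capture)
  if (length(sd_))
    rp$sve <- data.frame(
      participant_id = id[sd_], report_date = rand_date[sd_] + day_sve[sd_],
      pre_category = "sve", post_category = "sve",
      gi_subsite = NA_character_)
  direct_reports <- sim_rbind(rp, data.frame(
    participant_id = character(), report_date = as.Date(character()),
    pre_category = character(), post_category = character(),
    gi_subsite = character()))

  structure(list(participants = participants, true_events = true_events,
                 hospital_episodes = hospital_episodes,
                 death_records = death_records,
                 direct_reports = direct_reports, config = cfg),
            class = "bleed_cohort")
}

pick_code <- function(categories) {
  vapply(categories, function(cat) {
    pool <- .sim_codes[[cat]]
    pool[sample.int(length(pool), 1L)]
  }, "", USE.NAMES = FALSE)
}

sim_rbind <- function(parts, empty) {
  if (!length(parts)) return(empty)
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res <- res[do.call(order, unname(res[, 1:2])), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.bleed_cohort <- function(x, ...) {
  p <- x$participants
  py <- sum(as.numeric(p$end_of_followup - p$randomisation_date)) / 365.25
  cat("Synthetic linked-trial cohort\n")
  cat(sprintf("  %d participants (%d active / %d control), %.0f person-years\n",
              nrow(p), sum(p$arm == "active"), sum(p$arm == "control"), py))
  cat(sprintf("  true events: %d major bleeds, %d minor bleeds, %d SVEs\n",
              sum(x$true_events$outcome_class == "major_bleed"),
              sum(x$true_events$outcome_class == "minor_bleed"),
              sum(x$true_events$outcome_class == "sve")))
  cat(sprintf("  routine: %d episode-diagnoses, %d death-record rows; direct: %d reports\n",
              nrow(x$hospital_episodes), nrow(x$death_records),
              nrow(x$direct_reports)))
  cat(sprintf("  unlinked: %d; died: %d; seed %d\n",
              sum(!p$linked), sum(p$died), x$config$seed))
  invisible(x)
}
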