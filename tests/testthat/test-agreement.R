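test_that("cross-classification counts presence per source, irrespective of timing", {
  p <- mini_participants(4, fu = rep(2000, 4))
  mk <- function(ids, days) {
    out <- derive_outcomes(classify_severity(
      do.call(rbind, Map(routine_event_row, ids, days,
                         MoreArgs = list(category = "intracranial"))),
      primary_algorithm()), p, "routine", "any_major_bleed")
    out
  }
  r <- mk(c("P01", "P02"), c(10, 20))
  a <- mk(c("P01", "P03"), c(1500, 30))  # P01 dates far apart: still "both"
  tab <- cross_classify(r, a)
  expect_equal(c(tab$both, tab$routine_only, tab$adjudicated_only,
                 tab$neither), c(1, 1, 1, 1))
  expect_equal(tab$n, 4)
  # identical outcome sets: no discordant cells
  tab2 <- cross_classify(r, r)
  expect_equal(tab2$routine_only + tab2$adjudicated_only, 0)
  # all-empty outcome sets
  none <- derive_outcomes(classify_severity(extract_routine_bleeds(NULL, NULL),
                                            primary_algorithm()),
                          p, "routine", "any_major_bleed")
  tab3 <- cross_classify(none, none)
  expect_equal(c(tab3$both, tab3$routine_only, tab3$adjudicated_only,
                 tab3$neither), c(0, 0, 0, 4))
  expect_error(cross_classify(r, a[1:3, ]), "different participant sets")
})

test_that("kappa equals 1 for perfect agreement, 0 under independence, and is transpose-symmetric", {
  expect_equal(kappa_stat(bleed_crosstab(7, 0, 0, 93))$kappa, 1)
  expect_equal(kappa_stat(bleed_crosstab(1, 1, 1, 1))$kappa, 0)
  for (cells in list(c(30, 10, 5, 200), c(2, 9, 4, 40), c(11, 0, 7, 60))) {
    k1 <- kappa_stat(do.call(bleed_crosstab, as.list(cells)))$kappa
    k2 <- kappa_stat(bleed_crosstab(cells[1], cells[3], cells[2],
                                    cells[4]))$kappa
    expect_equal(k1, k2)
  }
})

test_that("degenerate margins leave kappa undefined, reported as NA", {
  expect_warning(k <- kappa_stat(bleed_crosstab(0, 0, 0, 25)), "degenerate")
  expect_true(is.na(k$kappa))
})

test_that("kappa, sensitivity and specificity match a direct-formula oracle on random small tables", {
  set.seed(7)
  for (i in 1:200) {
    cells <- as.numeric(rmultinom(1, sample(10:50, 1), c(.2, .2, .2, .4)))
    if (cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
    tab <- bleed_crosstab(cells[1], cells[2], cells[3], cells[4])
    want <- oracle_agreement(cells[1], cells[2], cells[3], cells[4])
    if (!is.na(want$kappa))
      expect_equal(kappa_stat(tab)$kappa, want$kappa, tolerance = 1e-12)
    ss <- suppressWarnings(sens_spec(tab))
    expect_equal(ss$sensitivity$estimate, want$sens, tolerance = 1e-12)
    expect_equal(ss$specificity$estimate, want$spec, tolerance = 1e-12)
  }
})

test_that("published any-major and intracranial agreement rows are reproduced", {
  cnt <- reference_agreement_counts()
  any_major <- cnt[cnt$outcome == "any_major_bleed", ]
  tab <- bleed_crosstab(any_major$both, any_major$routine_only,
                        any_major$adjudicated_only, any_major$neither)
  k <- kappa_stat(tab)
  expect_equal(round_half_up(k$kappa, 2), 0.53)
  expect_equal(round_half_up(k$ci, 2), c(0.49, 0.57))
  ss <- sens_spec(tab)
  expect_equal(round_half_up(100 * ss$sensitivity$estimate, 1), 56.9)
  expect_equal(round_half_up(100 * ss$sensitivity$ci, 1), c(52.8, 61.0))
  expect_equal(round_half_up(100 * ss$specificity$estimate, 1), 98.1)
  expect_equal(round_half_up(100 * ss$specificity$ci, 1), c(97.9, 98.3))
  ich <- cnt[cnt$outcome == "intracranial", ]
  k2 <- kappa_stat(bleed_crosstab(ich$both, ich$routine_only,
                                  ich$adjudicated_only, ich$neither))
  expect_equal(round_half_up(k2$kappa, 2), 0.73)
})

test_that("Wilson and exact intervals are ordered, clipped alternatives to Wald", {
  tab <- bleed_crosstab(9, 1, 1, 9)
  for (m in c("wald", "wilson", "exact")) {
    ss <- sens_spec(tab, method = m)
    expect_true(ss$sensitivity$ci[1] <= ss$sensitivity$estimate)
    expect_true(ss$sensitivity$ci[2] >= ss$sensitivity$estimate)
    expect_true(all(ss$sensitivity$ci >= 0 & ss$sensitivity$ci <= 1))
  }
  expect_warning(sens_spec(bleed_crosstab(0, 5, 0, 10)), "sensitivity")
})

test_that("timing concordance is 1 for equal dates, monotone in the window, NA when empty", {
  p <- mini_participants(3, fu = rep(2000, 3))
  mk <- function(days) derive_outcomes(classify_severity(
    do.call(rbind, Map(routine_event_row, c("P01", "P02"), days,
                       MoreArgs = list(category = "intracranial"))),
    primary_algorithm()), p, "routine", "any_major_bleed")
  r <- mk(c(100, 200))
  expect_equal(timing_concordance(r, r, 0)$proportion, 1)
  a <- mk(c(130, 500))
  t0 <- timing_concordance(r, a, 0)$proportion
  t90 <- timing_concordance(r, a, 90)$proportion
  t400 <- timing_concordance(r, a, 400)$proportion
  expect_equal(c(t0, t90, t400), c(0, 0.5, 1))
  none <- derive_outcomes(classify_severity(extract_routine_bleeds(NULL, NULL),
                                            primary_algorithm()),
                          p, "routine", "any_major_bleed")
  empty <- timing_concordance(none, none, 90)
  expect_true(is.na(empty$proportion))
  expect_equal(empty$n_both, 0)
})

test_that("simulated timing concordance matches the recall-error distribution", {
  # routine dates are exact; questionnaire dates carry rounded N(0, sd)
  # recall error, so 90-day concordance ~ P(|N(0, 30)| <= 90.5)
  coh <- simulate_cohort(perfect_capture_config(20000, seed = 77,
                                                report_error_sd_days = 30))
  cl <- classify_severity(
    extract_routine_bleeds(coh$hospital_episodes, coh$death_records),
    primary_algorithm())
  r <- derive_outcomes(cl, coh$participants, "routine", "any_major_bleed")
  a <- derive_outcomes(coh$direct_reports, coh$participants, "direct_adj",
                       "any_major_bleed")
  tc <- timing_concordance(r, a, 90)
  expect_gt(tc$n_both, 500)
  oracle <- 2 * pnorm(90.5 / 30) - 1
  expect_lt(abs(tc$proportion - oracle), 0.015)
})

test_that("discordance splits are exhaustive, exclusive and rule-ordered", {
  p <- mini_participants(6, fu = rep(2000, 6))
  base <- as.Date("2010-01-01")
  # routine majors for P01 (refuted report nearby), P02 (minor report),
  # P03 (nothing in direct data)
  routine_ev <- classify_severity(rbind(
    routine_event_row("P01", 100, "intracranial"),
    routine_event_row("P02", 100, "intracranial"),
    routine_event_row("P03", 100, "intracranial"),
    # P04: bleeding code present but not major (same-week, same-day stay)
    routine_event_row("P04", 303, "gastrointestinal", position = 1,
                      overnight = FALSE)),
    primary_algorithm())
  episodes <- data.frame(participant_id = "P05",
                         admission_date = base + 300,
                         discharge_date = base + 302,
                         icd10_code = "J18.9", diagnostic_position = 1L)
  reports <- data.frame(
    participant_id = c("P01", "P02", "P04", "P05", "P06"),
    report_date = base + c(110, 95, 300, 300, 300),
    pre_category = c("serious_gi", "minor", "intracranial", "intracranial",
                     "intracranial"),
    post_category = c("no_bleed", "minor", "intracranial", "intracranial",
                      "intracranial"),
    gi_subsite = NA_character_)
  r <- derive_outcomes(routine_ev, p, "routine", "any_major_bleed")
  a <- derive_outcomes(reports, p, "direct_adj", "any_major_bleed")
  tab <- cross_classify(r, a)
  bd <- discordance_breakdown(r, a, routine_ev, episodes, reports, 90)
  expect_equal(unname(bd$routine_only),
               c(1, 1, 1, 0))  # refuted, minor, nothing reported, other
  expect_equal(unname(bd$adjudicated_only),
               c(1, 1, 1))  # code-not-major, hospitalised-no-code, no record
  expect_equal(sum(bd$routine_only), tab$routine_only)
  expect_equal(sum(bd$adjudicated_only), tab$adjudicated_only)
})

test_that("discordance splits sum to the discordant cells on a simulated cohort", {
  coh <- simulate_cohort(sim_config(n_participants = 4000, seed = 41))
  ev <- extract_routine_bleeds(coh$hospital_episodes, coh$death_records)
  cl <- classify_severity(ev, primary_algorithm())
  r <- derive_outcomes(cl, coh$participants, "routine", "any_major_bleed")
  a <- derive_outcomes(coh$direct_reports, coh$participants, "direct_adj",
                       "any_major_bleed")
  tab <- cross_classify(r, a)
  bd <- discordance_breakdown(r, a, cl, coh$hospital_episodes,
                              coh$direct_reports, 90)
  expect_equal(sum(bd$adjudicated_only), tab$adjudicated_only)
  expect_equal(sum(bd$routine_only), tab$routine_only)
  expect_true(all(bd$adjudicated_only >= 0) && all(bd$routine_only >= 0))
})

test_that("lowering routine capture degrades sensitivity", {
  sens_at <- function(p_cap, seed) {
    coh <- simulate_cohort(sim_config(n_participants = 6000, seed = seed,
                                      p_routine_capture = p_cap,
                                      p_direct_capture = 1,
                                      p_false_report = 0))
    cl <- classify_severity(
      extract_routine_bleeds(coh$hospital_episodes, coh$death_records),
      primary_algorithm())
    r <- derive_outcomes(cl, coh$participants, "routine", "any_major_bleed")
    a <- derive_outcomes(coh$direct_reports, coh$participants, "direct_adj",
                         "any_major_bleed")
    suppressWarnings(sens_spec(cross_classify(r, a))$sensitivity$estimate)
  }
  drops <- vapply(1:5, function(s) sens_at(0.9, s) - sens_at(0.4, s),
                  numeric(1))
  expect_true(all(drops > 0))
})
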