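test_that("identical event patterns in both arms give a rate ratio of 1", {
  d <- data.frame(arm = rep(c("active", "control"), each = 5),
                  event = rep(c(TRUE, TRUE, FALSE, TRUE, FALSE), 2),
                  time = rep(c(3, 8, 10, 14, 20), 2))
  rr <- logrank_rr(d)
  expect_equal(rr$rr, 1)
  expect_equal(rr$observed_minus_expected, 0)
})

test_that("the four-participant toy example matches the hand-computed risk-set table", {
  # active events at day 1 and 2; control event day 3, censored day 4:
  # t=1: O-E contribution 1 - 2/4; V = (2/4)(2/4)(3/3)
  # t=2: 1 - 1/3;                 V = (1/3)(2/3)(2/2)
  # t=3: 0 - 0;                   V = 0 (single-arm risk set)
  d <- data.frame(arm = c("active", "active", "control", "control"),
                  event = c(TRUE, TRUE, TRUE, FALSE),
                  time = c(1, 2, 3, 4))
  rr <- logrank_rr(d)
  expect_equal(rr$observed_minus_expected, 2 - 5 / 6, tolerance = 1e-12)
  expect_equal(rr$variance, 1 / 4 + 2 / 9, tolerance = 1e-12)
  expect_equal(rr$rr, exp((7 / 6) / (17 / 36)), tolerance = 1e-12)
})

test_that("log-rank O, E, V agree with survival::survdiff on random instances", {
  set.seed(11)
  for (i in 1:25) {
    d <- random_surv_instance(sample(10:40, 1))
    if (!any(d$event) || length(unique(d$arm)) < 2) next
    rr <- suppressWarnings(logrank_rr(d))
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ arm, data = d)
    act <- which(sort(unique(d$arm)) == "active")
    expect_equal(rr$observed_minus_expected,
                 unname(sd_$obs[act] - sd_$exp[act]), tolerance = 1e-10)
    expect_equal(rr$variance, unname(sd_$var[act, act]), tolerance = 1e-10)
  }
})

test_that("the rate ratio is invariant to uniform time rescaling", {
  set.seed(3)
  d <- random_surv_instance(40, tie_prob = 0)
  rr1 <- logrank_rr(d)
  d$time <- d$time * 3.7
  rr2 <- logrank_rr(d)
  expect_equal(rr1$rr, rr2$rr, tolerance = 1e-12)
  expect_equal(rr1$ci, rr2$ci, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged", {
  expect_error(logrank_rr(data.frame(arm = "active", event = FALSE, time = 5)),
               "no events")
  # all events in a one-arm risk set: zero variance
  d <- data.frame(arm = c("active", "control"), event = c(TRUE, FALSE),
                  time = c(5, 1))
  expect_warning(rr <- logrank_rr(d), "variance")
  expect_true(is.na(rr$rr))
})

test_that("absolute excess is the scaled rate difference with a Poisson SE", {
  eq <- absolute_excess(list(events = 100, person_years = 10000),
                        list(events = 100, person_years = 10000))
  expect_equal(eq$excess, 0)
  ex <- absolute_excess(list(events = 314, person_years = 57000),
                        list(events = 245, person_years = 57000))
  expect_equal(ex$excess, 5000 * (314 - 245) / 57000, tolerance = 1e-12)
  expect_equal(round(ex$excess, 2), 6.05)
  expect_equal(ex$se, 5000 * sqrt(314 / 57000^2 + 245 / 57000^2),
               tolerance = 1e-12)
  # doubling counts and person-years leaves the excess unchanged
  dbl <- absolute_excess(list(events = 628, person_years = 114000),
                         list(events = 490, person_years = 114000))
  expect_equal(dbl$excess, ex$excess, tolerance = 1e-12)
  expect_error(absolute_excess(list(events = 0, person_years = 0),
                               list(events = 1, person_years = 10)),
               "person-years")
  # data.frame interface agrees with the count interface
  d <- data.frame(event = c(TRUE, FALSE, TRUE), time = c(100, 500, 300))
  viadf <- absolute_excess(d, list(events = 1, person_years = 5))
  expect_equal(viadf$events[["active"]], 2)
  expect_equal(viadf$person_years[["active"]], 900 / 365.25)
})

test_that("bootstrap of identical sources gives a zero difference and is seed-reproducible", {
  coh <- simulate_cohort(perfect_capture_config(2000, seed = 5))
  a <- derive_outcomes(coh$direct_reports, coh$participants, "direct_adj",
                       "any_major_bleed")
  bd <- rr_difference_bootstrap(a, a, n_boot = 200, seed = 42)
  expect_equal(bd$difference, 0)
  expect_equal(bd$ci, c(0, 0))
  bd2 <- rr_difference_bootstrap(a, a, n_boot = 200, seed = 42)
  expect_identical(bd$ci, bd2$ci)
  expect_error(rr_difference_bootstrap(a, a, n_boot = 50, seed = 1),
               "n_boot")
  expect_error(rr_difference_bootstrap(a, a, n_boot = 200), "seed")
})

test_that("bootstrap CI covers zero when both sources capture the same events", {
  covered <- vapply(1:20, function(s) {
    coh <- simulate_cohort(perfect_capture_config(3000, seed = 100 + s))
    cl <- classify_severity(
      extract_routine_bleeds(coh$hospital_episodes, coh$death_records),
      primary_algorithm())
    r <- derive_outcomes(cl, coh$participants, "routine", "any_major_bleed")
    a <- derive_outcomes(coh$direct_reports, coh$participants, "direct_adj",
                         "any_major_bleed")
    bd <- suppressWarnings(rr_difference_bootstrap(r, a, n_boot = 200,
                                                   seed = s))
    bd$ci[1] <= 0 && 0 <= bd$ci[2]
  }, logical(1))
  expect_gte(sum(covered), 17)
})

test_that("a one-algorithm sweep equals the direct log-rank computation and is deterministic", {
  coh <- simulate_cohort(sim_config(n_participants = 3000, seed = 19))
  sw <- algorithm_sweep(coh, algorithms = list(primary = primary_algorithm()))
  expect_equal(nrow(sw), 1)
  cl <- classify_severity(
    extract_routine_bleeds(coh$hospital_episodes, coh$death_records),
    primary_algorithm())
  direct <- logrank_rr(as_surv_data(
    derive_outcomes(cl, coh$participants, "routine", "any_major_bleed")))
  expect_equal(sw$rr, direct$rr, tolerance = 1e-12)
  sw2 <- algorithm_sweep(coh, algorithms = list(primary = primary_algorithm()))
  expect_identical(sw, sw2)
  expect_error(algorithm_sweep(coh, algorithms = list()), "empty")
})

test_that("sweep rows are ordered by strictness and anchored by the two named presets", {
  coh <- simulate_cohort(sim_config(n_participants = 3000, seed = 29))
  sw <- algorithm_sweep(coh)
  expect_equal(nrow(sw), 15)
  expect_true(!is.unsorted(sw$strictness))
  expect_true(all(c("all_bleeds_major", "primary") %in% sw$algorithm))
  # all_bleeds_major counts at least as many events as any other algorithm
  tot <- sw$events_active + sw$events_control
  expect_equal(max(tot), tot[sw$algorithm == "all_bleeds_major"])
})
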