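test_that("code matching is prefix-based after dot-stripping and uppercasing", {
  m <- default_bleed_code_map()
  got <- match_icd10(c("I61.9", "k920", "K92.0", "K625", "J18.9", "??", ""), m)
  expect_equal(got$category,
               c("intracranial", "gastrointestinal", "gastrointestinal",
                 "gastrointestinal", NA, NA, NA))
  expect_equal(got$malformed, c(rep(FALSE, 5), TRUE, TRUE))
  expect_equal(got$subsite[4], "lower")
})

test_that("a code mapping to two categories is rejected", {
  expect_error(bleed_code_map(data.frame(
    code = c("K92.0", "K920"), category = c("gastrointestinal", "other"))),
    "two categories")
})

test_that("hospital and death records yield candidate events per the admission/death date rule", {
  ep <- data.frame(participant_id = "P1",
                   admission_date = as.Date("2012-03-01"),
                   discharge_date = as.Date("2012-03-04"),
                   icd10_code = "I61.9", diagnostic_position = 3L)
  dth <- data.frame(participant_id = c("P2", "P2", "P3"),
                    death_date = as.Date("2013-05-05"),
                    icd10_code = c("K92.2", "I25.1", "J44.9"),
                    role = c("contributory", "underlying_cause",
                             "underlying_cause"))
  ev <- extract_routine_bleeds(ep, dth)
  expect_equal(nrow(ev), 2)
  ich <- ev[ev$participant_id == "P1", ]
  expect_equal(ich$bleed_category, "intracranial")
  expect_equal(ich$diagnostic_position, 3L)
  expect_equal(ich$event_date, as.Date("2012-03-01"))
  expect_true(ich$overnight_stay)
  # bleeding code in contributory position: an event, but never fatal
  contrib <- ev[ev$participant_id == "P2", ]
  expect_equal(contrib$source, "death")
  expect_false(contrib$fatal)
  expect_equal(classify_severity(contrib, primary_algorithm())$severity,
               "minor")
})

test_that("empty inputs give an empty, well-typed event table", {
  ev <- extract_routine_bleeds(NULL, NULL)
  expect_equal(nrow(ev), 0)
  expect_true(all(c("participant_id", "event_date", "bleed_category",
                    "severity") %in%
                    names(classify_severity(ev, primary_algorithm()))))
})

test_that("malformed code strings are skipped with a log message, not silently", {
  ep <- data.frame(participant_id = c("P1", "P2"),
                   admission_date = as.Date("2012-03-01"),
                   discharge_date = as.Date("2012-03-02"),
                   icd10_code = c("not-a-code", "K92.0"),
                   diagnostic_position = 1L)
  expect_message(ev <- extract_routine_bleeds(ep, NULL), "malformed")
  expect_equal(ev$participant_id, "P2")
})

test_that("the primary algorithm reproduces the four worked severity classifications", {
  alg <- primary_algorithm()
  # intracranial, any position, same-day discharge -> major
  e1 <- routine_event_row("P1", 10, "intracranial", position = 2,
                          overnight = FALSE)
  # gastrointestinal in secondary position, 3-night stay -> minor
  e2 <- routine_event_row("P2", 10, "gastrointestinal", position = 2,
                          overnight = TRUE)
  # gastrointestinal primary position but same-day discharge -> minor
  e3 <- routine_event_row("P3", 10, "gastrointestinal", position = 1,
                          overnight = FALSE)
  # gastrointestinal as underlying cause of death -> major
  e4 <- routine_event_row("P4", 10, "gastrointestinal", source = "death",
                          fatal = TRUE)
  got <- classify_severity(rbind(e1, e2, e3, e4), alg)$severity
  expect_equal(got, c("major", "minor", "minor", "major"))
})

test_that("classification is deterministic and a missing category rule errors", {
  e <- routine_event_row("P1", 1, "gastrointestinal", position = 1,
                         overnight = TRUE)
  a <- classify_severity(e, primary_algorithm())$severity
  expect_equal(a, classify_severity(e, primary_algorithm())$severity)
  e$bleed_category <- "nonsense"
  expect_error(classify_severity(e, primary_algorithm()), "no severity rule")
})

test_that("the grid has 15 named algorithms ordered by strictness, with the two anchors", {
  grid <- algorithm_grid()
  expect_length(grid, 15)
  expect_true(all(c("all_bleeds_major", "primary") %in% names(grid)))
  s <- vapply(grid, algorithm_strictness, numeric(1))
  expect_true(!is.unsorted(s))
  expect_equal(algorithm_strictness(grid$all_bleeds_major), 0)
  # the primary preset: any position for intracranial/eye, primary +
  # overnight for gastrointestinal/other
  pr <- grid$primary$rules
  expect_equal(pr$intracranial$position_scope, "any_position")
  expect_false(pr$eye$require_overnight)
  expect_equal(pr$gastrointestinal$position_scope, "primary_only")
  expect_true(pr$other$require_overnight)
})

test_that("all_bleeds_major classifies every extracted event as major", {
  coh <- simulate_cohort(sim_config(n_participants = 2000, seed = 31))
  ev <- extract_routine_bleeds(coh$hospital_episodes, coh$death_records)
  cl <- classify_severity(ev, all_bleeds_major_algorithm())
  hosp <- cl$source == "hospital"
  expect_true(all(cl$severity[hosp] == "major"))
  # death-source events are still governed by the underlying-cause rule
  expect_equal(cl$severity[!hosp] == "major", cl$fatal[!hosp])
})

test_that("relaxing any rule component never shrinks the major-event set", {
  set.seed(42)
  cats <- c("intracranial", "eye", "gastrointestinal", "other")
  events <- do.call(rbind, lapply(1:120, function(i)
    routine_event_row(sprintf("P%03d", i), i %% 50,
                      sample(cats, 1), position = sample(1:4, 1),
                      overnight = runif(1) < 0.5)))
  grid <- algorithm_grid()
  stricter <- function(a, b) { # TRUE if a's rules are all >= b's restrictions
    all(vapply(cats, function(cat) {
      ra <- a$rules[[cat]]; rb <- b$rules[[cat]]
      (ra$position_scope == "primary_only" ||
         rb$position_scope == "any_position") &&
        (ra$require_overnight || !rb$require_overnight)
    }, logical(1)))
  }
  majors <- lapply(grid, function(alg) {
    cl <- classify_severity(events, alg)
    which(cl$severity == "major")
  })
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    if (i == j || !stricter(grid[[i]], grid[[j]])) next
    expect_true(all(majors[[i]] %in% majors[[j]]),
                info = paste(names(grid)[i], "vs", names(grid)[j]))
  }
})

test_that("extraction and classification are order-independent and idempotent", {
  coh <- simulate_cohort(sim_config(n_participants = 1000, seed = 17))
  ev1 <- extract_routine_bleeds(coh$hospital_episodes, coh$death_records)
  shuf <- coh$hospital_episodes[sample(nrow(coh$hospital_episodes)), ]
  ev2 <- extract_routine_bleeds(shuf, coh$death_records)
  rownames(ev1) <- rownames(ev2) <- NULL
  expect_equal(ev1, ev2)
  cl1 <- classify_severity(ev1, primary_algorithm())
  expect_equal(classify_severity(cl1, primary_algorithm())$severity,
               cl1$severity)
})
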