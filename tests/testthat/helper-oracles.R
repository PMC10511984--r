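# Independent oracles and small builders used across test files.

# Brute-force log-rank: explicit risk-set enumeration per distinct event
# time, one subset operation at a time. Deliberately naive and independent
# of the package's vectorised accumulation.
oracle_logrank <- function(arm, event, time) {
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & arm == "active")
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & arm == "active")
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(o = o, e = e, v = v, rr = exp((o - e) / v))
}

# Direct-formula kappa / sensitivity / specificity from the four cells.
oracle_agreement <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  list(kappa = (po - pe) / (1 - pe),
       sens = a / (a + c),
       spec = d / (d + b))
}

random_surv_instance <- function(n, tie_prob = 0.5) {
  time <- if (runif(1) < tie_prob) sample(1:8, n, replace = TRUE)
  else round(rexp(n, 0.2), 3)
  data.frame(arm = sample(c("active", "control"), n, replace = TRUE),
             event = runif(n) < 0.6,
             time = time)
}

mini_participants <- function(n, arm = rep("control", n), fu = rep(1000, n),
                              linked = rep(TRUE, n)) {
  data.frame(participant_id = sprintf("P%02d", seq_len(n)),
             arm = arm,
             randomisation_date = as.Date("2010-01-01"),
             end_of_followup = as.Date("2010-01-01") + fu,
             died = FALSE, linked = linked)
}

# a routine-event row in the shape extract_routine_bleeds() emits
routine_event_row <- function(id, day, category, position = 1L,
                              overnight = TRUE, source = "hospital",
                              fatal = FALSE) {
  data.frame(participant_id = id,
             event_date = as.Date("2010-01-01") + day,
             bleed_category = category, subsite = NA_character_,
             source = source, diagnostic_position = as.integer(position),
             overnight_stay = overnight, fatal = fatal)
}

# perfect-capture configuration: the two sources see exactly the true
# major-bleed set
perfect_capture_config <- function(n, seed, ...) {
  sim_config(n_participants = n, seed = seed,
             p_routine_capture = 1, p_direct_capture = 1,
             p_false_report = 0, p_unlinked = 0, ...)
}
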