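# Builders for small hand-specified cohorts used across test files.

# events for one trial: perfect cyclic typing, n_press presses at fixed
# intervals, first press at t0
perfect_trial_events <- function(n_press, dt = 0.4, t0 = 0.5,
                                 pattern = c(4L, 1L, 3L, 2L, 4L)) {
  if (n_press == 0L) {
    return(data.frame(key = integer(), time = numeric()))
  }
  data.frame(
    key = pattern[((seq_len(n_press) - 1L) %% length(pattern)) + 1L],
    time = t0 + (seq_len(n_press) - 1L) * dt
  )
}

# assemble a full-schedule cohort from a per-trial event generator
# f(participant, session, trial) -> data.frame(key, time) or NULL
build_manual_cohort <- function(participants, task = task_spec(),
                                trial_fun, sessions_meta = NULL) {
  rows <- list()
  for (pp in participants) {
    for (s in seq_len(task$n_sessions)) {
      for (tr in seq_len(task$trials_per_session[s])) {
        ev <- trial_fun(pp, s, tr)
        if (!is.null(ev) && nrow(ev)) {
          rows[[length(rows) + 1L]] <- data.frame(
            participant = pp, session = s, trial = tr,
            key = ev$key, time = ev$time
          )
        }
      }
    }
  }
  events <- do.call(rbind, rows)
  if (is.null(sessions_meta)) {
    sessions_meta <- expand.grid(participant = participants,
                                 session = seq_len(task$n_sessions),
                                 stringsAsFactors = FALSE)
    sessions_meta$sleep_duration <- 8
    sessions_meta$sleep_quality <- 4L
    sessions_meta$reported_hand <- "left"
  }
  cohort(events, sessions = sessions_meta, task = task)
}

# The 12-participant screening fixture: one participant per rule and
# boundary. Hand-derived expected survivor sets live in the tests.
screening_fixture <- function() {
  task <- task_spec()
  pps <- sprintf("p%02d", 1:12)
  meta <- expand.grid(participant = pps, session = 1:5,
                      stringsAsFactors = FALSE)
  meta$sleep_duration <- 8
  meta$sleep_quality <- 4L
  meta$reported_hand <- "left"
  set_meta <- function(m, pp, s, field, value) {
    m[m$participant == pp & m$session == s, field] <- value
    m
  }
  meta <- set_meta(meta, "p07", 3, "sleep_duration", 5)     # below range
  meta <- set_meta(meta, "p08", 2, "sleep_duration", 6)     # boundary low
  meta <- set_meta(meta, "p08", 3, "sleep_duration", 12)    # boundary high
  meta <- set_meta(meta, "p09", 5, "sleep_duration", 12.5)  # above range
  meta <- set_meta(meta, "p10", 4, "reported_hand", "right")
  meta <- set_meta(meta, "p11", 4, "sleep_duration", NA)

  trial_fun <- function(pp, s, tr) {
    n_press <- 20L; t0 <- 0.5; dt <- 0.4
    if (pp == "p02" && s == 2) n_press <- 8L    # mean input 8 < 9
    if (pp == "p03" && s == 3) n_press <- 9L    # mean input exactly 9
    if (pp == "p04" && s == 2 && tr <= 6) t0 <- 2.5   # 6 slow starts
    if (pp == "p05" && s == 2 && tr <= 5) t0 <- 2.5   # exactly 5
    if (pp == "p06" && s == 4 && tr <= 3) t0 <- 2.5   # 3 slow starts ...
    if (pp == "p06" && s == 4 && tr %in% 4:6) return(NULL) # + 3 no-response
    if (pp == "p12") t0 <- 2.0                  # exactly at the threshold
    if (t0 > 2) dt <- 0.35  # keep the last press inside the 10-s trial
    perfect_trial_events(n_press, dt = dt, t0 = t0)
  }
  build_manual_cohort(pps, task, trial_fun, meta)
}

# small generated cohort shared by io/scoring tests
tiny_cohort <- function(n = 8, seed = 42, ...) {
  generate_cohort(synthetic_config(n_participants = n, seed = seed, ...))
}
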