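test_that("correct keypresses are counted per the sequence rule", {
  # one full repetition scores pattern length
  s <- score_trial(c(4, 1, 3, 2, 4))
  expect_equal(s$correct_keypresses, 5)
  expect_equal(s$complete_sequences, 1)
  expect_equal(s$trailing_partial, 0)

  # a trailing incomplete repetition counts its presses
  s <- score_trial(c(4, 1, 3))
  expect_equal(s$correct_keypresses, 3)
  expect_equal(s$complete_sequences, 0)
  expect_equal(s$trailing_partial, 3)

  # empty trial
  s <- score_trial(integer())
  expect_equal(s$correct_keypresses, 0)
  expect_false(s$responded)

  # error recovery: the 4 after a broken attempt starts a new sequence
  keys <- c(4, 1, 3, 2, 4, 4, 1, 2, 4, 1, 3, 2, 4)
  s <- score_trial(keys)
  orc <- oracle_score_one(keys, task_spec()$pattern)
  expect_equal(s$complete_sequences, orc$complete)
  expect_equal(s$correct_keypresses, orc$correct)
  expect_equal(s$complete_sequences, 2)
  expect_equal(s$trailing_partial, 0)
  expect_equal(s$correct_keypresses, 10)
})

test_that("keys outside the task alphabet are mismatches, not errors", {
  s <- score_trial(c(4, 1, 9, 4, 1, 3, 2, 4))
  expect_equal(s$complete_sequences, 1)
  expect_equal(s$total_keypresses, 8)
  expect_equal(s$correct_keypresses, 5)
})

test_that("scoring arithmetic and oracle equivalence hold on random strings", {
  set.seed(101)
  task <- task_spec()
  keymat <- random_key_matrix(2000, 60)
  orc <- oracle_score_matrix(keymat, task$pattern)
  for (i in seq_len(nrow(keymat))) {
    keys <- keymat[i, !is.na(keymat[i, ])]
    s <- score_trial(keys)
    # invariant: correct = 5 x complete + partial
    expect_identical(
      s$correct_keypresses,
      s$complete_sequences * task$pattern_length + s$trailing_partial)
    if (s$complete_sequences != orc$complete[i] ||
          s$trailing_partial != orc$partial[i]) {
      fail(paste("matcher/oracle disagreement on",
                 paste(keys, collapse = "")))
    }
  }
  succeed()
})

test_that("appending the next expected key never decreases the score", {
  set.seed(7)
  pat <- task_spec()$pattern
  for (rep in 1:50) {
    keys <- sample(1:4, sample(0:30, 1), replace = TRUE)
    s0 <- score_trial(keys)
    nxt <- pat[s0$trailing_partial + 1L]
    s1 <- score_trial(c(keys, nxt))
    expect_equal(s1$correct_keypresses, s0$correct_keypresses + 1L)
  }
})

test_that("session summaries use the mean of the 3 best trials", {
  expect_equal(summarize_session(c(10, 20, 30))$max_performance, 20)
  expect_equal(summarize_session(rep(25, 36))$max_performance, 25)
  expect_equal(summarize_session(c(5, 10, 15, 20, 25, 30))$max_performance,
               (30 + 25 + 20) / 3)
  # permutation invariance of the trial order
  v <- c(3, 29, 17, 8, 24, 11)
  expect_equal(summarize_session(v)$max_performance,
               summarize_session(rev(v))$max_performance)
  sh <- summarize_session(c(10, 20))
  expect_true(sh$short_session)
  expect_equal(sh$max_performance, 15)
  expect_error(summarize_session(numeric()), "zero trials")
})

test_that("gain table entries are differences of max performance", {
  sm <- data.frame(
    participant = rep(c("a", "b"), c(5, 2)),
    session = c(1:5, 1:2),
    max_performance = c(20, 24, 28, 32, 25, 20, 20),
    mean_performance = 0, mean_input_chars = 0,
    n_trials = 36, short_session = FALSE
  )
  g <- compute_gains(sm)
  a <- g[g$participant == "a", ]
  expect_equal(a$offline_s1_s2, 4)
  expect_equal(a$total_learning_s1_s4, 12)
  expect_equal(a$long_retention_s4_s5, -7)
  b <- g[g$participant == "b", ]
  expect_equal(b$offline_s1_s2, 0)
  expect_true(is.na(b$total_learning_s1_s4))
})

test_that("speed profiles use completed-sequence durations", {
  # constant 0.25 s intervals: every sequence spans 1.0 s -> 5 keys/s
  ev <- perfect_trial_events(40, dt = 0.25, t0 = 0.25)
  sp <- speed_profile(ev$key, ev$time)
  expect_equal(unique(sp$speeds), 5)
  expect_equal(sp$start_speed, sp$end_speed)
  # the same construction scores 40 correct keypresses
  expect_equal(score_trial(ev$key)$correct_keypresses, 40)

  # single completed sequence: start equals end
  ev <- perfect_trial_events(5, dt = 0.3)
  sp <- speed_profile(ev$key, ev$time)
  expect_length(sp$speeds, 1)
  expect_equal(sp$start_speed, sp$end_speed)

  # no completed sequence: missing, not zero
  sp <- speed_profile(c(4, 1, 3), c(0.1, 0.2, 0.3))
  expect_true(is.na(sp$start_speed))
  expect_length(sp$speeds, 0)
})

test_that("batch cohort scoring matches per-trial scoring", {
  gen <- tiny_cohort(n = 4, seed = 9)
  sc <- score_cohort(gen$cohort)
  ev <- gen$cohort$events
  # spot-check 20 random scheduled trials against score_trial()
  set.seed(1)
  rows <- sc$trials[sample(nrow(sc$trials), 20)]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i]
    keys <- ev[participant == r$participant & session == r$session &
                 trial == r$trial, key]
    s <- score_trial(keys)
    expect_identical(r$correct, s$correct_keypresses)
    expect_identical(r$total, s$total_keypresses)
  }
})
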