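test_that("latent sampling is seed-deterministic and sized correctly", {
  cfg <- synthetic_config(n_participants = 100, seed = 1)
  a <- sample_participants(cfg)
  b <- sample_participants(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 100)
  expect_equal(nrow(sample_participants(
    synthetic_config(n_participants = 0))), 0)
})

test_that("invalid distribution specs name the offending field", {
  cfg <- synthetic_config(n_participants = 5)
  cfg$distributions$error_rate <- list(family = "cauchy", location = 0)
  expect_error(sample_participants(cfg), "error_rate")
})

test_that("expected speed follows the closed-form learning curve", {
  lat <- list(baseline_speed = 6, gain_total = 4, learning_rate = 0.2,
              fatigue_rate = 0.02, consolidation_gain = 0,
              decay_fraction = 0)
  # hand computation: 6 + 4 (1 - e^(-0.2 * 35)) - 0.02 * 35
  expect_equal(expected_speed(lat, 1, 36), 9.2963525, tolerance = 1e-6)

  # saturation limit: huge rate reaches s0 + G by trial 2
  lat$learning_rate <- 50; lat$fatigue_rate <- 0
  expect_equal(expected_speed(lat, 1, 2), 10, tolerance = 1e-10)

  # no-learning participant is flat across trials and sessions
  flat <- list(baseline_speed = 3, gain_total = 0, learning_rate = 0.5,
               fatigue_rate = 0, consolidation_gain = 0,
               decay_fraction = 0.5)
  for (s in 1:5) for (tr in c(1, 9, 36)) {
    expect_equal(expected_speed(flat, s, tr), 3)
  }

  # consolidation accumulates over sessions 1-4, decay hits session 5
  lat2 <- list(baseline_speed = 2, gain_total = 0, learning_rate = 0.1,
               fatigue_rate = 0, consolidation_gain = 0.2,
               decay_fraction = 0.5)
  expect_equal(expected_speed(lat2, 4, 1), 2.6)
  expect_equal(expected_speed(lat2, 5, 1), 2.3)
})

test_that("simulated trials are deterministic given the RNG state", {
  cfg <- synthetic_config(interval_sdlog = 0, latency_sdlog = 0)
  set.seed(5)
  a <- simulate_trial(4, error_rate = 0, config = cfg)
  # deterministic intervals: presses at 0.5, 0.75, ..., count known
  expect_equal(nrow(a), 39)
  expect_equal(score_trial(a$key)$correct_keypresses, 39)
  set.seed(99)
  b1 <- simulate_trial(3, error_rate = 0.1)
  set.seed(99)
  b2 <- simulate_trial(3, error_rate = 0.1)
  expect_identical(b1, b2)
})

test_that("degenerate speeds give near-empty trials, never an error", {
  cfg <- synthetic_config(interval_sdlog = 0, latency_sdlog = 0)
  set.seed(1)
  ev <- simulate_trial(0.01, config = cfg)  # floored at 0.2 keys/s
  expect_lte(nrow(ev), 3)
})

test_that("scored performance tracks expected speed when noise is off", {
  cfg <- synthetic_config(
    n_participants = 4, seed = 8,
    dropout_per_session = 0, sleep_violation_rate = 0,
    interval_sdlog = 0, latency_sdlog = 0)
  cfg$distributions$noise_sd <- list(family = "constant", value = 0,
                                     min = 0, max = 1)
  cfg$distributions$error_rate <- list(family = "constant", value = 0,
                                       min = 0, max = 1)
  gen <- generate_cohort(cfg)
  sc <- score_cohort(gen$cohort)
  task <- task_spec()
  tr <- merge(sc$trials, gen$truth, by = "participant")
  for (i in seq_len(nrow(tr))) {
    exp_sp <- expected_speed(tr[i], tr$session[i], tr$trial[i])
    expect_lte(abs(tr$correct[i] - round(exp_sp * task$trial_duration)),
               task$pattern_length)
  }
})

test_that("attrition is monotone and cohort generation is reproducible", {
  cfg <- synthetic_config(n_participants = 30, seed = 7,
                          dropout_per_session = 0.3)
  gen <- generate_cohort(cfg)
  present <- table(gen$cohort$sessions$session)
  expect_true(all(diff(as.integer(present)) <= 0))
  # per participant: sessions contiguous from 1
  by_pp <- split(gen$cohort$sessions$session,
                 gen$cohort$sessions$participant)
  for (s in by_pp) expect_equal(sort(s), seq_along(s))
  # identical config: byte-identical written cohort
  d <- withr::local_tempdir()
  write_cohort(gen$cohort, file.path(d, "a"))
  write_cohort(generate_cohort(cfg)$cohort, file.path(d, "b"))
  fa <- file.path(d, "a", "keystrokes.csv")
  fb <- file.path(d, "b", "keystrokes.csv")
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("a clean configuration passes screening untouched", {
  cfg <- synthetic_config(n_participants = 10, seed = 2,
                          dropout_per_session = 0,
                          sleep_violation_rate = 0)
  cfg$distributions$error_rate <- list(family = "constant", value = 0,
                                       min = 0, max = 1)
  # keep every simulated participant well above the 9-char qualification
  cfg$distributions$baseline_speed$min <- 1.5
  gen <- generate_cohort(cfg)
  scr <- apply_screening(gen$cohort)
  expect_equal(nrow(scr$report$audit), 0)
  expect_equal(scr$cohort$events, gen$cohort$events)
})

test_that("null regime draws learning independent of baseline", {
  cfg <- synthetic_config(n_participants = 2000, seed = 31)
  lat <- sample_participants(cfg)
  expect_lt(abs(cor(lat$baseline_speed, lat$gain_total)), 0.05)
  expect_lt(abs(cor(lat$baseline_speed, lat$consolidation_gain)), 0.05)
})

test_that("predictable regime ties learning to session-1 latents", {
  cfg <- synthetic_config(n_participants = 500, seed = 31,
                          regime = "predictable_learning")
  lat <- sample_participants(cfg)
  expect_gt(cor(lat$baseline_speed, lat$consolidation_gain), 0.9)
  expect_gt(cor(lat$baseline_speed, lat$gain_total), 0.5)
})
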