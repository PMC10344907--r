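curve_fn <- function(t, p0, g, r, f) {
  p0 + g * (1 - exp(-r * (t - 1))) - f * (t - 1)
}

test_that("noise-free learning curves are recovered to high precision", {
  y <- curve_fn(1:36, 50, 30, 0.15, 0.3)
  fit <- fit_learning_curve(y)
  expect_true(fit$converged)
  expect_equal(fit$p0, 50, tolerance = 1e-4)
  expect_equal(fit$gain, 30, tolerance = 1e-4)
  expect_equal(fit$learning_rate, 0.15, tolerance = 1e-4)
  expect_equal(fit$fatigue_rate, 0.3, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
})

test_that("degenerate inputs fit degenerately", {
  fit <- fit_learning_curve(rep(60, 36))
  expect_equal(fit$p0, 60)
  expect_equal(fit$gain, 0)
  expect_equal(fit$rss, 0)
  expect_error(fit_learning_curve(c(1, 2, 3)), "at least 8")
})

test_that("rate estimates are unbiased enough under trial noise", {
  # reduced-size replicate of the recovery study (full run in the
  # acceptance suite): median estimates near truth under sd-5 noise
  set.seed(21)
  truth <- list(p0 = 50, g = 30, r = 0.35, f = 0.3)
  est <- replicate(40, {
    y <- curve_fn(1:36, truth$p0, truth$g, truth$r, truth$f) + rnorm(36, 0, 5)
    fit <- fit_learning_curve(y)
    c(fit$learning_rate, fit$fatigue_rate)
  })
  # ballpark bounds only: at 40 replicates the Monte-Carlo noise of the
  # median is itself ~0.07; the strict 200-replicate study runs in the
  # acceptance suite
  expect_lt(abs(median(est[1, ]) - truth$r), 0.1)
  expect_lt(abs(median(est[2, ]) - truth$f), 0.1)
})

test_that("LOWESS features reproduce linear and unimodal structure", {
  y <- 2 * (1:36)
  f <- lowess_features(y)
  expect_equal(f[["lowess_first"]], 2, tolerance = 1e-6)
  expect_equal(f[["lowess_last"]], 72, tolerance = 1e-6)
  expect_equal(f[["lowess_slope_early"]], 2, tolerance = 1e-6)
  expect_equal(f[["lowess_slope_late"]], 2, tolerance = 1e-6)

  fc <- lowess_features(rep(25, 36))
  expect_equal(fc[["lowess_slope_early"]], 0)
  expect_equal(fc[["lowess_max"]], 25)

  # noise-free unimodal profile peaking at trial 20
  yu <- 30 - 0.15 * ((1:36) - 20)^2
  fu <- lowess_features(yu)
  expect_lte(abs(fu[["lowess_argmax"]] - 20), 1)
})

test_that("session statistics use sample conventions", {
  ts <- data.frame(trial = 1:3, correct = c(10, 20, 30),
                   total = c(12, 22, 32), responded = TRUE)
  st <- session_statistics(ts)
  expect_equal(st[["perf_mean"]], 20)
  expect_equal(st[["perf_sd"]], 10)  # sample (n-1) sd
  expect_equal(st[["accuracy"]], 60 / 66)
  expect_equal(st[["n_nonresponded"]], 0)

  tc <- data.frame(trial = 1:36, correct = 25, total = 25, responded = TRUE)
  sc <- session_statistics(tc)
  expect_equal(unname(sc[c("perf_mean", "perf_median", "perf_min",
                           "perf_max")]), rep(25, 4))
  expect_equal(sc[["perf_sd"]], 0)
  expect_equal(sc[["accuracy"]], 1)
})

test_that("consistency features match hand-computed values", {
  # metronomic typing: zero interval variance in every sequence
  ev <- perfect_trial_events(20, dt = 0.4)
  evs <- rbind(cbind(trial = 1L, ev), cbind(trial = 2L, ev))
  ts <- data.frame(trial = 1:2, correct = c(20, 20), total = c(20, 20))
  f <- consistency_features(evs, ts)
  expect_equal(f[["wsc_mean"]], 0)
  expect_equal(f[["wsc_slope"]], 0)
  expect_equal(f[["pattern_consistency_trend"]], 0)

  # two trials, one sequence each, with known interval CVs
  iv1 <- c(0.4, 0.4, 0.5, 0.3)   # cv1 = sd/mean
  iv2 <- c(0.2, 0.4, 0.6, 0.4)
  mk <- function(iv, trial) data.frame(
    trial = trial, key = c(4L, 1L, 3L, 2L, 4L), time = cumsum(c(0.5, iv)))
  evs <- rbind(mk(iv1, 1L), mk(iv2, 2L))
  ts <- data.frame(trial = 1:2, correct = c(5, 5), total = c(5, 5))
  f <- consistency_features(evs, ts)
  cv1 <- sd(iv1) / mean(iv1)
  cv2 <- sd(iv2) / mean(iv2)
  expect_equal(f[["wsc_mean"]], mean(c(cv1, cv2)))
  expect_equal(f[["wsc_slope"]], cv2 - cv1)
})

test_that("micro gains are start/end speed differences that telescope", {
  mg <- micro_gains(c(2, 3, 3, 4, 4), c(3, 3, 4, 4, 5))
  expect_equal(mg$micro_online, c(1, 0, 1, 0, 1))
  expect_equal(mg$micro_offline, c(0, 0, 0, 0))
  expect_equal(sum(mg$micro_online) + sum(mg$micro_offline), 5 - 2)

  mgc <- micro_gains(rep(3.3, 5), rep(3.3, 5))
  expect_true(all(mgc$micro_online == 0) && all(mgc$micro_offline == 0))

  # telescoping identity on random speeds
  set.seed(4)
  for (i in 1:20) {
    s <- runif(5, 1, 6); e <- runif(5, 1, 6)
    mg <- micro_gains(s, e)
    expect_equal(sum(mg$micro_online) + sum(mg$micro_offline),
                 e[5] - s[1])
  }
})

test_that("design assembly follows the step registry and is split-aware", {
  gen <- tiny_cohort(n = 12, seed = 13)
  ft <- build_features(gen$cohort)
  d0 <- assemble_design(ft, 0)
  expect_identical(colnames(d0$X), c("age", "gender_female"))
  d5 <- assemble_design(ft, 5)
  d6 <- assemble_design(ft, 6)
  expect_equal(ncol(d6$X), ncol(d5$X) + 36)
  # registry order is deterministic across calls
  ft2 <- build_features(gen$cohort)
  expect_identical(colnames(assemble_design(ft2, 6)$X), colnames(d6$X))
  expect_equal(assemble_design(ft2, 6)$X, d6$X)

  # imputation medians come from training rows only
  ids <- ft$table$participant
  ftna <- ft
  ftna$table <- data.table::copy(ft$table)
  ftna$table[1, "lc_rate"] <- NA_real_
  train <- ids[-1]
  d <- assemble_design(ftna, 1, train_ids = train, ids = ids)
  expect_equal(d$X[1, "lc_rate"],
               unname(d$medians["lc_rate"]), ignore_attr = TRUE)
  expect_equal(unname(d$medians["lc_rate"]),
               median(ftna$table$lc_rate[-1], na.rm = TRUE))
})
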