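test_that("targets are interval differences restricted to complete pairs", {
  sm <- data.frame(
    participant = rep(c("a", "b"), c(2, 1)),
    session = c(1, 2, 1),
    max_performance = c(20, 24, 30),
    mean_performance = 0, mean_input_chars = 0, n_trials = 36,
    short_session = FALSE)
  g <- compute_gains(sm)
  y <- make_targets(g, "s2-s1")
  expect_equal(y, c(a = 4))  # b lacks session 2
  expect_error(make_targets(g, "s5-s4"), "no participant")
})

test_that("retention targets are predominantly negative under decay", {
  gen <- tiny_cohort(n = 40, seed = 17, dropout_per_session = 0.1)
  scr <- apply_screening(gen$cohort)
  g <- compute_gains(summarize_cohort(score_cohort(scr$cohort)))
  y <- make_targets(g, "s5-s4")
  expect_gt(mean(y < 0), 0.5)
})

test_that("the hold-out split is a deterministic partition", {
  ids <- sprintf("x%03d", 1:100)
  sp <- split_holdout(ids, 0.2, seed = 5)
  expect_length(sp$holdout, 20)
  expect_length(sp$train, 80)
  expect_setequal(c(sp$train, sp$holdout), ids)
  expect_length(intersect(sp$train, sp$holdout), 0)
  expect_identical(sp, split_holdout(ids, 0.2, seed = 5))
  expect_error(split_holdout(ids[1:9]), "at least 10")
})

test_that("z-scoring uses training statistics and flags constants", {
  z <- zscore_transform(cbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                        cbind(a = 2, b = 9))
  expect_equal(z$train[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z$train[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(z$apply[, "a"], 0, ignore_attr = TRUE)  # at the train mean
  expect_equal(z$apply[, "b"], 0, ignore_attr = TRUE)  # constant column
  expect_equal(z$constant_cols, "b")
})

test_that("hold-out R2 follows its definition, including negative values", {
  fake <- structure(list(model = NULL, pca = NULL), class = "step_fit")
  with_mocked_bindings(
    xgb_predict = function(model, X) X[, 1],
    {
      X <- cbind(c(3, 2, 1))
      expect_equal(evaluate_holdout(fake, X, c(1, 2, 3)), -3)
      expect_equal(evaluate_holdout(fake, cbind(c(1, 2, 3)), c(1, 2, 3)), 1)
      expect_equal(evaluate_holdout(fake, cbind(c(2, 2, 2)), c(1, 2, 3)), 0)
      expect_warning(r <- evaluate_holdout(fake, X, c(2, 2, 2)), "constant")
      expect_true(is.na(r))
    }
  )
})

test_that("a grid of size 1 is returned as the best configuration", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(40)
  sp <- search_space(max_depth = 2L, learning_rate = 0.1, nrounds = 20L,
                     subsample = 1, reg_lambda = 1, pca = FALSE)
  fit <- fit_step(X, y, sp, seed = 1)
  expect_equal(nrow(fit$cv_table), 1)
  expect_equal(fit$best$max_depth, 2L)
  expect_equal(fit$best$nrounds, 20L)
})

test_that("a planted feature is recovered almost perfectly", {
  set.seed(11)
  n <- 120
  X <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- X[, "signal"]
  sp <- search_space(max_depth = c(2L, 3L), learning_rate = 0.1,
                     nrounds = 300L, subsample = 1, reg_lambda = 1,
                     pca = FALSE)
  split <- split_holdout(seq_len(n), 0.2, seed = 3)
  z <- zscore_transform(X[split$train, ], X[split$holdout, ])
  fit <- fit_step(z$train, y[split$train], sp, seed = 1)
  r2 <- evaluate_holdout(fit, z$apply, y[split$holdout])
  expect_gt(r2, 0.95)
})

test_that("the stepped protocol is deterministic and leakage-free", {
  gen <- tiny_cohort(n = 40, seed = 23, dropout_per_session = 0.05)
  scr <- apply_screening(gen$cohort)
  cs <- score_cohort(scr$cohort)
  g <- compute_gains(summarize_cohort(cs))
  ft <- build_features(scr$cohort, cs)
  sp <- search_space(max_depth = 2L, learning_rate = 0.1, nrounds = 20L,
                     subsample = 1, reg_lambda = 1, pca = c(FALSE, TRUE))
  r1 <- run_protocol(ft, g, intervals = "s2-s1", space = sp, seed = 9,
                     steps = 0:2)
  r2 <- run_protocol(ft, g, intervals = "s2-s1", space = sp, seed = 9,
                     steps = 0:2)
  expect_equal(r1$summary, r2$summary)
  expect_equal(r1$intervals[["s2-s1"]]$steps, r2$intervals[["s2-s1"]]$steps)
  # one row per scanned step, and a disjoint recorded split
  expect_equal(r1$intervals[["s2-s1"]]$steps$step, 0:2)
  sp_rec <- r1$intervals[["s2-s1"]]$split
  expect_length(intersect(sp_rec$train, sp_rec$holdout), 0)
  expect_lte(r1$summary$holdout_r2, 1)
})
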