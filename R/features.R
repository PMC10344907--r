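#' Fit a within-session learning curve with a fatigue term
#'
#' Nonlinear least-squares fit of
#' `P(t) = p0 + gain (1 - exp(-r (t - 1))) - f (t - 1)` to a per-trial
#' performance vector, `t = 1..n`. The saturating exponential captures
#' the fast early improvement and plateau typical of sequence tapping;
#' the linear term absorbs within-session fatigue accumulation. The fit
#' uses Levenberg-Marquardt with box constraints
#' (`r` in \[0, 5\], `f` in \[0, 3\], `gain` in \[0, 150\], `p0 >= 0`)
#' from 5 fixed starting points spread over the plausible rate range; the
#' lowest-RSS solution wins. If no start converges, a coarse profile
#' search over `r` with a linear subfit provides fallback estimates and
#' `converged` is `FALSE`.
#'
#' @param performance Numeric per-trial correct-keypress counts (NAs
#'   allowed; at least 8 non-missing trials required).
#' @return List of class `learning_curve_fit`: `p0`, `gain`,
#'   `learning_rate`, `fatigue_rate`, `rss`, `converged`.
#' @export
#' @examples
#' t <- 1:36
#' y <- 20 + 10 * (1 - exp(-0.2 * (t - 1))) - 0.05 * (t - 1)
#' fit_learning_curve(y)
fit_learning_curve <- function(performance) {
  y <- as.numeric(performance)
  tt <- seq_along(y)
  ok <- is.finite(y)
  if (sum(ok) < 8L) stop("need at least 8 non-missing trials")
  y <- y[ok]; tt <- tt[ok]

  if (sd(y) == 0) {
    return(structure(list(p0 = y[1L], gain = 0, learning_rate = 0,
                          fatigue_rate = 0, rss = 0, converged = TRUE),
                     class = "learning_curve_fit"))
  }

  lower <- c(p0 = 0, gain = 0, r = 0, f = 0)
  upper <- c(p0 = 1e6, gain = 150, r = 5, f = 3)
  g0 <- min(max(max(y) - y[1L], 0.5), 150)
  p00 <- max(y[1L], 0)
  best <- NULL
  for (r0 in c(0.02, 0.08, 0.2, 0.6, 1.5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ p0 + gain * (1 - exp(-r * (tt - 1))) - f * (tt - 1),
        start = list(p0 = p00, gain = g0, r = r0, f = 0.01),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- coef(fit)
        best <- list(p0 = unname(cf["p0"]), gain = unname(cf["gain"]),
                     learning_rate = unname(cf["r"]),
                     fatigue_rate = unname(cf["f"]),
                     rss = rss, converged = TRUE)
      }
    }
  }
  if (is.null(best)) {
    # profile fallback: for fixed r the model is linear in (p0, gain, f)
    for (r0 in seq(0.01, 5, length.out = 40)) {
      sat <- 1 - exp(-r0 * (tt - 1))
      lin <- -(tt - 1)  # enters negated, so its coefficient is +f
      cf <- coef(lm(y ~ sat + lin))
      p0_hat <- max(unname(cf[1]), 0)
      g_hat <- min(max(unname(cf[2]), 0), 150)
      f_hat <- min(max(unname(cf[3]), 0), 3)
      pred <- p0_hat + g_hat * sat - f_hat * (tt - 1)
      rss <- sum((y - pred)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(p0 = p0_hat, gain = g_hat,
                     learning_rate = r0, fatigue_rate = f_hat,
                     rss = rss, converged = FALSE)
      }
    }
  }
  structure(best, class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<learning_curve_fit> p0=%.3f gain=%.3f rate=%.4f fatigue=%.4f rss=%.4g%s\n",
    x$p0, x$gain, x$learning_rate, x$fatigue_rate, x$rss,
    if (x$converged) "" else " (fallback)"))
  invisible(x)
}

#' LOWESS profile features of a performance vector
#'
#' A robust LOWESS smooth (tricube weights, span 0.3, one robustifying
#' iteration) of performance against trial index, summarised as: the
#' smoothed value at the first and last trial, the maximum smoothed value
#' and its trial index, and the mean finite-difference slope over the
#' first and last thirds of the session.
#'
#' @param performance Numeric per-trial performance (at least 8
#'   non-missing trials).
#' @param span LOWESS span (fraction of points per local fit).
#' @return Named numeric vector
#'   `lowess_first`, `lowess_last`, `lowess_max`, `lowess_argmax`,
#'   `lowess_slope_early`, `lowess_slope_late`.
#' @export
lowess_features <- function(performance, span = 0.3) {
  y <- as.numeric(performance)
  tt <- seq_along(y)
  ok <- is.finite(y)
  if (sum(ok) < 8L) stop("need at least 8 non-missing trials")
  lw <- lowess(tt[ok], y[ok], f = span, iter = 1)
  sm <- lw$y
  n <- length(sm)
  third <- max(2L, floor(n / 3))
  c(lowess_first = sm[1L],
    lowess_last = sm[n],
    lowess_max = max(sm),
    lowess_argmax = lw$x[which.max(sm)],
    lowess_slope_early = mean(diff(sm[seq_len(third)])),
    lowess_slope_late = mean(diff(sm[(n - third + 1L):n])))
}

#' Tapping-consistency features of one session
#'
#' For every completed sequence the coefficient of variation (sample
#' sd / mean) of its inter-press intervals measures within-sequence
#' timing consistency; the per-trial value is the median over that
#' trial's sequences. Features: the mean and the OLS slope (over trial
#' index) of that per-trial series, and the pattern-consistency trend,
#' i.e. the OLS slope over trials of correct/total keypresses.
#'
#' @param events data.table of the session's events (`trial`, `key`,
#'   `time`).
#' @param trial_scores data.table with per-trial `correct` and `total`
#'   for the same session.
#' @param task A [task_spec()].
#' @return Named numeric vector `wsc_mean`, `wsc_slope`,
#'   `pattern_consistency_trend` (NA where undefined).
#' @export
consistency_features <- function(events, trial_scores, task = task_spec()) {
  ev <- data.table::as.data.table(events)
  cv_by_trial <- ev[, {
    m <- match_pattern_cpp(as.integer(key), task$pattern)
    if (m$complete == 0L) {
      list(wsc = NA_real_)
    } else {
      cvs <- vapply(seq_len(m$complete), function(j) {
        iv <- diff(time[m$seq_start[j]:m$seq_end[j]])
        mu <- mean(iv)
        if (mu > 0) sd(iv) / mu else 0
      }, numeric(1))
      list(wsc = median(cvs))
    }
  }, by = trial]
  ts <- data.table::as.data.table(trial_scores)
  ratio <- ifelse(ts$total > 0, ts$correct / ts$total, NA_real_)
  c(wsc_mean = mean(cv_by_trial$wsc, na.rm = TRUE),
    wsc_slope = ols_slope(cv_by_trial$trial, cv_by_trial$wsc),
    pattern_consistency_trend = ols_slope(ts$trial, ratio))
}

#' Summary statistics of one scored session
#'
#' @param trial_scores data.table with per-trial `correct`, `total`,
#'   `responded` for one session (in trial order).
#' @return Named numeric vector: mean/sd/median/min/max of per-trial
#'   performance (sample sd), maximal performance (mean of 3 best),
#'   first- and last-trial performance, mean total keypresses, overall
#'   accuracy ratio, and the number of unanswered trials.
#' @export
session_statistics <- function(trial_scores) {
  ts <- data.table::as.data.table(trial_scores)
  p <- as.numeric(ts$correct)
  s <- summarize_session(p, ts$total)
  c(perf_mean = mean(p),
    perf_sd = sd(p),
    perf_median = median(p),
    perf_min = min(p),
    perf_max = max(p),
    max_performance = s$max_performance,
    perf_first = p[1L],
    perf_last = p[length(p)],
    mean_input_chars = mean(as.numeric(ts$total)),
    accuracy = if (sum(ts$total) > 0) sum(ts$correct) / sum(ts$total)
               else NA_real_,
    n_nonresponded = sum(!ts$responded))
}

#' Micro-online and micro-offline gains of the first trials
#'
#' Micro-online gain of trial k is its end-sequence speed minus its
#' start-sequence speed (within-trial change); micro-offline gain of gap
#' k is the start speed of trial k+1 minus the end speed of trial k
#' (change across the rest period). When all speeds are defined the
#' gains telescope: their sum equals end-speed(last) minus
#' start-speed(first). Missing speeds (trials with no completed
#' sequence) propagate as NA.
#'
#' @param start_speeds,end_speeds Numeric vectors of per-trial start and
#'   end sequence speeds (keys/s), trials in order (default: first 5
#'   trials of a session).
#' @return List of class `micro_gains`: `micro_online` (length k),
#'   `micro_offline` (length k-1).
#' @export
#' @examples
#' micro_gains(c(2, 3, 3, 4, 4), c(3, 3, 4, 4, 5))
micro_gains <- function(start_speeds, end_speeds) {
  stopifnot(length(start_speeds) == length(end_speeds),
            length(start_speeds) >= 1L)
  k <- length(start_speeds)
  structure(
    list(micro_online = end_speeds - start_speeds,
         micro_offline = if (k > 1L) start_speeds[-1L] - end_speeds[-k]
                         else numeric(0)),
    class = "micro_gains"
  )
}

# ---- feature table assembly ----------------------------------------------

#' Build the per-participant feature table for one session
#'
#' Computes every predictor tier from the scored data of `session` for
#' each participant that survives screening with that session present.
#' Tiers (introduced stepwise to the models):
#' step 0 demographics (age, gender indicator); step 1 learning-curve
#' parameters; step 2 tapping-consistency dynamics; step 3 LOWESS
#' profile features; step 4 session statistics; step 5 micro-online
#' (first 5 trials) and micro-offline (4 gaps) gains; step 6 raw
#' per-trial performance.
#'
#' @param x A (screened) [cohort()].
#' @param scores Optional [score_cohort()] result.
#' @param session Session whose behaviour is featurised (default 1).
#' @param n_micro_trials Number of leading trials for micro-gains.
#' @return List of class `skill_features`: `table` (data.table, one row
#'   per participant) and `registry` (named list mapping step `0..6` to
#'   its column names; the step-k design is the union of steps 0..k).
#' @export
build_features <- function(x, scores = NULL, session = 1L,
                           n_micro_trials = 5L) {
  stopifnot(inherits(x, "skill_cohort"))
  if (is.null(scores)) scores <- score_cohort(x)
  task <- x$task
  sess <- as.integer(session)
  tr <- scores$trials[session == sess]
  if (!nrow(tr)) stop("no trials in session ", sess)
  pps <- unique(tr$participant)
  speeds <- trial_speeds(scores)[session == sess]
  ev <- x$events[session == sess]
  n_trials <- task$trials_per_session[sess]

  rows <- lapply(pps, function(pp) {
    ts <- tr[participant == pp]
    p <- as.numeric(ts$correct)
    f1 <- tryCatch({
      fit <- fit_learning_curve(p)
      c(lc_p0 = fit$p0, lc_gain = fit$gain,
        lc_rate = fit$learning_rate, lc_fatigue = fit$fatigue_rate)
    }, error = function(e) c(lc_p0 = NA_real_, lc_gain = NA_real_,
                             lc_rate = NA_real_, lc_fatigue = NA_real_))
    f2 <- consistency_features(ev[participant == pp], ts, task)
    f3 <- tryCatch(lowess_features(p),
                   error = function(e)
                     setNames(rep(NA_real_, 6),
                              c("lowess_first", "lowess_last", "lowess_max",
                                "lowess_argmax", "lowess_slope_early",
                                "lowess_slope_late")))
    f4 <- session_statistics(ts)
    sp <- speeds[participant == pp][order(trial)][seq_len(n_micro_trials)]
    mg <- micro_gains(sp$start_speed, sp$end_speed)
    f5 <- c(setNames(mg$micro_online,
                     paste0("micro_online_", seq_along(mg$micro_online))),
            setNames(mg$micro_offline,
                     paste0("micro_offline_", seq_along(mg$micro_offline))))
    perf <- rep(NA_real_, n_trials)
    perf[ts$trial] <- p
    f6 <- setNames(perf, paste0("perf_trial_", seq_len(n_trials)))
    c(f1, f2, f3, f4, f5, f6)
  })
  feat <- data.table::as.data.table(do.call(rbind, rows))
  feat[, participant := pps]

  demo <- x$participants[, .(participant, age, gender)]
  demo[, `:=`(age = as.numeric(age),
              gender_female = as.numeric(gender == "female"))]
  demo[, gender := NULL]
  feat <- demo[feat, on = "participant"]
  data.table::setorder(feat, participant)

  registry <- list(
    `0` = c("age", "gender_female"),
    `1` = c("lc_p0", "lc_gain", "lc_rate", "lc_fatigue"),
    `2` = c("wsc_mean", "wsc_slope", "pattern_consistency_trend"),
    `3` = c("lowess_first", "lowess_last", "lowess_max", "lowess_argmax",
            "lowess_slope_early", "lowess_slope_late"),
    `4` = c("perf_mean", "perf_sd", "perf_median", "perf_min", "perf_max",
            "max_performance", "perf_first", "perf_last",
            "mean_input_chars", "accuracy", "n_nonresponded"),
    `5` = c(paste0("micro_online_", seq_len(n_micro_trials)),
            paste0("micro_offline_", seq_len(n_micro_trials - 1L))),
    `6` = paste0("perf_trial_", seq_len(n_trials))
  )
  structure(list(table = feat, registry = registry, session = sess),
            class = "skill_features")
}

#' @export
print.skill_features <- function(x, ...) {
  cat("<skill_features>", nrow(x$table), "participants,",
      ncol(x$table) - 1L, "features (session", paste0(x$session, ")\n"))
  invisible(x)
}

#' Assemble the step-k design matrix
#'
#' Selects the union of feature tiers 0..`upto_step` in registry order
#' and median-imputes missing values. Imputation medians are computed on
#' the training rows only (pass `train_ids`), so hold-out rows never
#' leak into preprocessing statistics.
#'
#' @param features A [build_features()] result.
#' @param upto_step Integer 0-6.
#' @param train_ids Participant ids whose rows define the imputation
#'   medians (default: all rows).
#' @param ids Participant ids to include as rows (default: all, in
#'   table order).
#' @return List: `X` (numeric matrix, rownames = participant ids),
#'   `medians`, `columns`.
#' @export
assemble_design <- function(features, upto_step, train_ids = NULL,
                            ids = NULL) {
  stopifnot(inherits(features, "skill_features"))
  steps <- as.character(0:6)
  if (!as.character(upto_step) %in% steps) {
    stop("unknown step index: ", upto_step)
  }
  cols <- unlist(features$registry[steps[seq_len(upto_step + 1L)]],
                 use.names = FALSE)
  tab <- features$table
  if (is.null(ids)) ids <- tab$participant
  if (is.null(train_ids)) train_ids <- ids
  X <- as.matrix(tab[match(ids, participant), cols, with = FALSE])
  rownames(X) <- ids
  Xtr <- as.matrix(tab[match(train_ids, participant), cols, with = FALSE])
  med <- apply(Xtr, 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_along(cols)) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- med[j]
  }
  list(X = X, medians = med, columns = cols)
}

utils::globalVariables(c("wsc", "age", "gender", "gender_female"))
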