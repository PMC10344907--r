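#' Default latent-parameter distributions for the synthetic generator
#'
#' Each latent participant parameter is drawn independently from a named
#' distribution spec (`family` plus parameters, with truncation bounds
#' `min`/`max` applied by clipping). The defaults target the scale of
#' performance seen in online sequence-tapping cohorts: first-trial
#' speeds around 2 correct keys/s (about 20 correct keypresses per 10-s
#' trial), within-session saturating gains of about 1 key/s, and strong
#' multi-month decay of the consolidated gains. Because the session
#' intercept model carries *all* between-session learning through the
#' consolidation increment, its mean (0.6 keys/s per transition) is set
#' high enough to exceed the extremal penalty of the short 9-trial
#' retention session (best-3-of-9 trials carry about 5 keypresses less
#' selection bias than best-3-of-36): this reproduces the sign structure
#' of real cohorts — positive offline and one-week retention gains,
#' total learning around +13 keypresses, and a clear multi-month
#' decline.
#'
#' @return Named list of distribution specs.
#' @export
default_latent_distributions <- function() {
  list(
    baseline_speed     = list(family = "normal", mean = 2.0, sd = 0.5,
                              min = 0.5, max = 6),
    gain_total         = list(family = "normal", mean = 1.0, sd = 0.3,
                              min = 0, max = 5),
    learning_rate      = list(family = "normal", mean = 0.5, sd = 0.07,
                              min = 0.05, max = 1.5),
    fatigue_rate       = list(family = "normal", mean = 0.005, sd = 0.004,
                              min = 0, max = 0.05),
    consolidation_gain = list(family = "normal", mean = 0.6, sd = 0.045,
                              min = 0, max = 1),
    decay_fraction     = list(family = "beta", shape1 = 8, shape2 = 2,
                              min = 0, max = 1),
    error_rate         = list(family = "beta", shape1 = 20, shape2 = 1980,
                              min = 0, max = 0.5),
    noise_sd           = list(family = "lognormal", meanlog = log(0.15),
                              sdlog = 0.3, min = 0, max = 1)
  )
}

#' Configure a synthetic keystroke cohort
#'
#' The generator produces keystroke-level cohorts with known ground
#' truth. Two regimes switch the study-level question the cohort encodes:
#' in `null_learning` every latent is drawn independently, so
#' between-session learning carries no signal recoverable from session-1
#' behaviour; in `predictable_learning` the asymptotic within-session
#' gain and the consolidation gain are monotone functions of
#' `baseline_speed` (and `learning_rate`) plus small noise, planting a
#' strong learnable signal.
#'
#' @param n_participants Number of participants enrolled in session 1.
#' @param regime `"null_learning"` or `"predictable_learning"`.
#' @param distributions Latent distribution specs, see
#'   [default_latent_distributions()].
#' @param dropout_per_session Probability of missing each subsequent
#'   session (attrition is monotone: a participant who misses session k
#'   has no later sessions).
#' @param sleep_violation_rate Fraction of participant-sessions reporting
#'   sleep outside the 6-12 h screening window.
#' @param missing_sleep_rate Fraction of sessions with no sleep report.
#' @param wrong_hand_rate Fraction of sessions failing the hand-report
#'   attention check.
#' @param latency_meanlog,latency_sdlog Log-normal parameters of the
#'   first-press latency (default median 0.5 s).
#' @param interval_sdlog Log-space spread of inter-press intervals
#'   (0 gives deterministic intervals of exactly 1/speed).
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 300L,
                             regime = c("null_learning",
                                        "predictable_learning"),
                             distributions = default_latent_distributions(),
                             dropout_per_session = 0.25,
                             sleep_violation_rate = 0.05,
                             missing_sleep_rate = 0,
                             wrong_hand_rate = 0,
                             latency_meanlog = log(0.5),
                             latency_sdlog = 0.35,
                             interval_sdlog = 0.1,
                             seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_participants >= 0,
            dropout_per_session >= 0, dropout_per_session < 1,
            sleep_violation_rate >= 0, sleep_violation_rate <= 1,
            missing_sleep_rate >= 0, missing_sleep_rate <= 1,
            wrong_hand_rate >= 0, wrong_hand_rate <= 1,
            interval_sdlog >= 0, latency_sdlog >= 0)
  need <- names(default_latent_distributions())
  miss <- setdiff(need, names(distributions))
  if (length(miss)) {
    stop("distributions is missing spec(s) for: ", paste(miss, collapse = ", "))
  }
  structure(
    list(n_participants = as.integer(n_participants), regime = regime,
         distributions = distributions,
         dropout_per_session = dropout_per_session,
         sleep_violation_rate = sleep_violation_rate,
         missing_sleep_rate = missing_sleep_rate,
         wrong_hand_rate = wrong_hand_rate,
         latency_meanlog = latency_meanlog, latency_sdlog = latency_sdlog,
         interval_sdlog = interval_sdlog, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

draw_latent <- function(n, spec, field) {
  fam <- spec$family
  x <- switch(fam,
    normal = rnorm(n, spec$mean, spec$sd),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    beta = rbeta(n, spec$shape1, spec$shape2),
    uniform = runif(n, spec$min, spec$max),
    constant = rep(spec$value, n),
    stop("unknown distribution family '", fam %||% "<missing>",
         "' for field '", field, "'")
  )
  pmin(pmax(x, spec$min %||% -Inf), spec$max %||% Inf)
}

#' Sample latent participant parameters
#'
#' In the `predictable_learning` regime `gain_total` is overwritten with
#' `0.2 + 0.3 * baseline_speed + 0.5 * learning_rate + N(0, 0.05)` and
#' `consolidation_gain` with
#' `0.05 + 0.7 * baseline_speed + N(0, 0.02)` (both clipped at their
#' bounds), making the session-1-to-2 performance change a monotone
#' function of session-1 latents. In `null_learning` every field is an
#' independent draw.
#'
#' @param config A [synthetic_config()].
#' @return data.table of latent parameters, one row per participant.
#' @export
sample_participants <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "latents"))
  n <- config$n_participants
  lat <- data.table::data.table(
    participant = sprintf("P%04d", seq_len(n))
  )
  for (f in names(default_latent_distributions())) {
    data.table::set(lat, j = f,
                    value = draw_latent(n, config$distributions[[f]], f))
  }
  if (config$regime == "predictable_learning" && n > 0) {
    g <- 0.2 + 0.3 * lat$baseline_speed + 0.5 * lat$learning_rate +
      rnorm(n, 0, 0.05)
    sp <- config$distributions$gain_total
    data.table::set(lat, j = "gain_total",
                    value = pmin(pmax(g, sp$min %||% 0), sp$max %||% Inf))
    cg <- 0.05 + 0.7 * lat$baseline_speed + rnorm(n, 0, 0.02)
    sp <- config$distributions$consolidation_gain
    data.table::set(lat, j = "consolidation_gain",
                    value = pmin(pmax(cg, sp$min %||% 0), 3))
  }
  lat[]
}

#' Expected tapping speed of a latent participant
#'
#' Within a session, speed follows a saturating-exponential learning
#' curve with a linear fatigue decrement:
#' `s(t) = s0 + G (1 - exp(-r (t - 1))) - f (t - 1)`. The session
#' intercept `s0` is the baseline speed plus the consolidation gains
#' accumulated over prior sessions (one increment per transition 1-2,
#' 2-3, 3-4); over the multi-month interval between sessions 4 and 5 the
#' accumulated learning (`s0` at session 4 minus baseline) is reduced by
#' the participant's decay fraction. Speeds are floored at 0.2 keys/s.
#'
#' @param latent One-row data.frame/list of latent parameters (or a
#'   data.table of several; vectorised over rows).
#' @param session Session index 1-5 (recycled).
#' @param trial Trial index within session (recycled).
#' @return Expected speed in correct keys/s.
#' @export
expected_speed <- function(latent, session, trial) {
  b <- latent$baseline_speed
  cg <- latent$consolidation_gain
  s0_4 <- b + 3 * cg
  s0 <- ifelse(session <= 4,
               b + (pmin(session, 4) - 1) * cg,
               b + (1 - latent$decay_fraction) * (s0_4 - b))
  sp <- s0 + latent$gain_total * (1 - exp(-latent$learning_rate * (trial - 1))) -
    latent$fatigue_rate * (trial - 1)
  pmax(sp, 0.2)
}

# Vectorised keystroke realisation shared by simulate_trial() and
# generate_cohort(). `trials` needs columns trial_uid (1..n, contiguous),
# eff_speed, error_rate; the RNG state of the caller is used as-is.
sim_events <- function(trials, task, config) {
  n <- nrow(trials)
  if (n == 0L) {
    return(data.table::data.table(trial_uid = integer(), key = integer(),
                                  time = numeric()))
  }
  dur <- task$trial_duration
  n_draw <- pmax(ceiling(1.35 * dur * trials$eff_speed) + 20L, 25L)
  uid <- rep.int(trials$trial_uid, n_draw)
  press <- sequence(n_draw)
  eff <- rep.int(trials$eff_speed, n_draw)
  err <- rep.int(trials$error_rate, n_draw)
  sdl <- config$interval_sdlog
  gap <- rlnorm(length(uid), meanlog = log(1 / eff) - sdl^2 / 2, sdlog = sdl)
  # first press: separately drawn attention latency, not an inter-press gap
  first <- press == 1L
  gap[first] <- rlnorm(sum(first), config$latency_meanlog,
                       config$latency_sdlog)
  ev <- data.table::data.table(trial_uid = uid, press = press, gap = gap)
  ev[, time := cumsum(gap), by = trial_uid]
  ev <- ev[time <= dur]
  L <- task$pattern_length
  ev[, key := task$pattern[((press - 1L) %% L) + 1L]]
  wrong <- runif(nrow(ev)) < rep_err_lookup(ev$trial_uid, trials)
  if (any(wrong)) {
    # replace with a uniformly-random different key from the alphabet
    kw <- ev$key[wrong]
    alphabet <- sort(unique(task$pattern))
    if (identical(alphabet, 1:4)) {
      pick <- ((kw - 1L + sample.int(3L, length(kw), TRUE)) %% 4L) + 1L
    } else {
      pick <- vapply(kw, function(k) {
        others <- alphabet[alphabet != k]
        others[sample.int(length(others), 1L)]
      }, integer(1))
    }
    ev$key[wrong] <- pick
  }
  ev[, `:=`(time = round(time, 3), press = NULL, gap = NULL)]
  ev[]
}

rep_err_lookup <- function(uid, trials) trials$error_rate[uid]

#' Simulate the keystroke stream of one trial
#'
#' Presses walk the task pattern cyclically; inter-press intervals are
#' log-normal with mean `1/effective_speed`, the first-press latency is
#' drawn separately (log-normal, default median 0.5 s), and each press is
#' replaced by a uniformly-random wrong key with probability
#' `error_rate`. Generation stops at the trial duration. Uses the current
#' RNG state.
#'
#' @param target_speed Target correct-keys/s for the trial (> 0 after
#'   flooring at 0.2).
#' @param error_rate Per-press probability of a wrong key.
#' @param task A [task_spec()].
#' @param config A [synthetic_config()] (only the latency/interval
#'   parameters are used).
#' @return data.table with columns `key`, `time`.
#' @export
simulate_trial <- function(target_speed, error_rate = 0,
                           task = task_spec(),
                           config = synthetic_config()) {
  eff <- max(0.2, target_speed)
  tr <- data.table::data.table(trial_uid = 1L, eff_speed = eff,
                               error_rate = error_rate)
  ev <- sim_events(tr, task, config)
  ev[, .(key, time)]
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws latent participants, applies monotone per-session dropout,
#' samples demographics and per-session sleep reports (a configurable
#' fraction outside the 6-12 h screening window), realises every
#' scheduled trial at keystroke level, and returns the cohort together
#' with the latent ground-truth table for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param task A [task_spec()].
#' @return List with elements `cohort` (a [cohort()]) and `truth`
#'   (data.table of latents plus `last_session`).
#' @export
generate_cohort <- function(config = synthetic_config(),
                            task = task_spec()) {
  stopifnot(inherits(config, "synthetic_config"))
  lat <- sample_participants(config)
  n <- nrow(lat)
  K <- task$n_sessions

  set.seed(derive_seed(config$seed, "schedule"))
  # monotone attrition: continue to session k+1 with prob 1 - dropout
  cont <- matrix(runif(n * (K - 1)) >= config$dropout_per_session,
                 nrow = n)
  last_session <- if (n) {
    1L + apply(cont, 1L, function(z) {
      w <- which(!z)
      if (length(w)) w[1L] - 1L else length(z)
    })
  } else integer(0)
  data.table::set(lat, j = "last_session", value = last_session)

  set.seed(derive_seed(config$seed, "metadata"))
  participants <- data.table::data.table(
    participant = lat$participant,
    age = pmin(pmax(round(rnorm(n, 44, 13)), 18), 78),
    gender = sample(c("female", "male"), n, TRUE, c(0.58, 0.42)),
    education = sample(c("high_school", "bachelors", "masters", "other"),
                       n, TRUE, c(0.26, 0.46, 0.17, 0.11)),
    music_hours = round(rexp(n, 0.857), 1),
    activity_hours = round(rexp(n, 0.693), 1)
  )
  sess <- data.table::data.table(
    participant = rep(lat$participant, last_session),
    session = unlist(lapply(last_session, seq_len), use.names = FALSE)
  )
  ns <- nrow(sess)
  viol <- runif(ns) < config$sleep_violation_rate
  low_side <- runif(ns) < 0.5
  sleep <- pmin(pmax(rnorm(ns, 7.5, 1), 6), 12)
  sleep[viol] <- ifelse(low_side[viol], runif(sum(viol), 3, 5.5),
                        runif(sum(viol), 12.5, 14))
  sleep[runif(ns) < config$missing_sleep_rate] <- NA_real_
  sess[, `:=`(
    sleep_duration = round(sleep, 1),
    sleep_quality = sample(1:5, ns, TRUE, c(0.05, 0.15, 0.3, 0.35, 0.15)),
    reported_hand = ifelse(runif(ns) < config$wrong_hand_rate,
                           "right", "left")
  )]

  set.seed(derive_seed(config$seed, "trials"))
  grid <- sess[, .(trial = seq_len(task$trials_per_session[session])),
               by = .(participant, session)]
  grid <- lat[grid, on = "participant"]
  grid[, target_speed := expected_speed(.SD, session, trial)]
  grid[, eff_speed := pmax(0.2, target_speed + rnorm(.N, 0, noise_sd))]
  grid[, trial_uid := .I]
  ev <- sim_events(grid[, .(trial_uid, eff_speed, error_rate)], task, config)
  ev <- grid[, .(trial_uid, participant, session, trial)][
    ev, on = "trial_uid"][, trial_uid := NULL]

  ch <- cohort(ev, participants, sess, task = task,
               provenance = list(generator = "skillcurve synthetic cohort",
                                 regime = config$regime,
                                 seed = config$seed))
  list(cohort = ch, truth = lat[])
}

utils::globalVariables(c("noise_sd", "error_rate"))
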