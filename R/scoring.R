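#' Score a single trial against the task pattern
#'
#' Performance is the number of correct keypresses in the trial: the
#' number of complete pattern repetitions times the pattern length, plus
#' every keypress of a trailing incomplete repetition. Matching is greedy
#' and left-to-right with reset-then-retest error recovery: a press that
#' breaks the pattern resets the match position and is immediately
#' re-tested as a potential pattern start, so an error never hides a
#' subsequent genuine sequence. Keys outside the task alphabet are
#' ordinary incorrect presses.
#'
#' @param keys Integer vector of pressed keys, in time order.
#' @param times Optional numeric vector of press times (seconds from
#'   trial onset), same length as `keys`.
#' @param task A [task_spec()].
#' @return A list of class `trial_score` with elements
#'   `correct_keypresses`, `complete_sequences`, `trailing_partial`,
#'   `total_keypresses`, `first_press_latency`, `responded`.
#' @export
#' @examples
#' score_trial(c(4, 1, 3, 2, 4, 4, 1, 3))
score_trial <- function(keys, times = NULL, task = task_spec()) {
  keys <- as.integer(keys)
  if (!is.null(times)) {
    stopifnot(length(times) == length(keys))
    if (is.unsorted(times)) stop("event times must be non-decreasing")
  }
  m <- match_pattern_cpp(keys, task$pattern)
  structure(
    list(
      correct_keypresses = m$complete * task$pattern_length + m$partial,
      complete_sequences = m$complete,
      trailing_partial = m$partial,
      total_keypresses = length(keys),
      first_press_latency = if (length(keys)) {
        if (is.null(times)) NA_real_ else times[1L]
      } else NA_real_,
      responded = length(keys) > 0L
    ),
    class = "trial_score"
  )
}

#' Score every scheduled trial of a cohort
#'
#' Returns one row per scheduled trial for every participant-session in
#' the cohort (trials with no recorded press appear with
#' `responded = FALSE` and zero keypresses), plus the per-sequence bounds
#' needed for tapping-speed profiles.
#'
#' @param x A [cohort()].
#' @return A list of class `skill_scores` with elements `trials` (one row
#'   per scheduled trial: `participant`, `session`, `trial`, `correct`,
#'   `complete`, `partial`, `total`, `first_press_latency`, `responded`)
#'   and `sequences` (one row per completed sequence: its trial and the
#'   event times of its first and last press).
#' @export
score_cohort <- function(x) {
  stopifnot(inherits(x, "skill_cohort"))
  task <- x$task
  ev <- x$events  # already sorted (participant, session, trial, time)

  # full scheduled trial grid for every participant-session on record
  grid <- x$sessions[, .(participant, session)]
  grid <- grid[session >= 1L & session <= task$n_sessions]
  grid <- grid[, .(trial = seq_len(task$trials_per_session[session])),
               by = .(participant, session)]
  data.table::setorder(grid, participant, session, trial)

  if (nrow(ev)) {
    idx <- ev[, .(start = .I[1L], end = .I[.N], latency = time[1L]),
              by = .(participant, session, trial)]
    grid <- idx[grid, on = c("participant", "session", "trial")]
    grid[is.na(start), `:=`(start = 1L, end = 0L)]
  } else {
    grid[, `:=`(start = 1L, end = 0L, latency = NA_real_)]
  }
  sc <- score_events_cpp(ev$key, grid$start, grid$end, task$pattern)
  trials <- grid[, .(participant, session, trial,
                     first_press_latency = latency)]
  trials[, `:=`(
    complete = sc$complete,
    partial = sc$partial,
    total = sc$total,
    correct = sc$complete * task$pattern_length + sc$partial,
    responded = sc$total > 0L
  )]
  data.table::setcolorder(trials, c("participant", "session", "trial",
                                    "correct", "complete", "partial",
                                    "total", "first_press_latency",
                                    "responded"))
  seqs <- if (length(sc$seq_trial)) {
    data.table::data.table(
      participant = trials$participant[sc$seq_trial],
      session = trials$session[sc$seq_trial],
      trial = trials$trial[sc$seq_trial],
      t_first = ev$time[sc$seq_start],
      t_last = ev$time[sc$seq_end],
      i_first = sc$seq_start,
      i_last = sc$seq_end
    )
  } else {
    data.table::data.table(participant = character(), session = integer(),
                           trial = integer(), t_first = numeric(),
                           t_last = numeric(), i_first = integer(),
                           i_last = integer())
  }
  structure(list(trials = trials, sequences = seqs, task = task),
            class = "skill_scores")
}

#' @export
print.skill_scores <- function(x, ...) {
  cat("<skill_scores>", nrow(x$trials), "trials,",
      nrow(x$sequences), "completed sequences\n")
  invisible(x)
}

#' Summarise one scored session
#'
#' The session score used for all between-session comparisons is the
#' maximal performance: the mean of the 3 best trials. With fewer than 3
#' trials the mean of all trials is used and the summary is flagged.
#'
#' @param performance Numeric vector of per-trial correct-keypress counts
#'   (in trial order).
#' @param total Optional per-trial total keypress counts (for
#'   `mean_input_chars`).
#' @return A list of class `session_summary`: `performance_vector`,
#'   `max_performance`, `mean_performance`, `mean_input_chars`,
#'   `n_trials`, `short_session`.
#' @export
#' @examples
#' summarize_session(c(5, 10, 15, 20, 25, 30))$max_performance  # 25
summarize_session <- function(performance, total = NULL) {
  performance <- as.numeric(performance)
  if (length(performance) == 0L) stop("session has zero trials")
  short <- length(performance) < 3L
  best <- if (short) performance else
    sort(performance, decreasing = TRUE)[1:3]
  structure(
    list(
      performance_vector = performance,
      max_performance = mean(best),
      mean_performance = mean(performance),
      mean_input_chars = if (is.null(total)) NA_real_ else
        mean(as.numeric(total)),
      n_trials = length(performance),
      short_session = short
    ),
    class = "session_summary"
  )
}

#' Per-session summaries for a whole scored cohort
#'
#' @param scores A [score_cohort()] result.
#' @return data.table with one row per participant-session:
#'   `max_performance` (mean of 3 best trials), `mean_performance`,
#'   `mean_input_chars`, `n_trials`, `short_session`.
#' @export
summarize_cohort <- function(scores) {
  stopifnot(inherits(scores, "skill_scores"))
  scores$trials[, {
    s <- summarize_session(correct, total)
    list(max_performance = s$max_performance,
         mean_performance = s$mean_performance,
         mean_input_chars = s$mean_input_chars,
         n_trials = s$n_trials,
         short_session = s$short_session)
  }, by = .(participant, session)]
}

#' Between-session gain table
#'
#' All gains are differences of per-session maximal performance (mean of
#' the 3 best trials): offline gains for consecutive session pairs, the
#' one-week retention gain (session 3 to 4), the long-term retention
#' change (session 4 to 5, typically negative), and the learning
#' intervals used as prediction targets. A participant lacking either
#' endpoint session has `NA` for that interval.
#'
#' @param summaries A [summarize_cohort()] table.
#' @return data.table keyed by `participant` with columns `mp1`..`mp5`
#'   (per-session max performance), `offline_s1_s2`, `offline_s2_s3`,
#'   `offline_s3_s4`, `learning_s1_s2`, `learning_s1_s3`,
#'   `total_learning_s1_s4`, `retention_s3_s4`, `long_retention_s4_s5`.
#' @export
compute_gains <- function(summaries) {
  dt <- data.table::as.data.table(summaries)
  wide <- data.table::dcast(dt, participant ~ session,
                            value.var = "max_performance")
  for (s in 1:5) {
    col <- as.character(s)
    if (!col %in% names(wide)) {
      data.table::set(wide, j = col, value = rep(NA_real_, nrow(wide)))
    }
    data.table::setnames(wide, col, paste0("mp", s))
  }
  wide[, `:=`(
    offline_s1_s2 = mp2 - mp1,
    offline_s2_s3 = mp3 - mp2,
    offline_s3_s4 = mp4 - mp3,
    learning_s1_s2 = mp2 - mp1,
    learning_s1_s3 = mp3 - mp1,
    total_learning_s1_s4 = mp4 - mp1,
    retention_s3_s4 = mp4 - mp3,
    long_retention_s4_s5 = mp5 - mp4
  )]
  data.table::setorder(wide, participant)
  wide[]
}

utils::globalVariables(c("start", "end", "t_first", "t_last",
                         "i_first", "i_last",
                         "mp1", "mp2", "mp3", "mp4", "mp5"))

#' Per-sequence tapping-speed profile of a trial
#'
#' For each completed sequence the speed is the pattern length divided by
#' the time between its first and last press. The start speed is the
#' speed of the first completed sequence and the end speed that of the
#' last; trials with no completed sequence have missing speeds. These
#' instantaneous speeds feed the micro-online/micro-offline gains of the
#' first trials of a session.
#'
#' @param keys Integer key vector of the trial.
#' @param times Numeric press times (seconds from trial onset).
#' @param task A [task_spec()].
#' @return List of class `speed_profile`: `speeds` (keys/s per completed
#'   sequence), `start_speed`, `end_speed`.
#' @export
speed_profile <- function(keys, times, task = task_spec()) {
  stopifnot(length(keys) == length(times))
  m <- match_pattern_cpp(as.integer(keys), task$pattern)
  if (m$complete == 0L) {
    sp <- numeric(0)
  } else {
    dur <- times[m$seq_end] - times[m$seq_start]
    sp <- ifelse(dur > 0, task$pattern_length / dur, NA_real_)
  }
  structure(
    list(speeds = sp,
         start_speed = if (length(sp)) sp[1L] else NA_real_,
         end_speed = if (length(sp)) sp[length(sp)] else NA_real_),
    class = "speed_profile"
  )
}

# Batch start/end sequence speeds per trial from score_cohort() output.
# Returns one row per scheduled trial with NA speeds where no sequence
# was completed.
trial_speeds <- function(scores) {
  L <- scores$task$pattern_length
  seqs <- scores$sequences
  base <- scores$trials[, .(participant, session, trial)]
  if (!nrow(seqs)) {
    base[, `:=`(start_speed = NA_real_, end_speed = NA_real_)]
    return(base[])
  }
  sp <- seqs[, .(
    start_speed = {
      d <- t_last[1L] - t_first[1L]
      if (d > 0) L / d else NA_real_
    },
    end_speed = {
      d <- t_last[.N] - t_first[.N]
      if (d > 0) L / d else NA_real_
    }
  ), by = .(participant, session, trial)]
  out <- sp[base, on = c("participant", "session", "trial")]
  data.table::setorder(out, participant, session, trial)
  out[]
}
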