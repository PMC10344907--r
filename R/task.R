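#' Define the sequence-tapping task schedule
#'
#' Describes the task every other function assumes: a fixed key pattern
#' typed cyclically for the whole trial, fixed-length trials separated by
#' breaks, and a per-session trial count. The defaults are the canonical
#' five-session design: pattern 4-1-3-2-4, 10-second trials, 36 trials per
#' session except the shorter retention session (session 4, 9 trials).
#'
#' @param pattern Integer vector of key labels typed cyclically.
#' @param trial_duration Trial length in seconds.
#' @param break_duration Break between trials in seconds.
#' @param trials_per_session Integer vector, number of trials in each
#'   session (its length fixes the number of sessions).
#' @return An object of class `skill_task`.
#' @export
#' @examples
#' task_spec()
task_spec <- function(pattern = c(4L, 1L, 3L, 2L, 4L),
                      trial_duration = 10,
                      break_duration = 10,
                      trials_per_session = c(36L, 36L, 36L, 9L, 36L)) {
  pattern <- as.integer(pattern)
  trials_per_session <- as.integer(trials_per_session)
  stopifnot(
    length(pattern) >= 1L, !anyNA(pattern),
    is.numeric(trial_duration), trial_duration > 0,
    is.numeric(break_duration), break_duration > 0,
    length(trials_per_session) >= 1L, all(trials_per_session > 0L)
  )
  structure(
    list(
      pattern = pattern,
      pattern_length = length(pattern),
      trial_duration = as.numeric(trial_duration),
      break_duration = as.numeric(break_duration),
      trials_per_session = trials_per_session,
      n_sessions = length(trials_per_session)
    ),
    class = "skill_task"
  )
}

#' @export
print.skill_task <- function(x, ...) {
  cat("<skill_task> pattern", paste(x$pattern, collapse = "-"),
      "|", x$trial_duration, "s trials |",
      paste(x$trials_per_session, collapse = "/"), "trials per session\n")
  invisible(x)
}
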