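#' Exclusion rules for multi-session cohorts
#'
#' The cascade mirrors the qualification and attention checks used in
#' unsupervised online multi-session studies:
#' \enumerate{
#'   \item qualification: a session averaging fewer than
#'     `min_mean_input_chars` input characters per trial (any key, right
#'     or wrong — the check is about engagement, not accuracy)
#'     disqualifies the participant from all subsequent sessions;
#'   \item attention: if, within any session, the number of slow-start
#'     trials (first press later than `slow_start_threshold` seconds)
#'     plus the number of unanswered trials exceeds `max_flagged_trials`,
#'     the participant's data are discarded from all sessions;
#'   \item sleep: a reported sleep duration outside `sleep_range`
#'     (inclusive bounds) removes that session and all following ones;
#'   \item hand report: a wrong reported hand removes that session (and,
#'     to keep per-participant sessions contiguous, everything after it).
#' }
#' Note the boundary semantics: "at least 9" and "6-12 h" are inclusive,
#' "more than 5" is strict (exactly 5 flagged trials is retained).
#'
#' @param min_mean_input_chars Qualification threshold (default 9).
#' @param slow_start_threshold Seconds (default 2).
#' @param max_flagged_trials Strict upper bound on flagged trials per
#'   session (default 5).
#' @param sleep_range Inclusive acceptable sleep interval in hours.
#' @param require_left_hand_report Apply the hand-report check?
#' @param missing_sleep `"violation"` (default) treats a missing sleep
#'   report as outside the range; `"ignore"` keeps the session.
#' @param attention_mode `"combined"` (default) pools slow starts and
#'   non-responses into one per-session counter; `"any_slow_start"` is
#'   the stricter alternative reading (a single slow start excludes).
#' @return List of class `screening_rules`.
#' @export
screening_rules <- function(min_mean_input_chars = 9,
                            slow_start_threshold = 2,
                            max_flagged_trials = 5,
                            sleep_range = c(6, 12),
                            require_left_hand_report = TRUE,
                            missing_sleep = c("violation", "ignore"),
                            attention_mode = c("combined",
                                               "any_slow_start")) {
  missing_sleep <- match.arg(missing_sleep)
  attention_mode <- match.arg(attention_mode)
  stopifnot(min_mean_input_chars > 0, slow_start_threshold > 0,
            max_flagged_trials >= 0, length(sleep_range) == 2L,
            sleep_range[1] < sleep_range[2])
  structure(
    list(min_mean_input_chars = min_mean_input_chars,
         slow_start_threshold = slow_start_threshold,
         max_flagged_trials = max_flagged_trials,
         sleep_range = as.numeric(sleep_range),
         require_left_hand_report = isTRUE(require_left_hand_report),
         missing_sleep = missing_sleep,
         attention_mode = attention_mode),
    class = "screening_rules"
  )
}

#' Apply the exclusion cascade to a scored cohort
#'
#' Rules are applied in the fixed order qualification, attention, sleep,
#' hand report; each rule operates on the sessions surviving the previous
#' ones. Every removal is recorded in a per-participant audit trail. The
#' result keeps per-participant sessions contiguous from session 1.
#'
#' @param x A [cohort()].
#' @param rules A [screening_rules()].
#' @param scores Optional pre-computed [score_cohort()] result (computed
#'   here if omitted).
#' @return List of class `screening_result`: `cohort` (cleaned),
#'   `report` (`survivors` per session, `rule_counts`, `audit` trail with
#'   one row per triggered rule).
#' @export
apply_screening <- function(x, rules = screening_rules(), scores = NULL) {
  stopifnot(inherits(x, "skill_cohort"), inherits(rules, "screening_rules"))
  if (is.null(scores)) scores <- score_cohort(x)
  tr <- scores$trials

  per_sess <- tr[, .(
    mean_input = mean(total),
    flagged = sum((!is.na(first_press_latency) &
                     first_press_latency > rules$slow_start_threshold) |
                    !responded),
    slow_starts = sum(!is.na(first_press_latency) &
                        first_press_latency > rules$slow_start_threshold)
  ), by = .(participant, session)]
  per_sess <- x$sessions[, .(participant, session, sleep_duration,
                             reported_hand)][
    per_sess, on = c("participant", "session")]
  data.table::setorder(per_sess, participant, session)
  per_sess[, keep := TRUE]
  audit <- list()
  note <- function(pp, rule, sess_trig, removed) {
    data.table::data.table(participant = pp, rule = rule,
                           session_triggered = sess_trig,
                           sessions_removed = removed)
  }

  # (1) qualification: < min chars in session k removes sessions > k
  q <- per_sess[keep == TRUE & mean_input < rules$min_mean_input_chars,
                .(k = session[1L]), by = participant]
  if (nrow(q)) {
    for (i in seq_len(nrow(q))) {
      pp <- q$participant[i]; k <- q$k[i]
      rm_s <- per_sess[participant == pp & session > k & keep == TRUE, session]
      if (length(rm_s)) {
        per_sess[participant == pp & session > k, keep := FALSE]
        audit[[length(audit) + 1L]] <-
          note(pp, "qualification", k, paste(rm_s, collapse = ","))
      }
    }
  }

  # (2) attention: flagged trials > threshold in any surviving session
  # removes the participant from all sessions
  att <- if (rules$attention_mode == "combined") {
    per_sess[keep == TRUE & flagged > rules$max_flagged_trials,
             .(k = session[1L]), by = participant]
  } else {
    per_sess[keep == TRUE & slow_starts > 0L,
             .(k = session[1L]), by = participant]
  }
  if (nrow(att)) {
    for (i in seq_len(nrow(att))) {
      pp <- att$participant[i]
      rm_s <- per_sess[participant == pp & keep == TRUE, session]
      per_sess[participant == pp, keep := FALSE]
      audit[[length(audit) + 1L]] <-
        note(pp, "attention", att$k[i], paste(rm_s, collapse = ","))
    }
  }

  # (3) sleep outside the range removes that session and all following
  sleep_bad <- per_sess[keep == TRUE &
                          ((is.na(sleep_duration) &
                              rules$missing_sleep == "violation") |
                             (!is.na(sleep_duration) &
                                (sleep_duration < rules$sleep_range[1] |
                                   sleep_duration > rules$sleep_range[2]))),
                        .(k = session[1L]), by = participant]
  if (nrow(sleep_bad)) {
    for (i in seq_len(nrow(sleep_bad))) {
      pp <- sleep_bad$participant[i]; k <- sleep_bad$k[i]
      rm_s <- per_sess[participant == pp & session >= k & keep == TRUE,
                       session]
      per_sess[participant == pp & session >= k, keep := FALSE]
      audit[[length(audit) + 1L]] <-
        note(pp, "sleep", k, paste(rm_s, collapse = ","))
    }
  }

  # (4) hand-report attention check; contiguity is preserved by removing
  # the offending session together with everything after it
  if (rules$require_left_hand_report) {
    hb <- per_sess[keep == TRUE & !is.na(reported_hand) &
                     reported_hand != "left",
                   .(k = session[1L]), by = participant]
    if (nrow(hb)) {
      for (i in seq_len(nrow(hb))) {
        pp <- hb$participant[i]; k <- hb$k[i]
        rm_s <- per_sess[participant == pp & session >= k & keep == TRUE,
                         session]
        per_sess[participant == pp & session >= k, keep := FALSE]
        audit[[length(audit) + 1L]] <-
          note(pp, "hand_report", k, paste(rm_s, collapse = ","))
      }
    }
  }

  keep_tab <- per_sess[keep == TRUE, .(participant, session)]
  clean <- cohort(
    x$events[keep_tab, on = c("participant", "session"), nomatch = NULL],
    x$participants[participant %in% unique(keep_tab$participant)],
    x$sessions[keep_tab, on = c("participant", "session"), nomatch = NULL],
    task = x$task,
    provenance = c(x$provenance, list(screened = TRUE))
  )
  audit <- if (length(audit)) data.table::rbindlist(audit) else
    data.table::data.table(participant = character(), rule = character(),
                           session_triggered = integer(),
                           sessions_removed = character())
  survivors <- keep_tab[, .N, by = session][order(session)]
  data.table::setnames(survivors, "N", "n_participants")
  rule_counts <- audit[, .N, by = rule]
  structure(
    list(cohort = clean,
         report = list(survivors = survivors,
                       rule_counts = rule_counts,
                       audit = audit)),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result>\n")
  print(x$report$survivors)
  if (nrow(x$report$rule_counts)) {
    cat("exclusion events by rule:\n")
    print(x$report$rule_counts)
  } else cat("no exclusions\n")
  invisible(x)
}

utils::globalVariables(c("mean_input", "slow_starts", "k", "N"))
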