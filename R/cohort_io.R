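#' Construct a keystroke cohort object
#'
#' A cohort bundles the raw behavioural event stream of a multi-session
#' tapping study with its schedule and metadata: one tidy keystroke table
#' (`participant`, `session`, `trial`, `key`, `time`), one per-participant
#' demographics table, and one per-(participant, session) self-report
#' table. Event times are seconds from trial onset, stored at millisecond
#' precision.
#'
#' @param events data.frame with columns `participant`, `session`,
#'   `trial`, `key`, `time`.
#' @param participants Optional data.frame with column `participant` and
#'   demographic fields (`age`, `gender`, `education`, `music_hours`,
#'   `activity_hours`). Missing fields are filled with `NA`.
#' @param sessions Optional data.frame with columns `participant`,
#'   `session` and self-report fields (`sleep_duration`, `sleep_quality`,
#'   `reported_hand`).
#' @param task A [task_spec()].
#' @param provenance Free-text/list provenance metadata.
#' @return An object of class `skill_cohort`.
#' @export
cohort <- function(events, participants = NULL, sessions = NULL,
                   task = task_spec(), provenance = list()) {
  stopifnot(inherits(task, "skill_task"))
  ev <- data.table::as.data.table(events)
  req <- c("participant", "session", "trial", "key", "time")
  miss <- setdiff(req, names(ev))
  if (length(miss)) {
    stop("events is missing column(s): ", paste(miss, collapse = ", "))
  }
  ev <- ev[, req, with = FALSE]
  ev[, `:=`(participant = as.character(participant),
            session = as.integer(session),
            trial = as.integer(trial),
            key = as.integer(key),
            time = round(as.numeric(time), 3))]
  data.table::setorder(ev, participant, session, trial, time)

  pp_ids <- sort(unique(ev$participant))
  pp <- if (is.null(participants)) {
    data.table::data.table(participant = pp_ids)
  } else {
    data.table::as.data.table(participants)
  }
  stopifnot("participant" %in% names(pp))
  pp[, participant := as.character(participant)]
  if (anyDuplicated(pp$participant)) stop("duplicate participant ids")
  for (f in c("age", "gender", "education", "music_hours", "activity_hours")) {
    if (!f %in% names(pp)) data.table::set(pp, j = f, value = rep(NA, nrow(pp)))
  }
  data.table::setorder(pp, participant)

  ss <- if (is.null(sessions)) {
    unique(ev[, .(participant, session)])
  } else {
    data.table::as.data.table(sessions)
  }
  stopifnot(all(c("participant", "session") %in% names(ss)))
  ss[, `:=`(participant = as.character(participant),
            session = as.integer(session))]
  for (f in c("sleep_duration", "sleep_quality", "reported_hand")) {
    if (!f %in% names(ss)) data.table::set(ss, j = f, value = rep(NA, nrow(ss)))
  }
  data.table::setorder(ss, participant, session)

  structure(
    list(events = ev, participants = pp, sessions = ss,
         task = task, provenance = provenance),
    class = "skill_cohort"
  )
}

#' @export
print.skill_cohort <- function(x, ...) {
  cat("<skill_cohort>", nrow(x$participants), "participants,",
      nrow(x$sessions), "participant-sessions,",
      nrow(x$events), "keypress events\n")
  invisible(x)
}

#' Read a cohort from its on-disk tabular format
#'
#' The native format is a directory holding `keystrokes.csv` (long table:
#' `participant,session,trial,key,time`) plus optional `participants.csv`
#' and `sessions.csv` metadata tables. Events are sorted stably by
#' (participant, session, trial, time), so ties in time keep file order.
#'
#' Keys outside the task alphabet are informative errors and are kept by
#' default (`bad_key = "keep"`); they count as incorrect presses when
#' scored. Rows whose time falls outside `[0, trial_duration]` are
#' rejected with a warning stating how many were dropped. A row that
#' cannot be parsed at all raises an error naming its line number.
#'
#' @param path Directory containing the CSV tables (or the path of the
#'   keystroke CSV itself).
#' @param task A [task_spec()].
#' @param bad_key `"keep"` (default) or `"drop"` for keys outside the
#'   task alphabet.
#' @return A [cohort()] object.
#' @export
read_cohort <- function(path, task = task_spec(),
                        bad_key = c("keep", "drop")) {
  bad_key <- match.arg(bad_key)
  kfile <- if (dir.exists(path)) file.path(path, "keystrokes.csv") else path
  if (!file.exists(kfile)) stop("no such file: ", kfile)
  ev <- data.table::fread(kfile, colClasses = list(character = "participant"),
                          showProgress = FALSE)
  req <- c("participant", "session", "trial", "key", "time")
  miss <- setdiff(req, names(ev))
  if (length(miss)) {
    stop("keystroke table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(ev)) {
    ev[, line := .I + 1L]  # header is line 1
    num <- function(x) suppressWarnings(as.numeric(x))
    bad <- which(!nzchar(as.character(ev$participant)) |
                   is.na(num(ev$session)) | is.na(num(ev$trial)) |
                   is.na(num(ev$time)))
    if (length(bad)) {
      stop("malformed keystroke row at line ", ev$line[bad[1]])
    }
    out_of_trial <- which(num(ev$time) < 0 | num(ev$time) > task$trial_duration)
    if (length(out_of_trial)) {
      warning(length(out_of_trial),
              " event(s) with time outside [0, ", task$trial_duration,
              "] rejected")
      ev <- ev[-out_of_trial]
    }
    if (bad_key == "drop") {
      ev <- ev[ev$key %in% task$pattern]
    }
    ev[, line := NULL]
  }
  base <- dirname(kfile)
  read_opt <- function(f) {
    p <- file.path(base, f)
    if (file.exists(p)) {
      data.table::fread(p, colClasses = list(character = "participant"),
                        showProgress = FALSE)
    } else NULL
  }
  cohort(ev, read_opt("participants.csv"), read_opt("sessions.csv"),
         task = task,
         provenance = list(source = normalizePath(base)))
}

#' Write a cohort to the on-disk tabular format
#'
#' Writes `keystrokes.csv`, `participants.csv` and `sessions.csv` into a
#' directory with deterministic column and row order (participant,
#' session, trial, time), so identical cohorts produce byte-identical
#' files.
#'
#' @param x A [cohort()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "skill_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  ev <- data.table::copy(x$events)
  data.table::setorder(ev, participant, session, trial, time)
  data.table::fwrite(ev, file.path(path, "keystrokes.csv"))
  data.table::fwrite(x$participants, file.path(path, "participants.csv"))
  data.table::fwrite(x$sessions, file.path(path, "sessions.csv"))
  invisible(path)
}

utils::globalVariables("line")
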