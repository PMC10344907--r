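#' Configure an end-to-end pipeline run
#'
#' Bundles the task schedule, generator scenario, screening rules,
#' search space and global seed for [run_pipeline()]. The constructor is
#' strict: unknown arguments are an error, so a typo in a config never
#' silently runs with defaults. Every stochastic stage derives its seed
#' from the global seed and the stage name via [derive_seed()].
#'
#' @param task A [task_spec()].
#' @param synthetic A [synthetic_config()] (the cohort source).
#' @param rules A [screening_rules()].
#' @param space A [search_space()].
#' @param intervals Prediction interval names.
#' @param feature_session Session featurised for prediction.
#' @param seed Global integer seed.
#' @param ... Unknown arguments (an error).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(task = task_spec(),
                            synthetic = synthetic_config(),
                            rules = screening_rules(),
                            space = search_space(),
                            intervals = c("s2-s1", "s3-s1", "s4-s1",
                                          "s4-s3", "s5-s4"),
                            feature_session = 1L,
                            seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  }
  stopifnot(inherits(task, "skill_task"),
            inherits(synthetic, "synthetic_config"),
            inherits(rules, "screening_rules"),
            inherits(space, "search_space"))
  structure(list(task = task, synthetic = synthetic, rules = rules,
                 space = space, intervals = intervals,
                 feature_session = as.integer(feature_session),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or import) -> score -> screen -> features ->
#' predict -> associate and writes every stage output plus a
#' machine-readable manifest (stage seeds and output checksums) to a run
#' directory. Reruns with an identical config produce identical
#' manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created).
#' @param cohort Optional pre-built [cohort()]; if `NULL` the synthetic
#'   generator is used (its seed is re-derived from the global seed).
#' @return List of class `pipeline_run` with the in-memory stage
#'   results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "init"
  res <- tryCatch({
    stage <- "simulate"
    if (is.null(cohort)) {
      syn <- config$synthetic
      syn$seed <- derive_seed(config$seed, "simulate")
      gen <- generate_cohort(syn, config$task)
      cohort <- gen$cohort
      data.table::fwrite(gen$truth, file.path(out_dir, "ground_truth.csv"))
    }
    write_cohort(cohort, file.path(out_dir, "cohort"))

    stage <- "score"
    scores <- score_cohort(cohort)
    data.table::fwrite(scores$trials, file.path(out_dir, "trial_scores.csv"))

    stage <- "screen"
    scr <- apply_screening(cohort, config$rules, scores)
    jsonlite::write_json(
      list(survivors = scr$report$survivors,
           rule_counts = scr$report$rule_counts,
           audit = scr$report$audit),
      file.path(out_dir, "screening.json"), dataframe = "rows")
    clean_scores <- score_cohort(scr$cohort)
    summaries <- summarize_cohort(clean_scores)
    data.table::fwrite(summaries, file.path(out_dir, "session_summaries.csv"))
    gains <- compute_gains(summaries)
    data.table::fwrite(gains, file.path(out_dir, "gains.csv"))

    stage <- "features"
    feats <- build_features(scr$cohort, clean_scores,
                            session = config$feature_session)
    data.table::fwrite(feats$table, file.path(out_dir, "features.csv"))

    stage <- "predict"
    report <- run_protocol(feats, gains, intervals = config$intervals,
                           space = config$space,
                           seed = derive_seed(config$seed, "predict"))
    jsonlite::write_json(
      list(summary = report$summary,
           steps = data.table::rbindlist(
             lapply(report$intervals, `[[`, "steps"))),
      file.path(out_dir, "prediction.json"), dataframe = "rows",
      digits = NA)

    stage <- "associate"
    rel <- reliability_matrices(gains)
    gain_tests <- offline_gain_tests(gains)
    decay <- tryCatch(decay_predictors(gains), error = function(e) NULL)
    bands <- tryCatch(quantile_bands(summaries), error = function(e) NULL)
    assoc <- list(
      offline_gains = lapply(gain_tests, unclass),
      reliability_performance_r2 = rel$performance,
      reliability_learning_r2 = rel$learning,
      decay = if (!is.null(decay)) lapply(unclass(decay), unclass),
      band_curves = if (!is.null(bands)) bands$curves
    )
    jsonlite::write_json(assoc, file.path(out_dir, "association.json"),
                         dataframe = "rows", digits = NA, force = TRUE)
    list(cohort = cohort, scores = scores, screening = scr,
         summaries = summaries, gains = gains, features = feats,
         prediction = report, association = assoc)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       predict = derive_seed(config$seed, "predict")),
    regime = config$synthetic$regime,
    n_participants = config$synthetic$n_participants,
    checksums = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(c(res, list(out_dir = out_dir, manifest = manifest)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> outputs in", x$out_dir, "\n")
  print(x$prediction$summary)
  invisible(x)
}
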