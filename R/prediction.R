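#' Prediction intervals over the session schedule
#'
#' Three learning intervals predict the change in maximal performance
#' from session 1 to sessions 2, 3 and 4, and two retention intervals
#' predict the change over the one-week (3 to 4) and multi-month (4 to
#' 5) gaps.
#'
#' @param name One of `"s2-s1"`, `"s3-s1"`, `"s4-s1"`, `"s4-s3"`,
#'   `"s5-s4"`.
#' @return List of class `interval_spec` with `name`, `from`, `to`,
#'   `kind` (`"learning"` or `"retention"`).
#' @export
interval_spec <- function(name = c("s2-s1", "s3-s1", "s4-s1",
                                   "s4-s3", "s5-s4")) {
  name <- match.arg(name)
  ft <- switch(name,
               "s2-s1" = c(1L, 2L), "s3-s1" = c(1L, 3L),
               "s4-s1" = c(1L, 4L), "s4-s3" = c(3L, 4L),
               "s5-s4" = c(4L, 5L))
  structure(list(name = name, from = ft[1L], to = ft[2L],
                 kind = if (ft[1L] == 1L && ft[2L] <= 4L) "learning"
                        else "retention"),
            class = "interval_spec")
}

#' Per-participant prediction targets for an interval
#'
#' The target is the change in maximal performance over the interval,
#' restricted to participants with both endpoint sessions.
#'
#' @param gains A [compute_gains()] table.
#' @param interval An [interval_spec()] or its name.
#' @return Named numeric vector (names = participant ids).
#' @export
make_targets <- function(gains, interval) {
  if (is.character(interval)) interval <- interval_spec(interval)
  g <- data.table::as.data.table(gains)
  y <- g[[paste0("mp", interval$to)]] - g[[paste0("mp", interval$from)]]
  names(y) <- g$participant
  y <- y[is.finite(y)]
  if (!length(y)) stop("no participant has both endpoint sessions for ",
                       interval$name)
  y
}

#' Seed-deterministic hold-out split
#'
#' Simple random split into training and hold-out ids; disjoint,
#' exhaustive, identical for identical seeds.
#'
#' @param ids Character/integer vector of row ids (at least 10).
#' @param fraction Hold-out fraction (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `holdout`.
#' @export
split_holdout <- function(ids, fraction = 0.2, seed = 1L) {
  n <- length(ids)
  if (n < 10L) stop("need at least 10 rows to split, got ", n)
  n_hold <- max(1L, round(n * fraction))
  set.seed(seed)
  hold <- sort(sample.int(n, n_hold))
  list(train = ids[-hold], holdout = ids[hold])
}

#' Z-score columns using training statistics only
#'
#' Each column is centred and scaled by the training rows' mean and
#' sample standard deviation; the same transform is applied to the
#' `apply` rows. Columns constant on the training rows map to 0 and are
#' flagged.
#'
#' @param train Numeric matrix of training rows.
#' @param apply Optional matrix to transform with the training
#'   statistics.
#' @return List: `train`, `apply`, `center`, `scale`, `constant_cols`.
#' @export
zscore_transform <- function(train, apply = NULL) {
  ctr <- colMeans(train)
  scl <- apply2_sd(train)
  const <- scl == 0 | !is.finite(scl)
  scl[const] <- 1
  tz <- sweep(sweep(train, 2L, ctr), 2L, scl, "/")
  tz[, const] <- 0
  az <- NULL
  if (!is.null(apply)) {
    az <- sweep(sweep(apply, 2L, ctr), 2L, scl, "/")
    az[, const] <- 0
  }
  list(train = tz, apply = az, center = ctr, scale = scl,
       constant_cols = colnames(train)[const] %||% which(const))
}

apply2_sd <- function(m) apply(m, 2L, sd)

#' Hyperparameter search space for the boosted-tree models
#'
#' Exhaustive grid over gradient-boosted decision-tree ensemble
#' hyperparameters, deliberately including strong regularisation (high
#' `reg_lambda`, shallow trees, subsampling) because the feature count
#' is large relative to the participant count. The PCA variant
#' additionally reduces the z-scored training design to the components
#' explaining 95% of training variance.
#'
#' @param max_depth,learning_rate,nrounds,subsample,reg_lambda Grid
#'   values.
#' @param pca Logical vector of variants to try (`FALSE`, `TRUE`).
#' @param pca_variance Training-variance fraction retained by PCA.
#' @param cv_folds Number of cross-validation folds.
#' @param holdout_fraction Hold-out fraction.
#' @return List of class `search_space` (the `grid` element holds the
#'   expanded configuration table).
#' @export
search_space <- function(max_depth = c(2L, 3L, 4L),
                         learning_rate = c(0.01, 0.05, 0.1),
                         nrounds = c(100L, 300L, 600L),
                         subsample = c(0.6, 1.0),
                         reg_lambda = c(1, 10),
                         pca = c(FALSE, TRUE),
                         pca_variance = 0.95,
                         cv_folds = 5L,
                         holdout_fraction = 0.2) {
  grid <- expand.grid(max_depth = max_depth, learning_rate = learning_rate,
                      nrounds = nrounds, subsample = subsample,
                      reg_lambda = reg_lambda, KEEP.OUT.ATTRS = FALSE)
  stopifnot(nrow(grid) >= 1L, cv_folds >= 2L,
            holdout_fraction > 0, holdout_fraction < 1)
  structure(list(grid = grid, pca = unique(pca),
                 pca_variance = pca_variance,
                 cv_folds = as.integer(cv_folds),
                 holdout_fraction = holdout_fraction),
            class = "search_space")
}

xgb_fit <- function(X, y, par, nrounds) {
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = xgboost::xgb.params(
      max_depth = par$max_depth, learning_rate = par$learning_rate,
      subsample = par$subsample, reg_lambda = par$reg_lambda,
      nthread = 1, objective = "reg:squarederror"),
    data = dm, nrounds = nrounds, verbose = 0)
}

xgb_predict <- function(model, X) {
  predict(model, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Grid-search a boosted-tree model on one design matrix
#'
#' Exhaustive search over the hyperparameter grid (and PCA on/off
#' variants), scored by mean k-fold cross-validation MSE on the training
#' rows; fold membership is seed-deterministic. The winning
#' configuration is refit on the full training set.
#'
#' @param X Z-scored training design matrix.
#' @param y Training targets.
#' @param space A [search_space()].
#' @param seed Integer seed for fold assignment and subsampling.
#' @return List of class `step_fit`: `model`, `pca` (rotation or NULL),
#'   `best` (winning row of the CV table), `cv_table` (per-configuration
#'   mean CV MSE and R2).
#' @export
fit_step <- function(X, y, space, seed = 1L) {
  stopifnot(inherits(space, "search_space"), nrow(X) == length(y))
  if (any(!is.finite(y))) stop("non-finite prediction target")
  n <- nrow(X)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(space$cv_folds), n))

  variants <- list()
  for (use_pca in space$pca) {
    if (use_pca) {
      pc <- prcomp(X, center = FALSE, scale. = FALSE)
      v <- pc$sdev^2
      keep <- which(cumsum(v) / sum(v) >= space$pca_variance)[1L]
      keep <- max(keep, 1L)
      rot <- pc$rotation[, seq_len(keep), drop = FALSE]
      variants[[length(variants) + 1L]] <-
        list(pca = rot, X = X %*% rot, label = TRUE)
    } else {
      variants[[length(variants) + 1L]] <-
        list(pca = NULL, X = X, label = FALSE)
    }
  }

  cv_rows <- list()
  best <- NULL
  for (vr in variants) {
    Xv <- vr$X
    for (gi in seq_len(nrow(space$grid))) {
      par <- space$grid[gi, ]
      sse <- 0; sst <- 0
      for (fold in seq_len(space$cv_folds)) {
        te <- folds == fold
        set.seed(seed + 1000L * fold + gi)
        m <- xgb_fit(Xv[!te, , drop = FALSE], y[!te], par, par$nrounds)
        pr <- xgb_predict(m, Xv[te, , drop = FALSE])
        sse <- sse + sum((y[te] - pr)^2)
        sst <- sst + sum((y[te] - mean(y[te]))^2)
      }
      row <- data.table::data.table(
        pca = vr$label, max_depth = par$max_depth,
        learning_rate = par$learning_rate, nrounds = par$nrounds,
        subsample = par$subsample, reg_lambda = par$reg_lambda,
        cv_mse = sse / n, cv_r2 = 1 - sse / sst)
      cv_rows[[length(cv_rows) + 1L]] <- row
      if (is.null(best) || row$cv_mse < best$row$cv_mse) {
        best <- list(row = row, par = par, variant = vr)
      }
    }
  }
  set.seed(seed + 99991L)
  final <- xgb_fit(best$variant$X, y, best$par, best$par$nrounds)
  structure(
    list(model = final, pca = best$variant$pca, best = best$row,
         cv_table = data.table::rbindlist(cv_rows)),
    class = "step_fit"
  )
}

#' Explained variance on the hold-out rows
#'
#' `R2 = 1 - SS_res / SS_tot` with the total sum of squares centred on
#' the hold-out target mean. Negative values mean the model predicts
#' worse than the hold-out mean. The hold-out rows must never have been
#' seen during search; this function is the only consumer of them.
#'
#' @param fit A [fit_step()] result.
#' @param X_holdout Z-scored hold-out design (training statistics!).
#' @param y_holdout Hold-out targets.
#' @return Hold-out R2 (NA with a warning if the hold-out target is
#'   constant).
#' @export
evaluate_holdout <- function(fit, X_holdout, y_holdout) {
  stopifnot(inherits(fit, "step_fit"))
  sst <- sum((y_holdout - mean(y_holdout))^2)
  if (sst == 0) {
    warning("constant hold-out target: R2 undefined")
    return(NA_real_)
  }
  Xv <- if (is.null(fit$pca)) X_holdout else X_holdout %*% fit$pca
  pr <- xgb_predict(fit$model, Xv)
  1 - sum((y_holdout - pr)^2) / sst
}

#' Run the stepped feature-introduction prediction protocol
#'
#' For each interval: compute targets, draw one seed-deterministic 20%
#' hold-out split of the available participants, then for each feature
#' step 0..6 (design = union of tiers up to that step, median-imputed
#' and z-scored with training statistics only) grid-search the boosted
#' ensemble by mean 5-fold CV MSE. The step/variant with the highest
#' mean CV R2 is evaluated exactly once on the hold-out rows.
#'
#' @param features A [build_features()] result.
#' @param gains A [compute_gains()] table.
#' @param intervals Character vector of interval names.
#' @param space A [search_space()].
#' @param seed Global seed; per-interval seeds are derived from it.
#' @param steps Feature steps to scan (default 0:6).
#' @return List of class `prediction_report`: per interval, the per-step
#'   CV summary, selected step/variant with best hyperparameters,
#'   `cv_r2` of the selection and `holdout_r2`; plus a tidy `summary`
#'   table.
#' @export
run_protocol <- function(features, gains,
                         intervals = c("s2-s1", "s3-s1", "s4-s1",
                                       "s4-s3", "s5-s4"),
                         space = search_space(), seed = 1L,
                         steps = 0:6) {
  stopifnot(inherits(features, "skill_features"))
  out <- list()
  for (iv in intervals) {
    spec_iv <- interval_spec(iv)
    y_all <- make_targets(gains, spec_iv)
    ids <- intersect(features$table$participant, names(y_all))
    if (length(ids) < 10L) stop("fewer than 10 participants for ", iv)
    iv_seed <- derive_seed(seed, paste0("interval:", iv))
    sp <- split_holdout(ids, space$holdout_fraction, iv_seed)
    stopifnot(length(intersect(sp$train, sp$holdout)) == 0L)
    y_tr <- y_all[sp$train]
    y_ho <- y_all[sp$holdout]

    step_rows <- list()
    best_fit <- NULL
    for (st in steps) {
      dz <- assemble_design(features, st, train_ids = sp$train,
                            ids = c(sp$train, sp$holdout))
      Xtr <- dz$X[sp$train, , drop = FALSE]
      Xho <- dz$X[sp$holdout, , drop = FALSE]
      z <- zscore_transform(Xtr, Xho)
      fit <- fit_step(z$train, y_tr, space,
                      seed = derive_seed(iv_seed, paste0("step:", st)))
      step_rows[[length(step_rows) + 1L]] <- data.table::data.table(
        interval = iv, step = st, pca = fit$best$pca,
        cv_r2 = fit$best$cv_r2, cv_mse = fit$best$cv_mse,
        max_depth = fit$best$max_depth,
        learning_rate = fit$best$learning_rate,
        nrounds = fit$best$nrounds, subsample = fit$best$subsample,
        reg_lambda = fit$best$reg_lambda)
      if (is.null(best_fit) || fit$best$cv_r2 > best_fit$cv_r2) {
        best_fit <- list(fit = fit, step = st, cv_r2 = fit$best$cv_r2,
                         X_holdout = z$apply)
      }
    }
    holdout_r2 <- evaluate_holdout(best_fit$fit, best_fit$X_holdout, y_ho)
    out[[iv]] <- list(
      interval = iv, n_train = length(sp$train),
      n_holdout = length(sp$holdout),
      steps = data.table::rbindlist(step_rows),
      selected_step = best_fit$step,
      selected = best_fit$fit$best,
      cv_r2 = best_fit$cv_r2,
      holdout_r2 = holdout_r2,
      split = sp
    )
  }
  summary <- data.table::rbindlist(lapply(out, function(r)
    data.table::data.table(interval = r$interval, n_train = r$n_train,
                           n_holdout = r$n_holdout,
                           selected_step = r$selected_step,
                           cv_r2 = r$cv_r2, holdout_r2 = r$holdout_r2)))
  structure(list(intervals = out, summary = summary, seed = seed),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>\n")
  print(x$summary)
  invisible(x)
}
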