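#' One-sample t-test with effect size
#'
#' Two-sided one-sample t-test against `mu`, reporting Cohen's d for the
#' one-sample case (`mean / sd`) and the t-based 95% confidence interval
#' of the mean. Used for the offline-gain analyses.
#'
#' @param values Numeric vector (n >= 2, non-constant).
#' @param mu Null value (default 0).
#' @return List of class `stat_result`: `statistic`, `df`, `p`,
#'   `cohens_d`, `ci`, `mean`, `n`.
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3))
one_sample_t <- function(values, mu = 0) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite values")
  if (sd(x) == 0) stop("zero variance: t statistic undefined")
  tt <- t.test(x, mu = mu)
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, cohens_d = (mean(x) - mu) / sd(x),
         ci = as.vector(tt$conf.int), mean = mean(x), n = n),
    class = "stat_result"
  )
}

#' Pearson or Spearman correlation with confidence interval
#'
#' Pairwise-complete correlation with two-sided p-value. The 95%
#' confidence interval uses the Fisher z transform (for Spearman it is
#' the same large-sample approximation).
#'
#' @param x,y Numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return List of class `stat_result`: `estimate`, `df`, `p`, `ci`,
#'   `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairwise-complete observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  r <- unname(ct$estimate)
  ci <- if (method == "pearson" && !is.null(ct$conf.int)) {
    unname(ct$conf.int)
  } else {
    z <- atanh(r) + c(-1, 1) * 1.96 / sqrt(n - 3)
    tanh(z)
  }
  structure(
    list(estimate = r, df = n - 2L, p = ct$p.value, ci = ci, n = n,
         method = method),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  if (!is.null(x$statistic)) {
    cat(sprintf("t(%d) = %.3f, p = %.4g, d = %.3f, CI = [%.2f, %.2f]\n",
                x$df, x$statistic, x$p, x$cohens_d, x$ci[1], x$ci[2]))
  } else {
    cat(sprintf("%s r(%d) = %.3f, p = %.4g, CI = [%.2f, %.2f]\n",
                x$method, x$df, x$estimate, x$p, x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Test-retest reliability matrices
#'
#' Block A: squared Pearson correlations between per-session maximal
#' performance (sessions 1-4) — the test-retest reliability of the
#' performance measure. Block B: squared correlations between session
#' max performance and each learning interval (s2-s1, s3-s1, s4-s1) —
#' how much performance explains learning. Each cell uses the
#' pairwise-complete participant set.
#'
#' @param gains A [compute_gains()] table.
#' @return List of class `reliability_matrices`: `performance` (4x4 R2),
#'   `learning` (4x3 R2), with matching `_n` and `_p` matrices.
#' @export
reliability_matrices <- function(gains) {
  g <- data.table::as.data.table(gains)
  mp_cols <- paste0("mp", 1:4)
  lr_cols <- c("learning_s1_s2", "learning_s1_s3", "total_learning_s1_s4")
  cell <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      return(c(NA_real_, sum(ok), NA_real_))
    }
    ct <- cor.test(a[ok], b[ok])
    c(unname(ct$estimate)^2, sum(ok), ct$p.value)
  }
  mk <- function(cols_a, cols_b) {
    r2 <- matrix(NA_real_, length(cols_a), length(cols_b),
                 dimnames = list(cols_a, cols_b))
    nn <- r2; pp <- r2
    for (i in seq_along(cols_a)) for (j in seq_along(cols_b)) {
      v <- cell(g[[cols_a[i]]], g[[cols_b[j]]])
      r2[i, j] <- v[1]; nn[i, j] <- v[2]; pp[i, j] <- v[3]
    }
    list(r2 = r2, n = nn, p = pp)
  }
  A <- mk(mp_cols, mp_cols)
  B <- mk(mp_cols, lr_cols)
  structure(
    list(performance = A$r2, performance_n = A$n, performance_p = A$p,
         learning = B$r2, learning_n = B$n, learning_p = B$p),
    class = "reliability_matrices"
  )
}

#' Predictors of long-term retention decay
#'
#' Pearson correlations of the long-retention performance change
#' (session 5 minus session 4) with (a) maximal performance in the
#' retention session and (b) the total learning accumulated from session
#' 1 to the retention session. When decay is proportional to prior
#' learning, both are negative and (b) is the stronger predictor.
#'
#' @param gains A [compute_gains()] table.
#' @return List of class `decay_predictors` with `retention_max` and
#'   `total_learning`, each a [correlate()] result.
#' @export
decay_predictors <- function(gains) {
  g <- data.table::as.data.table(gains)
  ok <- is.finite(g$mp4) & is.finite(g$mp5) & is.finite(g$mp1)
  structure(
    list(
      retention_max = correlate(g$mp4[ok], g$long_retention_s4_s5[ok]),
      total_learning = correlate(g$total_learning_s1_s4[ok],
                                 g$long_retention_s4_s5[ok])
    ),
    class = "decay_predictors"
  )
}

#' Quantile rank-stability bands
#'
#' Participants present in the retention session are split into
#' `n_bands` quantile bands (each spanning an equal share of the
#' retention-session maximal-performance distribution; ties broken by
#' stable participant-id order, so band sizes differ by at most 1), and
#' each band's mean performance curve across all sessions is computed
#' with a t-based 95% confidence interval. Non-crossing band curves
#' indicate that participants' relative rank is stable over the
#' experiment.
#'
#' @param summaries A [summarize_cohort()] table.
#' @param retention_session Session defining the bands (default 4).
#' @param n_bands Number of bands (default 5).
#' @return List of class `quantile_bands`: `assignment` (participant,
#'   band), `curves` (band x session mean, ci_low, ci_high, n).
#' @export
quantile_bands <- function(summaries, retention_session = 4L,
                           n_bands = 5L) {
  dt <- data.table::as.data.table(summaries)
  ret <- dt[session == retention_session][order(max_performance, participant)]
  n <- nrow(ret)
  if (n < n_bands) stop("need at least ", n_bands,
                        " participants in the retention session")
  ret[, band := ceiling(seq_len(n) * n_bands / n)]
  assignment <- ret[, .(participant, band)]
  joined <- assignment[dt, on = "participant", nomatch = NULL]
  curves <- joined[, {
    m <- mean(max_performance)
    s <- sd(max_performance)
    half <- if (.N > 1L && is.finite(s)) qt(0.975, .N - 1L) * s / sqrt(.N)
            else NA_real_
    list(mean = m, ci_low = m - half, ci_high = m + half, n = .N)
  }, by = .(band, session)]
  data.table::setorder(curves, band, session)
  structure(list(assignment = assignment, curves = curves,
                 retention_session = retention_session,
                 n_bands = n_bands),
            class = "quantile_bands")
}

#' Offline-gain t-tests for consecutive session pairs
#'
#' One-sample t-tests of the between-session changes in maximal
#' performance: the three consecutive offline gains (1-2, 2-3, 3-4) and
#' the long-retention change (4-5).
#'
#' @param gains A [compute_gains()] table.
#' @return Named list of [one_sample_t()] results.
#' @export
offline_gain_tests <- function(gains) {
  g <- data.table::as.data.table(gains)
  list(
    s1_s2 = one_sample_t(g$offline_s1_s2),
    s2_s3 = one_sample_t(g$offline_s2_s3),
    s3_s4 = one_sample_t(g$offline_s3_s4),
    s4_s5 = one_sample_t(g$long_retention_s4_s5)
  )
}
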