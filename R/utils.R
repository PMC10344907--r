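#' Derive a stage-specific random seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed from the global
#' run seed plus the stage name, so adding or reordering stages never
#' perturbs the random streams of the others.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label, e.g. `"simulate"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 69069 + h) %% 2147483647)
}

# Ordinary least-squares slope of y on x, NA-tolerant; NA when fewer than
# two complete pairs or x has no spread.
ols_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  vx <- sum((x - mean(x))^2)
  if (vx == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / vx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
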