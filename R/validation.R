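#' Correlation of factor scores with an external word measure
#'
#' Convergent-evidence check: the Pearson correlation over words between a
#' factor's scores and an external per-word measure (mean behavioral rating,
#' corpus-derived similarity, log frequency, or letter count).
#'
#' @param factor_scores Named or ordered numeric vector of per-word factor
#'   scores.
#' @param external Numeric vector of the external measure, same word order.
#' @return The Pearson correlation.
#' @export
convergent_correlation <- function(factor_scores, external) {
  stopifnot(length(factor_scores) == length(external))
  if (stats::sd(external) == 0 || stats::sd(factor_scores) == 0) {
    stop("constant vector: correlation undefined")
  }
  stats::cor(factor_scores, external)
}

#' Stepwise word-length / word-frequency check
#'
#' Tests whether word frequency explains activation beyond word length:
#' step 1 regresses the per-word mean activation of a factor location on
#' word length; step 2 adds log word frequency. Returns the step-1 R
#' squared, the increment in R squared, and the incremental F test (1 and
#' n - 3 degrees of freedom).
#'
#' @param activation Per-word mean activation of the location's voxels.
#' @param word_length Per-word letter counts.
#' @param log_frequency Per-word log word frequencies.
#' @return List with `r2_step1`, `delta_r2`, `f_statistic`, `p_value`, `df`.
#' @export
stepwise_frequency_check <- function(activation, word_length,
                                     log_frequency) {
  n <- length(activation)
  stopifnot(length(word_length) == n, length(log_frequency) == n, n > 3)
  if (abs(stats::cor(word_length, log_frequency)) > 1 - 1e-10) {
    stop("word length and frequency are collinear")
  }
  fit1 <- stats::lm(activation ~ word_length)
  fit2 <- stats::lm(activation ~ word_length + log_frequency)
  tss <- sum((activation - mean(activation))^2)
  r2_1 <- 1 - sum(stats::residuals(fit1)^2) / tss
  r2_2 <- 1 - sum(stats::residuals(fit2)^2) / tss
  delta <- r2_2 - r2_1
  df2 <- n - 3
  f <- if (1 - r2_2 < 1e-12) {
    # exact fit: no residual variance; a zero increment carries no evidence
    if (delta < 1e-12) 0 else Inf
  } else {
    (delta / 1) / ((1 - r2_2) / df2)
  }
  list(r2_step1 = r2_1, delta_r2 = delta, f_statistic = f,
       p_value = stats::pf(f, 1, df2, lower.tail = FALSE),
       df = c(1L, df2))
}
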