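#' Prediction-error metrics
#'
#' The screen's prediction-quality metrics: per-sample absolute error
#' `AE = |y_obs - y_pred|`, its mean `MAE`, the standard deviation of
#' the absolute errors `SD_AE`, and the percent relative error
#' `RE = 100 * |y_obs - y_pred| / y_obs`.
#'
#' `sd_ae()` defaults to the sample standard deviation (n - 1
#' denominator); set `population = TRUE` for the n-denominator variant.
#' `relative_errors()` is undefined where `y_obs == 0`; those samples
#' are returned as `NA` with a warning.
#'
#' @param y_obs,y_pred observed and predicted values.
#' @param ae a vector of absolute errors.
#' @param population use the population (n) denominator for `sd_ae()`.
#' @return numeric vector (`absolute_errors`, `relative_errors`) or
#'   scalar (`mae`, `sd_ae`).
#' @name error_metrics
NULL

#' @rdname error_metrics
#' @export
absolute_errors <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred))
  abs(y_obs - y_pred)
}

#' @rdname error_metrics
#' @export
mae <- function(ae) mean(ae)

#' @rdname error_metrics
#' @export
sd_ae <- function(ae, population = FALSE) {
  n <- length(ae)
  if (n < 2L) return(NA_real_)
  if (population) sqrt(sum((ae - mean(ae))^2) / n) else sd(ae)
}

#' @rdname error_metrics
#' @export
relative_errors <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred))
  out <- 100 * abs(y_obs - y_pred) / y_obs
  zero <- y_obs == 0
  if (any(zero)) {
    warn(sprintf("relative error undefined for %d sample(s) with y_obs = 0",
                 sum(zero)), class = "ramanscreen_zero_obs_warning")
    out[zero] <- NA_real_
  }
  out
}

#' One-tailed paired t-test on absolute errors
#'
#' Classical paired Student's t-test of `H1: mean(a - b) > 0` (i.e. the
#' first group's errors are larger), df = n - 1. Used to decide whether
#' one model's absolute errors exceed another's on the same samples.
#'
#' @param ae_a,ae_b paired absolute-error vectors (same samples, same
#'   order).
#' @param alpha significance level (default 0.05).
#' @return a tibble with `t`, `df`, `p_value`, `reject` and the mean
#'   difference.
#' @export
paired_t_one_tailed <- function(ae_a, ae_b, alpha = 0.05) {
  stopifnot(length(ae_a) == length(ae_b))
  keep <- is.finite(ae_a) & is.finite(ae_b)
  a <- ae_a[keep]; b <- ae_b[keep]
  d <- a - b
  if (length(d) < 2L) {
    abort("need at least two pairs", class = "ramanscreen_parameter_error")
  }
  if (sd(d) == 0) {
    # degenerate: all differences identical; t undefined unless 0
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    return(tibble::tibble(t = t_stat, df = length(d) - 1L, p_value = p,
                          reject = p <= alpha, mean_diff = mean(d)))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, reject = ht$p.value <= alpha,
    mean_diff = unname(ht$estimate)
  )
}

#' Mean relative error with confidence interval
#'
#' t-interval (df = n - 1) for the mean of the per-sample relative
#' errors of one filter combination. With a single value the interval
#' is undefined and flagged `NA`.
#'
#' @param re vector of relative errors (%); `NA`s dropped.
#' @param level confidence level (default 0.95).
#' @return a tibble with `mean`, `lo`, `hi`, `n`.
#' @export
re_mean_ci <- function(re, level = 0.95) {
  re <- re[is.finite(re)]
  n <- length(re)
  if (n == 0L) return(tibble::tibble(mean = NA_real_, lo = NA_real_,
                                     hi = NA_real_, n = 0L))
  m <- mean(re)
  if (n == 1L) return(tibble::tibble(mean = m, lo = NA_real_, hi = NA_real_, n = 1L))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) * sd(re) / sqrt(n)
  tibble::tibble(mean = m, lo = m - half, hi = m + half, n = n)
}
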