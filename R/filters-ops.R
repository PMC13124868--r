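#' Filter operator parameters
#'
#' Defaults follow the screened filter library: Savitzky-Golay with a
#' second-order polynomial over 15 points, median moving window of 15
#' points, asymmetric least squares with smoothing factor 1e4 and
#' asymmetry 0.001, Daubechies order-4 wavelet in mean-detrend mode.
#' The EWMA smoothing constant and the derivative window have no
#' published value; the defaults (alpha = 0.3, window 15) give
#' smoothing strength comparable to the 15-point operators.
#'
#' @param sg_window,sg_polyorder Savitzky-Golay window (odd, >= 3) and
#'   polynomial order.
#' @param mw_window median moving-window size (odd).
#' @param asls_lambda,asls_p AsLS smoothing factor (> 0) and asymmetry
#'   (in (0, 1)).
#' @param asls_max_iter,asls_tol AsLS IRLS iteration cap and weight
#'   convergence tolerance.
#' @param wds_levels wavelet decomposition depth; `NULL` = maximum
#'   feasible depth.
#' @param ewma_alpha EWMA smoothing constant in (0, 1].
#' @param deriv_window window for the Savitzky-Golay derivative
#'   operators.
#' @param norm_range optional `c(lo, hi)` wavenumber sub-range for the
#'   peak-height / peak-area normalizations; `NULL` = full axis.
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(sg_window = 15L, sg_polyorder = 2L,
                          mw_window = 15L,
                          asls_lambda = 1e4, asls_p = 0.001,
                          asls_max_iter = 50L, asls_tol = 1e-6,
                          wds_levels = NULL,
                          ewma_alpha = 0.3,
                          deriv_window = 15L,
                          norm_range = NULL) {
  for (w in c(sg_window, mw_window, deriv_window)) {
    if (w < 3L || w %% 2L == 0L) {
      abort("windows must be odd and >= 3", class = "ramanscreen_parameter_error")
    }
  }
  if (asls_lambda <= 0) abort("asls_lambda must be > 0",
                              class = "ramanscreen_parameter_error")
  if (asls_p <= 0 || asls_p >= 1) abort("asls_p must be in (0, 1)",
                                        class = "ramanscreen_parameter_error")
  if (ewma_alpha <= 0 || ewma_alpha > 1) abort("ewma_alpha must be in (0, 1]",
                                               class = "ramanscreen_parameter_error")
  structure(
    list(sg_window = as.integer(sg_window), sg_polyorder = as.integer(sg_polyorder),
         mw_window = as.integer(mw_window),
         asls_lambda = asls_lambda, asls_p = asls_p,
         asls_max_iter = as.integer(asls_max_iter), asls_tol = asls_tol,
         wds_levels = wds_levels, ewma_alpha = ewma_alpha,
         deriv_window = as.integer(deriv_window), norm_range = norm_range),
    class = "filter_params"
  )
}

## ---- smoothing -------------------------------------------------------

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial fit evaluated at the window centre;
#' edges handled by polynomial fits on the edge frames, so polynomials
#' up to the fit order are reproduced exactly everywhere.
#'
#' @param y numeric intensity vector.
#' @param params a [filter_params()].
#' @return smoothed vector, same length.
#' @export
sg_smooth <- function(y, params = filter_params()) {
  if (length(y) < params$sg_window) {
    abort("spectrum shorter than the Savitzky-Golay window",
          class = "ramanscreen_parameter_error")
  }
  as.numeric(signal::sgolayfilt(y, p = params$sg_polyorder, n = params$sg_window))
}

#' Symmetric exponentially weighted moving average
#'
#' Averages a forward recursive pass `s_i = alpha*y_i + (1-alpha)*s_(i-1)`
#' with the same pass run over the reversed vector, cancelling the
#' directional lag of a one-sided EWMA.
#'
#' @inheritParams sg_smooth
#' @return smoothed vector, same length.
#' @export
ewma_smooth <- function(y, params = filter_params()) {
  a <- params$ewma_alpha
  if (a <= 0 || a > 1) abort("ewma_alpha must be in (0, 1]",
                             class = "ramanscreen_parameter_error")
  fwd <- as.numeric(stats::filter(a * y, 1 - a, method = "recursive",
                                  init = y[1L]))
  rev_y <- rev(y)
  bwd <- rev(as.numeric(stats::filter(a * rev_y, 1 - a, method = "recursive",
                                      init = rev_y[1L])))
  (fwd + bwd) / 2
}

# Daubechies order-4 scaling filter (8 taps, orthonormal, sums to sqrt(2)).
db4_filter <- function() {
  c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
    -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
    0.0328830116668852, -0.0105974017850690)
}

# One-level periodized DWT (length must be even).
dwt_step <- function(x, h, g) {
  n <- length(x)
  L <- length(h)
  idx <- outer(seq(1L, n, by = 2L), 0:(L - 1L), `+`)
  idx <- (idx - 1L) %% n + 1L
  xm <- matrix(x[idx], ncol = L)
  list(a = as.numeric(xm %*% h), d = as.numeric(xm %*% g))
}

idwt_step <- function(a, d, h, g) {
  n2 <- 2L * length(a)
  L <- length(h)
  out <- numeric(n2)
  # transpose of the analysis operator (orthonormal => inverse)
  pos <- seq(1L, n2, by = 2L)
  for (k in 0:(L - 1L)) {
    tgt <- (pos + k - 1L) %% n2 + 1L
    contrib <- a * h[k + 1L] + d * g[k + 1L]
    for (j in seq_along(tgt)) out[tgt[j]] <- out[tgt[j]] + contrib[j]
  }
  out
}

#' Wavelet denoising (Daubechies order 4, mean-detrend)
#'
#' Subtracts the spectrum mean, runs a periodized Daubechies-4 discrete
#' wavelet transform (the signal is reflected-padded to a power of two),
#' soft-thresholds all detail coefficients at the universal threshold
#' `sigma * sqrt(2 log n)` with `sigma` estimated from the median
#' absolute deviation of the finest-scale details, reconstructs, and
#' adds the mean back.
#'
#' @inheritParams sg_smooth
#' @return denoised vector, same length.
#' @export
wavelet_denoise <- function(y, params = filter_params()) {
  h <- db4_filter()
  g <- rev(h) * c(1, -1)[(seq_along(h) %% 2L) + 1L] # QMF: g_k = (-1)^k h_{L-1-k}
  n <- length(y)
  if (n < length(h)) abort("spectrum shorter than the wavelet filter",
                           class = "ramanscreen_parameter_error")
  mu <- mean(y)
  x <- y - mu
  n2 <- 2L^ceiling(log2(n))
  if (n2 > n) { # reflect-pad to a power of two
    pad <- rev(x)[seq_len(n2 - n)]
    x <- c(x, pad)
  }
  max_lev <- floor(log2(n2 / length(h))) + 1L
  lev <- min(params$wds_levels %||% max_lev, max_lev)
  a <- x
  details <- vector("list", lev)
  for (l in seq_len(lev)) {
    st <- dwt_step(a, h, g)
    a <- st$a
    details[[l]] <- st$d
  }
  sigma <- median(abs(details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n2))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  if (sigma > 0) details <- lapply(details, soft)
  for (l in rev(seq_len(lev))) a <- idwt_step(a, details[[l]], h, g)
  a[seq_len(n)] + mu
}

#' Median moving window
#'
#' Centred running median (default window 15); at the edges the window
#' shrinks to fit, so output length always equals input length. Removes
#' isolated spikes narrower than half the window completely.
#'
#' @inheritParams sg_smooth
#' @return filtered vector, same length.
#' @export
moving_median <- function(y, params = filter_params()) {
  k <- params$mw_window
  n <- length(y)
  if (n < k) abort("spectrum shorter than the median window",
                   class = "ramanscreen_parameter_error")
  out <- as.numeric(stats::runmed(y, k, endrule = "keep"))
  half <- (k - 1L) %/% 2L
  for (i in c(seq_len(half), seq(n - half + 1L, n))) { # shrinking edge windows
    out[i] <- median(y[max(1L, i - half):min(n, i + half)])
  }
  out
}

# Cache of (n, lambda) -> lambda * t(D) %*% D penalty matrices.
.asls_cache <- new.env(parent = emptyenv())

asls_penalty <- function(n, lambda) {
  key <- paste0(n, "_", format(lambda, digits = 17))
  if (!is.null(.asls_cache[[key]])) return(.asls_cache[[key]])
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  P <- lambda * Matrix::crossprod(D)
  .asls_cache[[key]] <- P
  P
}

#' Asymmetric least squares curve fit
#'
#' Estimates the smooth curve `z` minimizing
#' `sum(w_i (y_i - z_i)^2) + lambda * sum((diff(z, differences = 2))^2)`
#' with asymmetric weights `w_i = p` where `y_i > z_i` and `1 - p`
#' otherwise, iterated to weight convergence (Whittaker smoother with
#' iteratively reweighted asymmetry). With the default small `p` the
#' curve hugs the signal from below, tracking baseline rather than
#' peaks. Used directly as a smoothing operator and, via
#' [baseline_asls()], as a baseline correction.
#'
#' @inheritParams sg_smooth
#' @return the fitted smooth curve `z`, same length as `y`.
#' @export
asls_fit <- function(y, params = filter_params()) {
  n <- length(y)
  P <- asls_penalty(n, params$asls_lambda)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(params$asls_max_iter)) {
    A <- P + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, params$asls_p, 1 - params$asls_p)
    if (max(abs(w_new - w)) < params$asls_tol) {
      return(z)
    }
    w <- w_new
  }
  warn("AsLS did not reach weight convergence; returning last iterate",
       class = "ramanscreen_convergence_warning")
  z
}

## ---- baseline --------------------------------------------------------

#' Baseline corrections
#'
#' `baseline_row_center()` subtracts the spectrum mean;
#' `baseline_offset()` subtracts the minimum (lowest-point offset);
#' `baseline_linear()` subtracts the ordinary least-squares line of
#' intensity on wavenumber fitted over the whole axis;
#' `baseline_asls()` subtracts the [asls_fit()] curve.
#'
#' @param y numeric intensity vector.
#' @param axis wavenumber axis (for the linear fit).
#' @param params a [filter_params()] (for AsLS).
#' @return corrected vector, same length.
#' @name baselines
NULL

#' @rdname baselines
#' @export
baseline_row_center <- function(y) y - mean(y)

#' @rdname baselines
#' @export
baseline_offset <- function(y) y - min(y)

#' @rdname baselines
#' @export
baseline_linear <- function(y, axis) {
  x <- axis - mean(axis)
  b <- sum(x * y) / sum(x * x)
  y - (mean(y) + b * x)
}

#' @rdname baselines
#' @export
baseline_asls <- function(y, params = filter_params()) {
  y - asls_fit(y, params)
}

## ---- normalization ---------------------------------------------------

#' Spectrum normalizations
#'
#' `snv()` is the standard normal variate: per-spectrum centring and
#' scaling to unit (sample) standard deviation. `norm_peak_height()`
#' divides by the maximum intensity; `norm_peak_area()` divides by the
#' trapezoid-rule area of `|y|`. An optional `norm_range` in
#' [filter_params()] restricts where the maximum/area is taken (the
#' whole spectrum is still rescaled).
#'
#' @param y numeric intensity vector.
#' @param axis wavenumber axis (for the area integral).
#' @param params a [filter_params()].
#' @return normalized vector, same length.
#' @name normalizations
NULL

#' @rdname normalizations
#' @export
snv <- function(y) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) {
    abort("SNV undefined for a constant spectrum",
          class = "ramanscreen_degenerate_error")
  }
  (y - mean(y)) / s
}

norm_window <- function(y, axis, params) {
  if (is.null(params$norm_range)) return(seq_along(y))
  which(axis >= params$norm_range[1L] & axis <= params$norm_range[2L])
}

#' @rdname normalizations
#' @export
norm_peak_height <- function(y, axis = seq_along(y), params = filter_params()) {
  m <- max(y[norm_window(y, axis, params)])
  if (m <= 0) abort("peak-height normalization needs a positive maximum",
                    class = "ramanscreen_degenerate_error")
  y / m
}

#' @rdname normalizations
#' @export
norm_peak_area <- function(y, axis = seq_along(y), params = filter_params()) {
  w <- norm_window(y, axis, params)
  yy <- abs(y[w])
  xx <- axis[w]
  area <- sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
  if (area == 0) abort("peak-area normalization needs nonzero area",
                       class = "ramanscreen_degenerate_error")
  y / area
}

## ---- other -----------------------------------------------------------

#' Multiplicative scatter correction
#'
#' `msc_fit()` estimates the reference spectrum as the mean of the
#' calibration spectra. `msc_apply()` regresses each spectrum on the
#' reference (`y ~ a + b * ref`, ordinary least squares) and returns
#' `(y - a) / b`, removing additive offset and multiplicative gain. The
#' reference is estimated on calibration samples only and reused
#' unchanged for validation/test spectra. If the fitted gain is not
#' positive the spectrum is returned uncorrected with a warning.
#'
#' @param calibration matrix of calibration spectra (rows = samples).
#' @param y a spectrum; `ref` a fitted reference from [msc_fit()].
#' @param ref reference spectrum.
#' @return `msc_fit()`: numeric reference spectrum; `msc_apply()`: the
#'   corrected spectrum.
#' @export
msc_fit <- function(calibration) {
  colMeans(as.matrix(calibration))
}

#' @rdname msc_fit
#' @export
msc_apply <- function(y, ref) {
  if (length(y) != length(ref)) {
    abort("MSC reference length must equal the axis length",
          class = "ramanscreen_format_error")
  }
  rc <- ref - mean(ref)
  b <- sum(rc * y) / sum(rc * rc)
  a <- mean(y) - b * mean(ref)
  if (!is.finite(b) || b <= 0) {
    warn("MSC gain not positive; returning spectrum uncorrected",
         class = "ramanscreen_illconditioned_warning")
    return(y)
  }
  (y - a) / b
}

#' Savitzky-Golay derivatives
#'
#' `deriv_first_quadratic()` is the first derivative from a local
#' quadratic fit; `deriv_second_cubic()` the second derivative from a
#' local cubic fit. Both use `deriv_window` points (default 15) and are
#' scaled by the axis step, so units are intensity per cm^-1 (or per
#' cm^-2).
#'
#' @param y numeric intensity vector.
#' @param axis wavenumber axis (for the step size).
#' @param params a [filter_params()].
#' @return derivative vector, same length.
#' @export
deriv_first_quadratic <- function(y, axis = seq_along(y), params = filter_params()) {
  step <- axis[2L] - axis[1L]
  as.numeric(signal::sgolayfilt(y, p = 2, n = params$deriv_window, m = 1, ts = step))
}

#' @rdname deriv_first_quadratic
#' @export
deriv_second_cubic <- function(y, axis = seq_along(y), params = filter_params()) {
  step <- axis[2L] - axis[1L]
  as.numeric(signal::sgolayfilt(y, p = 3, n = params$deriv_window, m = 2, ts = step))
}
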