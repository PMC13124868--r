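params <- filter_params()

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  x <- seq_len(100)
  expect_equal(sg_smooth(rep(3.7, 100), params), rep(3.7, 100))
  quad <- 0.02 * x^2 - 1.5 * x + 4
  expect_equal(sg_smooth(quad, params), quad, tolerance = 1e-8)
  # unit impulse at the centre of a window returns the centre
  # convolution coefficient from the local-quadratic normal equations
  y <- numeric(31); y[16] <- 1
  coef <- sg_coef_oracle(15, 2)
  expect_equal(sg_smooth(y, params)[16], coef[8], tolerance = 1e-10)
  expect_error(sg_smooth(rep(1, 10), params),
               class = "ramanscreen_parameter_error")
})

test_that("symmetric EWMA is lag-free and respects its limits", {
  y <- sin(seq(0, 6, length.out = 80))
  expect_equal(ewma_smooth(y, filter_params(ewma_alpha = 1)), y)
  expect_equal(ewma_smooth(rep(2, 50), params), rep(2, 50))
  # linear ramp: forward and backward lags cancel in the interior
  ramp <- seq(0, 10, length.out = 50)
  alpha <- params$ewma_alpha
  fwd <- numeric(50); fwd[1] <- ramp[1]
  for (i in 2:50) fwd[i] <- alpha * ramp[i] + (1 - alpha) * fwd[i - 1]
  bwd <- numeric(50); bwd[50] <- ramp[50]
  for (i in 49:1) bwd[i] <- alpha * ramp[i] + (1 - alpha) * bwd[i + 1]
  oracle <- (fwd + bwd) / 2
  got <- ewma_smooth(ramp, params)
  expect_equal(got, oracle, tolerance = 1e-12)
  # interior tracks the ramp up to a small edge-decay remnant
  expect_lt(max(abs(got[10:40] - ramp[10:40])), 0.02)
  expect_error(ewma_smooth(y, filter_params(ewma_alpha = 1.2)),
               class = "ramanscreen_parameter_error")
})

test_that("wavelet denoising is exact on flat input and reduces noise", {
  expect_equal(wavelet_denoise(numeric(300), params), numeric(300))
  expect_equal(wavelet_denoise(rep(4.2, 300), params), rep(4.2, 300),
               tolerance = 1e-10)
  # Monte-Carlo: RMSE against the truth improves for a noisy sinusoid
  truth <- 5 * sin(seq(0, 8 * pi, length.out = 500))
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- truth + rnorm(500, 0, 1)
    den <- wavelet_denoise(noisy, params)
    sqrt(mean((den - truth)^2)) < sqrt(mean((noisy - truth)^2))
  }, logical(1))
  expect_true(all(wins))
})

test_that("moving median removes spikes and preserves structure", {
  expect_equal(moving_median(rep(1.5, 60), params), rep(1.5, 60))
  mono <- cumsum(runif(60))
  expect_false(is.unsorted(moving_median(mono, params)))
  spiky <- rep(1, 101); spiky[51] <- 100
  out <- moving_median(spiky, params)
  expect_equal(max(out), 1)
  expect_length(out, 101L)
})

test_that("AsLS hugs smooth signal and tracks baseline under peaks", {
  # a straight line has zero curvature penalty: z ~ y (the weight
  # iteration oscillates on the exact-tie input; the iterate is exact)
  line <- seq(2, 8, length.out = 200)
  expect_equal(suppressWarnings(asls_fit(line, params)), line,
               tolerance = 1e-6)
  # flat baseline 10 + three positive Gaussian peaks: z stays near 10
  # away from the peaks
  x <- seq_len(500)
  peaks <- 30 * exp(-0.5 * ((x - 100) / 8)^2) +
    45 * exp(-0.5 * ((x - 250) / 10)^2) +
    25 * exp(-0.5 * ((x - 400) / 7)^2)
  y <- 10 + peaks
  # the weight iteration may oscillate at the cap on this fixture; the
  # returned last iterate is asserted below either way
  z <- suppressWarnings(asls_fit(y, params))
  away <- abs(x - 100) > 40 & abs(x - 250) > 50 & abs(x - 400) > 35
  # at lambda = 1e4 the curve tracks the flat baseline with a small
  # cheap-undershoot wiggle between peaks; it must stay close to 10
  # and strictly below the peak tops
  expect_lt(max(abs(z[away] - 10) / 10), 0.075)
  expect_lt(mean(abs(z[away] - 10) / 10), 0.03)
  expect_lt(max(z), 12)
  # p = 0.5, lambda -> 0 reduces to the identity
  z0 <- asls_fit(y, filter_params(asls_lambda = 1e-8, asls_p = 0.5))
  expect_equal(z0, y, tolerance = 1e-4)
  # baseline variant subtracts the curve: peak heights within 5%
  corr <- suppressWarnings(baseline_asls(y, params))
  expect_lt(abs(max(corr[80:120]) - 30) / 30, 0.05)
  expect_lt(abs(max(corr[230:270]) - 45) / 45, 0.05)
  # near-idempotence: the second estimated baseline is small relative
  # to the peak heights
  twice <- suppressWarnings(baseline_asls(corr, params))
  expect_lt(max(abs(twice - corr)), 0.02 * 45)
})

test_that("simple baseline corrections have their defining properties", {
  y <- c(3, 1, 2)
  expect_equal(baseline_row_center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(mean(baseline_row_center(rnorm(50))), 0)
  expect_equal(baseline_offset(y), c(2, 0, 1))
  expect_equal(min(baseline_offset(rnorm(50))), 0)
  yy <- rnorm(30); yy <- yy - min(yy)
  expect_equal(baseline_offset(yy), yy)
  # linear: exact line -> zeros; residual orthogonal to [1, axis]
  ax <- seq(100, 199)
  expect_equal(baseline_linear(0.5 * ax - 3, ax), numeric(100),
               tolerance = 1e-10)
  set.seed(2)
  r <- baseline_linear(rnorm(100), ax)
  expect_equal(sum(r), 0, tolerance = 1e-9)
  expect_equal(sum(r * ax), 0, tolerance = 1e-6)
  # line + Gaussian peak: peak preserved up to the OLS tilt, which the
  # closed-form OLS of the peak on [1, ax] predicts exactly
  peak <- 20 * exp(-0.5 * ((ax - 150) / 5)^2)
  y2 <- 2 * ax + 7 + peak
  xc <- ax - mean(ax)
  tilt <- mean(peak) + sum(xc * peak) / sum(xc^2) * xc
  expect_equal(baseline_linear(y2, ax), peak - tilt, tolerance = 1e-9)
})

test_that("SNV standardizes and is affine-invariant", {
  set.seed(3)
  y <- rnorm(200, 5, 2)
  z <- snv(y)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(snv(3.2 * y + 17), z, tolerance = 1e-10)
  expect_error(snv(rep(1, 50)), class = "ramanscreen_degenerate_error")
})

test_that("peak normalizations scale as documented", {
  expect_equal(norm_peak_height(c(1, 4, 2)), c(0.25, 1, 0.5))
  set.seed(4)
  y <- abs(rnorm(100)) + 0.1
  expect_equal(max(norm_peak_height(y)), 1)
  expect_equal(norm_peak_height(2 * y), norm_peak_height(y))
  expect_error(norm_peak_height(c(-2, -1)),
               class = "ramanscreen_degenerate_error")
  # unit rectangle of width w -> height 1/w
  ax <- seq(0, 99)
  rect <- as.numeric(ax >= 10 & ax <= 30)
  out <- norm_peak_area(rect, ax)
  # trapezoid area of the discrete rectangle: 20 unit panels + 2 ramps
  expect_equal(max(out), 1 / 21, tolerance = 1e-12)
  area <- function(v) sum(diff(ax) * (head(abs(v), -1) + tail(abs(v), -1)) / 2)
  expect_equal(area(norm_peak_area(y, ax)), 1, tolerance = 1e-12)
  expect_equal(norm_peak_area(5 * y, ax), norm_peak_area(y, ax))
  expect_error(norm_peak_area(numeric(100), ax),
               class = "ramanscreen_degenerate_error")
})

test_that("MSC removes additive offset and multiplicative gain", {
  set.seed(5)
  ref <- abs(rnorm(120)) + seq(0, 2, length.out = 120)
  cal <- rbind(ref, ref)
  fitted_ref <- msc_fit(cal)
  expect_equal(fitted_ref, ref, ignore_attr = TRUE)
  expect_equal(msc_apply(ref, ref), ref)
  expect_equal(msc_apply(2 * ref + 3, ref), ref, tolerance = 1e-10)
  # random affine perturbations collapse back to the reference
  for (s in 1:5) {
    set.seed(s)
    a <- runif(1, -2, 2); b <- runif(1, 0.5, 3)
    expect_equal(msc_apply(a + b * ref, ref), ref, tolerance = 1e-9)
  }
  expect_warning(msc_apply(-ref, ref),
                 class = "ramanscreen_illconditioned_warning")
})

test_that("SG derivatives are exact for low-order polynomials", {
  ax <- seq(100, 399)
  a <- 0.003; b <- -0.4; cc <- 10
  quad <- a * ax^2 + b * ax + cc
  expect_equal(deriv_first_quadratic(quad, ax, params), 2 * a * ax + b,
               tolerance = 1e-8)
  cub <- 1e-5 * ax^3 - 0.01 * ax^2 + 2
  expect_equal(deriv_second_cubic(cub, ax, params), 6e-5 * ax - 0.02,
               tolerance = 1e-8)
  expect_equal(deriv_first_quadratic(rep(4, 300), ax, params), numeric(300),
               tolerance = 1e-12)
})

test_that("combinations compose in category order and preserve shape", {
  set.seed(6)
  ax <- seq(200, 598, by = 2)
  ds <- spectral_dataset(matrix(abs(rnorm(5 * 200, 10, 2)), 5), ax,
                         paste0("s", 1:5))
  # all-none is the identity
  raw <- apply_combination(ds, raw_combination())
  expect_equal(raw$intensities, ds$intensities)
  # (MW, offset) equals the manual composition
  combo <- "smoothing=MW,baseline=offset,norm=none,other=none"
  got <- apply_combination(ds, combo)
  manual <- t(apply(ds$intensities, 1, function(y) {
    baseline_offset(moving_median(y, params))
  }))
  expect_equal(unname(got$intensities), unname(manual))
  # every one of the 480 combinations preserves the matrix shape
  grid <- filter_combinations()
  ok <- vapply(seq_len(nrow(grid)), function(i) {
    out <- try(suppressWarnings(
      apply_combination(ds, grid[i, ], cal_ids = paste0("s", 1:4))),
      silent = TRUE)
    if (inherits(out, "try-error")) return(NA)
    identical(dim(out$intensities), dim(ds$intensities))
  }, logical(1))
  expect_true(all(ok, na.rm = TRUE))
  # degenerate preprocessing surfaces as a labelled error, not a crash
  const <- spectral_dataset(matrix(1, 2, 200), ax, c("a", "b"))
  expect_error(
    apply_combination(const, "smoothing=none,baseline=none,norm=snv,other=none"),
    regexp = "norm=snv")
})

test_that("the filter grid enumerates 6*5*4*4 = 480 unique members", {
  grid <- filter_combinations()
  expect_equal(nrow(grid), 480L)
  expect_equal(anyDuplicated(grid$label), 0L)
  lv <- filter_levels()
  expect_equal(prod(lengths(lv)), 480L)
  # label round trip
  back <- parse_combination(grid$label)
  expect_equal(back$smoothing, grid$smoothing)
  expect_equal(back$other, grid$other)
})
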