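test_that("calibration split is 80/20, seeded, and run-stratified", {
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:65),
    run_id = rep(paste0("run", 1:5), times = c(12, 12, 13, 13, 15))
  )
  sp <- split_calibration(samples, seed = 3)
  expect_length(sp$cal, 52L)
  expect_length(sp$val, 13L)
  expect_setequal(c(sp$cal, sp$val), samples$sample_id)
  expect_identical(sp, split_calibration(samples, seed = 3))
  runs_in_cal <- unique(samples$run_id[samples$sample_id %in% sp$cal])
  expect_setequal(runs_in_cal, paste0("run", 1:5))
})

test_that("PLS recovers a rank-1 signal with one latent variable", {
  set.seed(10)
  # rank-1 spectra: one concentration profile times one pure-component
  # spectrum; any single column is then proportional to the profile
  t0 <- rnorm(40)
  p0 <- abs(rnorm(60)) + 0.5
  X <- outer(t0, p0)
  y <- 3 * X[, 7]
  m <- fit_pls(X, y, max_lv = 5, seed = 1)
  expect_equal(m$n_lv, 1L)
  expect_gte(m$r2cum[1], 0.999)
})

test_that("PLS Q2 under a permutation null stays near zero", {
  set.seed(11)
  X <- matrix(rnorm(30 * 50), 30)
  q2 <- vapply(1:20, function(s) {
    set.seed(s)
    y <- sample(rnorm(30)) # independent of X by construction
    m <- fit_pls(X, y, max_lv = 3, seed = s)
    m$q2cum[m$n_lv]
  }, numeric(1))
  expect_lte(mean(q2), 0.05)
})

test_that("stored regression vector reproduces component-space predictions", {
  set.seed(12)
  X <- matrix(rnorm(35 * 80), 35)
  y <- as.numeric(X %*% rnorm(80) * 0.3 + rnorm(35) * 0.2)
  m <- fit_pls(X, y, max_lv = 4, seed = 2)
  f <- m$nipals
  # oracle: scores from sequential deflation, then T q per component
  Xc <- sweep(X, 2, f$x_center)
  pred_oracle <- rep(f$y_center, 35)
  for (k in seq_len(m$n_lv)) {
    tk <- Xc %*% f$W[, k]
    pred_oracle <- pred_oracle + f$q[k] * as.numeric(tk)
    Xc <- Xc - tk %*% t(f$P[, k])
  }
  expect_equal(predict(m, X), pred_oracle, tolerance = 1e-8)
  # predicting the calibration mean spectrum returns the mean response
  expect_equal(predict(m, matrix(f$x_center, 1)), mean(y), tolerance = 1e-8)
  # brute-force (X - xbar) b + ybar
  expect_equal(predict(m, X),
               as.numeric(sweep(X, 2, f$x_center) %*% m$coefficients) + f$y_center,
               tolerance = 1e-10)
  expect_identical(predict(m, X), predict(m, X))
})

test_that("PLS at full rank matches ordinary least squares", {
  set.seed(13)
  X <- matrix(rnorm(50 * 6), 50)
  y <- as.numeric(X %*% c(1, -2, 0.5, 3, -1, 2) + rnorm(50) * 0.1)
  m <- fit_pls(X, y, max_lv = 6, cv_groups = 5, q2_gain = -Inf, seed = 1)
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(predict(m, X), as.numeric(cbind(1, X) %*% ols$coefficients),
               tolerance = 1e-6)
})

test_that("kernel-space screening PLS is identical to NIPALS", {
  set.seed(14)
  X <- matrix(rnorm(40 * 300), 40)
  y <- as.numeric(X %*% rnorm(300) * 0.1 + rnorm(40) * 0.3)
  cal <- 1:32; val <- 33:40
  m <- fit_pls(X[cal, ], y[cal], max_lv = 6, seed = 9)
  kf <- ramanscreen:::pls1_kernel_cv(tcrossprod(X), cal, val, y[cal],
                                     6, 7, 0.01, 9)
  expect_identical(m$n_lv, kf$n_lv)
  expect_equal(m$q2cum, kf$q2cum, tolerance = 1e-10)
  expect_equal(predict(m, X[val, ]), kf$predict(val), tolerance = 1e-8)
})

test_that("PLS predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(15)
  X <- matrix(rnorm(30 * 80), 30, dimnames = list(NULL, paste0("V", 1:80)))
  y <- as.numeric(X %*% rnorm(80) * 0.2 + rnorm(30) * 0.1)
  m <- fit_pls(X, y, max_lv = 3, seed = 1)
  mo <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  Xnew <- matrix(rnorm(8 * 80), 8, dimnames = list(NULL, paste0("V", 1:80)))
  theirs <- predict(mo, Xnew)$predict[, 1, 3]
  B <- ramanscreen:::pls1_coefs(m$nipals)
  ours <- as.numeric(Xnew %*% B[, 3]) + m$y_center - sum(m$x_center * B[, 3])
  expect_equal(ours, theirs, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA basis retains variance as specified", {
  set.seed(16)
  # exactly rank-2 data
  U <- matrix(rnorm(30 * 2), 30); V <- matrix(rnorm(2 * 40), 2)
  X2 <- U %*% V
  b <- fit_pca_scores(X2, variance_target = 0.999)
  expect_equal(b$n_pc, 2L)
  X <- matrix(rnorm(25 * 50), 25)
  b2 <- fit_pca_scores(X, variance_target = 0.99, n_pc_max = 20)
  sc <- project_scores(b2, X)
  expect_equal(unname(colMeans(sc)), numeric(b2$n_pc), tolerance = 1e-10)
  # Eckart-Young: relative squared reconstruction error equals the
  # unexplained variance fraction
  Xc <- sweep(X, 2, b2$center)
  recon <- sc %*% t(b2$rotation)
  rel_err <- sum((Xc - recon)^2) / sum(Xc^2)
  expect_equal(rel_err, 1 - sum(b2$explained), tolerance = 1e-10)
})

test_that("the ANN search grid has exactly 25 (N+1) members", {
  for (N in c(1L, 3L, 7L)) {
    acts <- ramanscreen:::ann_activations()
    grid <- tidyr::expand_grid(n_hidden = seq_len(N + 1L),
                               hidden_activation = acts,
                               output_activation = acts)
    expect_equal(nrow(grid), 25L * (N + 1L))
  }
})

test_that("ANN search solves a linear-realizable target and is seeded", {
  set.seed(17)
  n <- 40
  scores <- matrix(rnorm(n * 3), n)
  y <- 2 * scores[, 1] + 1
  a <- ann_search(scores, y, seed = 5, max_epochs = 300)
  expect_equal(nrow(tidy(a)), 100L) # 25 * (3 + 1)
  expect_gte(a$correlations[["test"]], 0.99)
  b <- ann_search(scores, y, seed = 5, max_epochs = 300)
  expect_identical(glance(a), glance(b))
  expect_equal(predict(a, scores), predict(b, scores))
})

test_that("ANN predictions match a manual forward pass", {
  set.seed(18)
  scores <- matrix(rnorm(30 * 2), 30)
  y <- scores[, 1]^2 + rnorm(30, 0, 0.05)
  a <- ann_search(scores, y, seed = 3, max_epochs = 200)
  Z <- sweep(sweep(scores, 2, a$x_center), 2, a$x_scale, `/`)
  acts <- list(identity = function(x) x,
               logistic = function(x) 1 / (1 + exp(-x)),
               tanh = tanh,
               exponential = function(x) exp(pmin(pmax(x, -30), 30)),
               sine = sin)
  h <- acts[[a$hidden_activation]](
    sweep(Z %*% a$weights$W1, 2, a$weights$b1, `+`))
  out <- acts[[a$output_activation]](as.numeric(h %*% a$weights$W2 + a$weights$b2))
  expect_equal(predict(a, scores), out * a$y_scale + a$y_center,
               tolerance = 1e-12)
})
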