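#' Split samples into calibration and validation sets
#'
#' Random 80/20 split, stratified by run so that every run contributes
#' to calibration (and, where its size allows, to validation). Seeded
#' and reproducible.
#'
#' @param samples a tibble with `sample_id` and `run_id` columns (e.g.
#'   the `samples` element of a [spectral_dataset()]), or a
#'   `spectral_dataset`.
#' @param fraction calibration fraction (default 0.8).
#' @param seed integer seed.
#' @return a list with character vectors `cal` and `val`.
#' @export
split_calibration <- function(samples, fraction = 0.8, seed = 1L) {
  if (inherits(samples, "spectral_dataset")) samples <- samples$samples
  stopifnot(fraction > 0, fraction < 1)
  rid <- samples$run_id
  if (is.null(rid)) rid <- rep("all", nrow(samples))
  rid[is.na(rid)] <- "all"
  with_seed(derive_seed(seed, "split"), {
    by_run <- split(samples$sample_id, rid)
    val <- unlist(lapply(by_run, function(ids) {
      n_val <- round((1 - fraction) * length(ids))
      n_val <- min(n_val, length(ids) - 1L) # every run keeps >= 1 cal sample
      if (n_val <= 0L) return(character())
      sample(ids, n_val)
    }), use.names = FALSE)
  })
  list(cal = setdiff(samples$sample_id, val), val = val)
}

# PLS1 NIPALS on centred data. Returns per-component weights W, loadings
# P, y-loadings q, plus centres. For a single y, each component is
# closed-form (w = X'y), no inner iteration needed.
pls1_nipals <- function(X, y, a) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  n <- nrow(X); p <- ncol(X)
  a <- min(a, n - 1L, p)
  W <- matrix(0, p, a); P <- matrix(0, p, a); q <- numeric(a)
  Tm <- matrix(0, n, a)
  ss_y <- sum(yc^2)
  s0 <- sum(Xc^2)
  r2cum <- numeric(a)
  for (k in seq_len(a)) {
    w <- crossprod(Xc, yc)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-7 * sqrt(s0 * ss_y) + .Machine$double.xmin) { a <- k - 1L; break }
    w <- w / nw
    tk <- Xc %*% w
    tt <- sum(tk^2)
    if (tt <= 1e-14 * s0 + .Machine$double.xmin) { a <- k - 1L; break }
    p_k <- crossprod(Xc, tk)[, 1L] / tt
    q_k <- sum(tk * yc) / tt
    Xc <- Xc - tcrossprod(tk, p_k)
    yc <- yc - q_k * tk[, 1L]
    W[, k] <- w; P[, k] <- p_k; q[k] <- q_k; Tm[, k] <- tk
    r2cum[k] <- if (ss_y > 0) 1 - sum(yc^2) / ss_y else NA_real_
  }
  if (a == 0L) {
    return(list(n_comp = 0L, x_center = xm, y_center = ym,
                W = W[, 0, drop = FALSE], P = P[, 0, drop = FALSE],
                q = numeric(0), r2cum = numeric(0)))
  }
  list(n_comp = a, x_center = xm, y_center = ym,
       W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], scores = Tm[, seq_len(a), drop = FALSE],
       r2cum = r2cum[seq_len(a)])
}

# CV group labels: seeded shuffle then round-robin. Shared by the NIPALS
# and kernel paths so their Q2/LV selection is identical.
cv_group_assign <- function(n, k, seed) {
  with_seed(derive_seed(seed, "cv"), {
    ord <- sample.int(n)
    g <- integer(n)
    g[ord] <- rep_len(seq_len(k), n)
    g
  })
}

# Kernel-space PLS1 on a precomputed uncentered Gram matrix K0 = X X'.
# Algebraically identical to pls1_nipals (see tests) but every
# per-component operation is O(n^2), so a screen that reuses one K0 per
# preprocessed matrix across parameters and CV folds is orders of
# magnitude faster than refitting in wavenumber space. `tr` indexes the
# training rows of K0; predictions for arbitrary rows come from kernel
# slices, so the p-dimensional regression vector is never formed.
pls1_kernel <- function(K0, tr, y, amax) {
  nS <- length(tr)
  Ks <- K0[tr, tr, drop = FALSE]
  rm_ <- rowMeans(Ks)
  gm <- mean(Ks)
  Kc <- Ks - outer(rm_, rep(1, nS)) - outer(rep(1, nS), rm_) + gm
  ym <- mean(y)
  yd <- y - ym
  ss_y <- sum(yd^2)
  Kd <- Kc
  s0 <- sum(diag(Kc)) # total centred X variance; scale-relative rank cutoffs
  amax <- min(amax, nS - 1L)
  Tm <- matrix(0, nS, amax); Z <- matrix(0, nS, amax); V <- matrix(0, nS, amax)
  q <- numeric(amax); tts <- numeric(amax); r2cum <- numeric(amax)
  a <- 0L
  for (k in seq_len(amax)) {
    Ky <- Kd %*% yd
    c2 <- sum(yd * Ky)
    if (c2 <= 1e-14 * s0 * ss_y + .Machine$double.xmin) break
    tk <- as.numeric(Ky) / sqrt(c2)
    tt <- sum(tk^2)
    if (tt <= 1e-14 * s0 + .Machine$double.xmin) break
    qk <- sum(tk * yd) / tt
    # n-space images of w_k and p_k: apply the accumulated score
    # projections (I - t t'/tt) in order 1..k-1
    z <- yd; v <- tk
    for (j in seq_len(k - 1L)) {
      z <- z - Tm[, j] * (sum(Tm[, j] * z) / tts[j])
      v <- v - Tm[, j] * (sum(Tm[, j] * v) / tts[j])
    }
    Z[, k] <- z / sqrt(c2)
    V[, k] <- v / tt
    Tm[, k] <- tk; tts[k] <- tt; q[k] <- qk
    yd <- yd - qk * tk
    kt <- Kd %*% tk / tt
    ktt <- sum(tk * kt) / tt
    Kd <- Kd - tcrossprod(tk, kt) - tcrossprod(kt, tk) + ktt * tcrossprod(tk)
    r2cum[k] <- if (ss_y > 0) 1 - sum(yd^2) / ss_y else NA_real_
    a <- k
  }
  if (a == 0L) {
    return(list(n_comp = 0L, tr = tr, y_center = ym, rm = rm_, gm = gm))
  }
  Z <- Z[, seq_len(a), drop = FALSE]
  V <- V[, seq_len(a), drop = FALSE]
  PW <- crossprod(V, Kc %*% Z) # = P'W
  PW[lower.tri(PW)] <- 0
  # alpha_a: n-space coefficient vector using the first a components
  alpha <- matrix(0, nS, a)
  for (k in seq_len(a)) {
    alpha[, k] <- Z[, seq_len(k), drop = FALSE] %*%
      solve(PW[seq_len(k), seq_len(k), drop = FALSE], q[seq_len(k)])
  }
  list(n_comp = a, tr = tr, y_center = ym, rm = rm_, gm = gm,
       alpha = alpha, r2cum = r2cum[seq_len(a)])
}

# Predict rows `rows` of K0 with the first `a` components.
pls1_kernel_predict <- function(fit, K0, rows, a = fit$n_comp) {
  if (fit$n_comp == 0L) return(rep(fit$y_center, length(rows)))
  a <- min(a, fit$n_comp)
  Krs <- K0[rows, fit$tr, drop = FALSE]
  Krs <- Krs - rowMeans(Krs) -
    matrix(fit$rm, length(rows), length(fit$tr), byrow = TRUE) + fit$gm
  as.numeric(Krs %*% fit$alpha[, a]) + fit$y_center
}

# Full screen-side PLS fit from a Gram matrix: CV for Q2cum, sequential
# LV selection, validation predictions. Mirrors fit_pls exactly.
pls1_kernel_cv <- function(K0, cal, val, y_cal, max_lv, cv_groups, q2_gain,
                           seed) {
  if (var(y_cal) == 0) {
    abort("response has zero variance", class = "ramanscreen_degenerate_error")
  }
  n <- length(cal)
  if (n <= cv_groups) {
    abort("need more calibration samples than CV groups",
          class = "ramanscreen_parameter_error")
  }
  a_max <- min(max_lv, n - 1L)
  fit <- pls1_kernel(K0, cal, y_cal, a_max)
  a_fit <- fit$n_comp
  if (a_fit == 0L) {
    abort("no usable PLS component", class = "ramanscreen_degenerate_error")
  }
  grp <- cv_group_assign(n, cv_groups, seed)
  press <- matrix(0, cv_groups, a_fit)
  ss0 <- numeric(cv_groups)
  for (g in seq_len(cv_groups)) {
    tr <- cal[grp != g]
    ho <- cal[grp == g]
    f <- pls1_kernel(K0, tr, y_cal[grp != g], a_fit)
    for (k in seq_len(a_fit)) {
      pred <- pls1_kernel_predict(f, K0, ho, k)
      press[g, k] <- sum((y_cal[grp == g] - pred)^2)
    }
    ss0[g] <- sum((y_cal[grp == g] - f$y_center)^2)
  }
  q2cum <- 1 - colSums(press) / sum(ss0)
  gains <- diff(c(0, q2cum))
  n_lv <- 1L
  for (k in seq_len(a_fit)) {
    if (gains[k] > q2_gain) n_lv <- k else break
  }
  n_lv <- as.integer(max(1L, min(n_lv, a_fit)))
  list(n_lv = n_lv, q2cum = q2cum, r2cum = fit$r2cum,
       predict = function(rows) pls1_kernel_predict(fit, K0, rows, n_lv))
}

# Regression vectors for 1..a components: column k gives b using k comps.
pls1_coefs <- function(fit) {
  a <- fit$n_comp
  B <- matrix(0, length(fit$x_center), a)
  if (a == 0L) return(B)
  R <- fit$W %*% solve(triu_ptw(fit$P, fit$W)) # R = W (P'W)^-1
  for (k in seq_len(a)) {
    B[, k] <- R[, seq_len(k), drop = FALSE] %*% fit$q[seq_len(k)]
  }
  B
}

triu_ptw <- function(P, W) {
  M <- crossprod(P, W)
  M[lower.tri(M)] <- 0 # P'W is upper triangular in exact arithmetic
  M
}

#' Fit a PLS calibration model
#'
#' PLS1 (single response) fitted by NIPALS on column-centred spectra.
#' `Q2cum` is obtained from k-group cross-validation (default 7
#' groups), with groups assigned round-robin after a seeded shuffle.
#' The number of latent variables retained is chosen sequentially:
#' components are accepted while the cross-validated `Q2cum` gain
#' exceeds `q2_gain` (default 0.01), capped at `max_lv`; at least one
#' component is always kept.
#'
#' @param X calibration spectra matrix (rows = samples).
#' @param y numeric response (one biochemical parameter).
#' @param max_lv cap on latent variables.
#' @param cv_groups number of cross-validation groups (default 7).
#' @param q2_gain minimum Q2cum improvement to accept a component.
#' @param seed integer seed (CV group shuffle).
#' @return an object of class `pls_model` with elements `n_lv`,
#'   `coefficients` (regression vector on the original spectral scale),
#'   `intercept`, `r2cum`, `q2cum`, and the NIPALS decomposition.
#' @export
fit_pls <- function(X, y, max_lv = 10L, cv_groups = 7L, q2_gain = 0.01,
                    seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (var(y) == 0) {
    abort("response has zero variance", class = "ramanscreen_degenerate_error")
  }
  if (n <= cv_groups) {
    abort("need more calibration samples than CV groups",
          class = "ramanscreen_parameter_error")
  }
  a_max <- min(max_lv, n - 1L, ncol(X))
  fit <- pls1_nipals(X, y, a_max)
  a_fit <- fit$n_comp
  # 7-group CV: seeded shuffle then round-robin assignment
  grp <- cv_group_assign(n, cv_groups, seed)
  press <- matrix(0, cv_groups, a_fit)
  ss0 <- numeric(cv_groups)
  for (g in seq_len(cv_groups)) {
    tr <- grp != g
    f <- pls1_nipals(X[tr, , drop = FALSE], y[tr], a_fit)
    B <- pls1_coefs(f)
    ko <- min(a_fit, f$n_comp)
    Xh <- sweep(X[!tr, , drop = FALSE], 2L, f$x_center)
    for (k in seq_len(a_fit)) {
      kk <- min(k, ko)
      pred <- if (kk >= 1L) Xh %*% B[, kk] + f$y_center else rep(f$y_center, nrow(Xh))
      press[g, k] <- sum((y[!tr] - pred)^2)
    }
    ss0[g] <- sum((y[!tr] - f$y_center)^2)
  }
  q2cum <- 1 - colSums(press) / sum(ss0)
  gains <- diff(c(0, q2cum))
  n_lv <- 1L
  for (k in seq_len(a_fit)) {
    if (gains[k] > q2_gain) n_lv <- k else break
  }
  n_lv <- as.integer(max(1L, min(n_lv, a_fit)))
  B <- pls1_coefs(fit)
  b <- B[, n_lv]
  structure(
    list(n_lv = n_lv, coefficients = b,
         intercept = fit$y_center - sum(fit$x_center * b),
         x_center = fit$x_center, y_center = fit$y_center,
         r2cum = fit$r2cum, q2cum = q2cum, max_lv = a_fit,
         nipals = fit, cv_groups = cv_groups, seed = seed),
    class = "pls_model"
  )
}

#' Predict from a PLS model
#'
#' Applies the stored centring and regression vector:
#' `yhat = (x - x_center) . b + y_center`.
#'
#' @param object a `pls_model`.
#' @param newdata spectra matrix or [spectral_dataset()].
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectral_dataset")) newdata <- newdata$intensities
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' @exportS3Method base::print
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables (of %d fitted)\n",
              x$n_lv, x$max_lv))
  cat(sprintf("  R2cum = %.4f  Q2cum = %.4f at selected LV\n",
              x$r2cum[x$n_lv], x$q2cum[x$n_lv]))
  invisible(x)
}

#' Tidy a PLS model
#'
#' One row per fitted component with cumulative explained (`r2cum`) and
#' cross-validated (`q2cum`) Y-variance and whether the component is
#' retained.
#'
#' @param x a `pls_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$max_lv),
    r2cum = x$r2cum,
    q2cum = x$q2cum,
    retained = seq_len(x$max_lv) <= x$n_lv
  )
}

#' @rdname tidy.pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(
    n_lv = x$n_lv,
    r2cum = x$r2cum[x$n_lv],
    q2cum = x$q2cum[x$n_lv],
    cv_groups = x$cv_groups
  )
}
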