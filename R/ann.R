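#' Fit a PCA score basis on calibration spectra
#'
#' Column-centred principal component analysis; retains the smallest
#' number of components reaching `variance_target` cumulative explained
#' variance, capped by `n_pc_max` and `n_cal - 1`. The basis stores the
#' centring vector and loadings so new spectra can be projected
#' consistently.
#'
#' @param X calibration spectra matrix.
#' @param variance_target cumulative explained-variance fraction
#'   (default 0.99).
#' @param n_pc_max cap on retained components.
#' @return an object of class `pca_basis` with `rotation`, `center`,
#'   `explained` (per-component fractions) and `n_pc`.
#' @export
fit_pca_scores <- function(X, variance_target = 0.99, n_pc_max = 25L) {
  X <- as.matrix(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > max(ev) * 1e-12]
  frac <- ev / sum(pc$sdev^2)
  n_pc <- which(cumsum(frac) >= variance_target)[1L]
  if (is.na(n_pc)) n_pc <- length(frac)
  n_pc <- min(n_pc, n_pc_max, nrow(X) - 1L, length(frac))
  structure(
    list(rotation = pc$rotation[, seq_len(n_pc), drop = FALSE],
         center = pc$center,
         explained = frac[seq_len(n_pc)],
         n_pc = n_pc),
    class = "pca_basis"
  )
}

#' Project spectra onto a PCA basis
#'
#' @param basis a `pca_basis`.
#' @param X spectra matrix or [spectral_dataset()].
#' @return score matrix `n x n_pc`.
#' @export
project_scores <- function(basis, X) {
  if (inherits(X, "spectral_dataset")) X <- X$intensities
  sweep(as.matrix(X), 2L, basis$center) %*% basis$rotation
}

ann_activations <- function() c("identity", "logistic", "tanh", "exponential", "sine")

act_fun <- function(name, clip = 30) {
  switch(name,
    identity = list(f = function(x) x, df = function(x, fx) 1),
    logistic = list(f = function(x) 1 / (1 + exp(-x)),
                    df = function(x, fx) fx * (1 - fx)),
    tanh = list(f = tanh, df = function(x, fx) 1 - fx^2),
    exponential = list(f = function(x) exp(pmin(pmax(x, -clip), clip)),
                       df = function(x, fx) ifelse(abs(x) < clip, fx, 0)),
    sine = list(f = sin, df = function(x, fx) cos(x))
  )
}

# Train one MLP (1 hidden layer, H neurons, 1 output) by full-batch
# gradient descent with momentum; early stop on test-set SSE.
train_mlp <- function(Xtr, ytr, Xte, yte, H, act_h, act_o, seed,
                      lr = 0.05, momentum = 0.9, max_epochs = 500L,
                      patience = 20L) {
  P <- ncol(Xtr)
  fh <- act_fun(act_h); fo <- act_fun(act_o)
  with_seed(seed, {
    W1 <- matrix(runif(P * H, -0.5, 0.5), P, H)
    b1 <- runif(H, -0.5, 0.5)
    W2 <- matrix(runif(H, -0.5, 0.5), H, 1L)
    b2 <- runif(1L, -0.5, 0.5)
  })
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  forward <- function(X, W1, b1, W2, b2) {
    a1 <- sweep(X %*% W1, 2L, b1, `+`)
    h1 <- fh$f(a1)
    a2 <- as.numeric(h1 %*% W2 + b2)
    list(a1 = a1, h1 = h1, a2 = a2, out = fo$f(a2))
  }
  best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  wait <- 0L
  n_tr <- nrow(Xtr)
  for (ep in seq_len(max_epochs)) {
    fw <- forward(Xtr, W1, b1, W2, b2)
    err <- fw$out - ytr
    if (!all(is.finite(err))) break # diverged member
    d2 <- err * fo$df(fw$a2, fw$out) / n_tr
    gW2 <- crossprod(fw$h1, d2)
    gb2 <- sum(d2)
    dh <- (d2 %*% t(W2)) * fh$df(fw$a1, fw$h1)
    gW1 <- crossprod(Xtr, dh)
    gb1 <- colSums(dh)
    vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
    te <- forward(Xte, W1, b1, W2, b2)$out
    loss <- mean((te - yte)^2)
    if (is.finite(loss) && loss < best$loss - 1e-12) {
      best <- list(loss = loss, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best
}

mlp_forward <- function(net, X, act_h, act_o) {
  fh <- act_fun(act_h); fo <- act_fun(act_o)
  h1 <- fh$f(sweep(X %*% net$W1, 2L, net$b1, `+`))
  fo$f(as.numeric(h1 %*% net$W2 + net$b2))
}

#' Automated MLP network search on PC scores
#'
#' Trains the full grid of single-hidden-layer perceptrons: hidden
#' neuron count from 1 to `N + 1` (N = number of input principal
#' components) crossed with five hidden and five output activation
#' functions (identity, logistic, tanh, exponential, sine) — exactly
#' `25 * (N + 1)` candidate networks. Samples are split 70/15/15 into
#' training/test/validation subsets (seeded). Each member is trained by
#' full-batch gradient descent with momentum and early stopping on the
#' test subset; the winner is the network with the highest Pearson
#' correlation between target and output on the test subset (ties:
#' fewer hidden neurons, then earlier activation in the stated order).
#' Non-convergent members are recorded and skipped.
#'
#' Inputs are standardized per score column and the target is
#' standardized internally; predictions are returned on the original
#' scale.
#'
#' @param scores PC score matrix (rows = samples).
#' @param y numeric response.
#' @param seed integer seed (split + weight initialization).
#' @param max_epochs,patience training schedule.
#' @return an object of class `ann_model`: winner weights, topology,
#'   activations, split indices, correlations per subset, and the
#'   search `log` tibble (one row per candidate).
#' @export
ann_search <- function(scores, y, seed = 1L, max_epochs = 500L,
                       patience = 20L) {
  scores <- as.matrix(scores)
  y <- as.numeric(y)
  n <- nrow(scores)
  if (n < 10L) abort("need >= 10 samples for a 70/15/15 split",
                     class = "ramanscreen_parameter_error")
  N <- ncol(scores)
  # 70/15/15 split
  idx <- with_seed(derive_seed(seed, "ann_split"), sample.int(n))
  n_tr <- round(0.70 * n)
  n_te <- round(0.15 * n)
  tr <- idx[seq_len(n_tr)]
  te <- idx[seq(n_tr + 1L, n_tr + n_te)]
  va <- idx[seq(n_tr + n_te + 1L, n)]
  # standardize on training subset
  xm <- colMeans(scores[tr, , drop = FALSE])
  xs <- apply(scores[tr, , drop = FALSE], 2L, sd)
  xs[xs == 0] <- 1
  Z <- sweep(sweep(scores, 2L, xm), 2L, xs, `/`)
  ym <- mean(y[tr]); ys <- sd(y[tr])
  if (ys == 0) abort("response has zero variance in the training subset",
                     class = "ramanscreen_degenerate_error")
  yz <- (y - ym) / ys
  acts <- ann_activations()
  grid <- tidyr::expand_grid(n_hidden = seq_len(N + 1L),
                             hidden_activation = acts,
                             output_activation = acts)
  log <- grid
  log$test_r <- NA_real_
  log$converged <- FALSE
  nets <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    net <- train_mlp(Z[tr, , drop = FALSE], yz[tr],
                     Z[te, , drop = FALSE], yz[te],
                     H = grid$n_hidden[i],
                     act_h = grid$hidden_activation[i],
                     act_o = grid$output_activation[i],
                     seed = derive_seed(seed, paste0("ann_member_", i)),
                     max_epochs = max_epochs, patience = patience)
    if (!is.finite(net$loss)) next
    pred_te <- mlp_forward(net, Z[te, , drop = FALSE],
                           grid$hidden_activation[i], grid$output_activation[i])
    if (!all(is.finite(pred_te)) || sd(pred_te) == 0) next
    log$test_r[i] <- stats::cor(yz[te], pred_te)
    log$converged[i] <- TRUE
    nets[[i]] <- net
  }
  if (!any(log$converged)) {
    abort("no candidate network converged", class = "ramanscreen_degenerate_error")
  }
  # winner: max test r; ties -> fewer hidden neurons, then activation order
  ord <- order(-log$test_r, log$n_hidden,
               match(log$hidden_activation, acts),
               match(log$output_activation, acts),
               na.last = TRUE)
  win <- ord[1L]
  net <- nets[[win]]
  pred_all <- mlp_forward(net, Z, log$hidden_activation[win],
                          log$output_activation[win])
  corr <- c(train = stats::cor(yz[tr], pred_all[tr]),
            test = stats::cor(yz[te], pred_all[te]),
            validation = stats::cor(yz[va], pred_all[va]))
  structure(
    list(n_pc = N, n_hidden = log$n_hidden[win],
         hidden_activation = log$hidden_activation[win],
         output_activation = log$output_activation[win],
         weights = net[c("W1", "b1", "W2", "b2")],
         x_center = xm, x_scale = xs, y_center = ym, y_scale = ys,
         split = list(train = tr, test = te, validation = va),
         correlations = corr, log = log, seed = seed),
    class = "ann_model"
  )
}

#' Predict from an ANN model
#'
#' Projects spectra onto the stored PCA basis (same centring), applies
#' the stored score standardization and forward-passes the winning
#' network; output is rescaled to the response's original units.
#'
#' @param object an `ann_model`.
#' @param newdata score matrix (if `basis` is `NULL`) or spectra
#'   matrix / [spectral_dataset()] (with `basis`).
#' @param basis optional `pca_basis` used to project spectra first.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.ann_model <- function(object, newdata, basis = NULL, ...) {
  scores <- if (is.null(basis)) as.matrix(newdata) else project_scores(basis, newdata)
  Z <- sweep(sweep(scores, 2L, object$x_center), 2L, object$x_scale, `/`)
  z <- mlp_forward(object$weights, Z, object$hidden_activation,
                   object$output_activation)
  z * object$y_scale + object$y_center
}

#' @exportS3Method base::print
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %d PCs -> %d hidden (%s) -> 1 (%s)\n",
              x$n_pc, x$n_hidden, x$hidden_activation, x$output_activation))
  cat(sprintf("  r(train/test/val) = %.3f / %.3f / %.3f; grid searched: %d networks\n",
              x$correlations[1L], x$correlations[2L], x$correlations[3L],
              nrow(x$log)))
  invisible(x)
}

#' Tidy/glance an ANN search
#'
#' `tidy()` returns the full search log (one row per candidate network
#' with its test-set correlation); `glance()` the winner summary.
#'
#' @param x an `ann_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.ann_model <- function(x, ...) tibble::as_tibble(x$log)

#' @rdname tidy.ann_model
#' @export
glance.ann_model <- function(x, ...) {
  tibble::tibble(
    n_pc = x$n_pc, n_hidden = x$n_hidden,
    hidden_activation = x$hidden_activation,
    output_activation = x$output_activation,
    r_train = x$correlations[["train"]],
    r_test = x$correlations[["test"]],
    r_validation = x$correlations[["validation"]],
    n_candidates = nrow(x$log)
  )
}
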