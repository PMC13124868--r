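#' Code the screen as a factorial design
#'
#' Turns screen rows into a full-factorial dataset with the four filter
#' categories as sum-to-zero coded factors (replicate raw rows share
#' the raw cell's coding). The main-effects design matrix has
#' `1 + 5 + 4 + 3 + 3 = 16` columns.
#'
#' @param screen a `screen_table` (or any tibble with the four category
#'   columns); failed rows are dropped.
#' @param response which response column to carry (default both `mae`
#'   and `sd_ae`).
#' @return a tibble with factor columns `smoothing, baseline,
#'   normalization, other` (levels in library order, `contr.sum`
#'   contrasts attached) plus the response column(s).
#' @export
code_design <- function(screen, response = c("mae", "sd_ae")) {
  lv <- filter_levels()
  df <- tibble::as_tibble(screen)
  if ("failed" %in% names(df)) df <- dplyr::filter(df, !.data$failed)
  out <- df[intersect(c("parameter", "technique", "repetition", response),
                      names(df))]
  for (cat in names(lv)) {
    f <- factor(df[[cat]], levels = lv[[cat]])
    stats::contrasts(f) <- stats::contr.sum(length(lv[[cat]]))
    out[[cat]] <- f
  }
  dplyr::relocate(out, dplyr::all_of(names(lv)))
}

doe_formula <- function(response) {
  stats::as.formula(paste(
    response, "~ (smoothing + baseline + normalization + other)^2"))
}

# Profile log-likelihood of the Box-Cox transform for a candidate lambda.
boxcox_ll <- function(lambda, y, X_formula, data) {
  bc <- MASS::boxcox(X_formula, data = data, lambda = lambda, plotit = FALSE)
  bc$y[which.min(abs(bc$x - lambda))]
}

choose_transform <- function(formula, data, response) {
  y <- data[[response]]
  if (any(y <= 0)) return(list(name = "none", lambda = 1))
  bc <- MASS::boxcox(formula, data = data, lambda = seq(-1, 2, by = 0.05),
                     plotit = FALSE)
  ll_max <- max(bc$y)
  lambda_hat <- bc$x[which.max(bc$y)]
  cutoff <- ll_max - stats::qchisq(0.95, 1) / 2
  ll_at <- function(l) bc$y[which.min(abs(bc$x - l))]
  # prefer the simplest transform whose lambda is supported by the profile
  if (ll_at(1) >= cutoff) {
    list(name = "none", lambda = 1)
  } else if (ll_at(0) >= cutoff) {
    list(name = "log", lambda = 0)
  } else {
    list(name = "boxcox", lambda = lambda_hat)
  }
}

apply_transform <- function(y, tr) {
  switch(tr$name,
         none = y,
         log = log(y),
         boxcox = (y^tr$lambda - 1) / tr$lambda)
}

invert_transform <- function(z, tr) {
  switch(tr$name,
         none = z,
         log = exp(z),
         boxcox = (tr$lambda * z + 1)^(1 / tr$lambda))
}

#' Fit a factorial model for a prediction-error metric
#'
#' Ordinary least squares of the (optionally transformed) response on
#' the four coded factors, main effects plus all two-factor
#' interactions, followed by backward elimination: the droppable term
#' with the largest F-test p-value above `alpha` is removed repeatedly;
#' `drop1()`'s marginality rule keeps the model hierarchical (a main
#' effect is never dropped while one of its interactions remains).
#' `transform = "auto"` picks among none / log / Box-Cox by the Box-Cox
#' profile likelihood, preferring the simpler transform when the
#' profile supports it.
#'
#' @param coded output of [code_design()] (optionally pre-filtered to
#'   one parameter).
#' @param response `"mae"` or `"sd_ae"`.
#' @param alpha significance level for term retention (default 0.05).
#' @param transform `"auto"`, `"none"`, `"log"` or `"boxcox"`.
#' @return an object of class `metric_model`: the reduced `lm` fit, the
#'   transform, retained terms, and the observed response range
#'   (used later as desirability bounds).
#' @export
fit_metric_model <- function(coded, response = c("mae", "sd_ae"),
                             alpha = 0.05, transform = "auto") {
  response <- match.arg(response)
  data <- tibble::as_tibble(coded)
  data <- data[is.finite(data[[response]]), ]
  full_formula <- doe_formula(response)
  tr <- if (transform == "auto") {
    choose_transform(full_formula, data, response)
  } else if (transform == "boxcox") {
    bc <- MASS::boxcox(full_formula, data = data,
                       lambda = seq(-1, 2, by = 0.05), plotit = FALSE)
    list(name = "boxcox", lambda = bc$x[which.max(bc$y)])
  } else {
    list(name = transform, lambda = if (transform == "log") 0 else 1)
  }
  data$.y <- apply_transform(data[[response]], tr)
  fml <- stats::as.formula(
    ".y ~ (smoothing + baseline + normalization + other)^2")
  fit <- stats::lm(fml, data = data)
  if (any(is.na(coef(fit)))) {
    abort("aliased terms in the factorial model (design not full rank)",
          class = "ramanscreen_design_error")
  }
  repeat {
    # suppressWarnings: drop1 complains on saturated (zero-residual)
    # fits, which the NaN-p guard below already handles
    dr <- suppressWarnings(stats::drop1(fit, test = "F"))
    dr <- dr[rownames(dr) != "<none>", , drop = FALSE]
    if (nrow(dr) == 0L) break
    pv <- dr[["Pr(>F)"]]
    pv[!is.finite(pv)] <- 0 # saturated/perfect fits: keep the term
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    fit <- stats::update(fit, stats::as.formula(
      paste(". ~ . -", rownames(dr)[worst])))
  }
  structure(
    list(fit = fit, response = response, transform = tr, alpha = alpha,
         terms = attr(stats::terms(fit), "term.labels"),
         observed_range = range(data[[response]]),
         n = nrow(data)),
    class = "metric_model"
  )
}

#' Predict a metric model over filter combinations
#'
#' @param object a `metric_model`.
#' @param newdata tibble with the four category columns (default: all
#'   480 cells); coded internally.
#' @param ... unused.
#' @return numeric predictions on the original response scale.
#' @export
predict.metric_model <- function(object, newdata = filter_combinations(), ...) {
  lv <- filter_levels()
  nd <- tibble::as_tibble(newdata)
  for (cat in names(lv)) {
    nd[[cat]] <- factor(nd[[cat]], levels = lv[[cat]])
  }
  z <- stats::predict(object$fit, newdata = nd)
  invert_transform(as.numeric(z), object$transform)
}

#' @exportS3Method base::print
print.metric_model <- function(x, ...) {
  cat(sprintf("<metric_model> %s ~ %s (transform: %s)\n", x$response,
              paste(x$terms, collapse = " + "), x$transform$name))
  invisible(x)
}

#' Tidy / glance a factorial metric model
#'
#' `tidy()` returns the retained coefficients; `glance()` the fit
#' summary.
#'
#' @param x a `metric_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.metric_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1L],
                 std_error = s[, 2L], statistic = s[, 3L], p_value = s[, 4L])
}

#' @rdname tidy.metric_model
#' @export
glance.metric_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    response = x$response, transform = x$transform$name,
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    sigma = s$sigma, df_residual = x$fit$df.residual, n = x$n,
    n_terms = length(x$terms)
  )
}

#' Desirability specification
#'
#' Derringer-style minimize goals for the two prediction-error
#' responses: MAE carries importance 5, SD_AE importance 4; bounds
#' default to the observed response minimum and maximum over the
#' screen; weight 1 (linear ramp).
#'
#' @param importance named numeric vector of importances in 1..5.
#' @param weight ramp exponent(s) (default 1).
#' @return a list of class `desirability_spec`.
#' @export
desirability_spec <- function(importance = c(mae = 5, sd_ae = 4), weight = 1) {
  if (any(importance < 1 | importance > 5)) {
    abort("importances must be in 1..5", class = "ramanscreen_parameter_error")
  }
  structure(list(importance = importance, weight = weight),
            class = "desirability_spec")
}

#' Desirability of response values
#'
#' For a minimize goal, `d = ((U - y) / (U - L))^w`, clipped to
#' \[0, 1\]; the overall desirability is the importance-weighted
#' geometric mean `D = (prod d_i^r_i)^(1 / sum r_i)`.
#'
#' @param values numeric vector (one response value per response).
#' @param lower,upper bounds `L`, `U` per response (`L < U`).
#' @param importance importances `r_i`.
#' @param weight ramp exponent(s).
#' @return a list with per-response `d` and overall `D`.
#' @export
desirability <- function(values, lower, upper, importance = rep(1, length(values)),
                         weight = 1) {
  stopifnot(length(lower) == length(values), length(upper) == length(values))
  if (any(lower >= upper)) {
    abort("desirability bounds need L < U", class = "ramanscreen_parameter_error")
  }
  w <- rep_len(weight, length(values))
  d <- pmin(pmax((upper - values) / (upper - lower), 0), 1)^w
  r <- rep_len(importance, length(values))
  D <- prod(d^r)^(1 / sum(r))
  list(d = d, D = D)
}

#' Optimize the filter combination by desirability
#'
#' Because the factors are categorical and the design exhaustive, the
#' optimizer evaluates the fitted metric models at all 480 cells and
#' returns the combination maximizing the overall desirability `D`.
#' In `individual` mode, `models` holds one parameter's MAE and SD_AE
#' models (importances 5 and 4). In `overall` mode it holds all
#' parameters' models (7 x 2 = 14 responses), each scaled by its own
#' observed bounds so units never mix.
#'
#' @param models a named list of `metric_model` objects; names are used
#'   in the ramp output. Each model's desirability bounds default to
#'   its `observed_range`.
#' @param spec a [desirability_spec()]; importances are matched to each
#'   model's `response` (`mae` -> 5, `sd_ae` -> 4 by default).
#' @param cells candidate combinations (default all 480).
#' @return an object of class `desirability_result`: the best
#'   combination, its per-response predictions and `d_i`, overall `D`,
#'   and the full 480-cell evaluation (`ramp`).
#' @export
optimize_combination <- function(models, spec = desirability_spec(),
                                 cells = filter_combinations()) {
  stopifnot(length(models) >= 1L)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- paste0("response_", seq_along(models))
  }
  preds <- purrr::map(models, predict, newdata = cells)
  lower <- purrr::map_dbl(models, ~ .x$observed_range[1L])
  upper <- purrr::map_dbl(models, ~ .x$observed_range[2L])
  imp <- purrr::map_dbl(models, function(m) {
    unname(spec$importance[[m$response]] %||% 1)
  })
  n_cells <- nrow(cells)
  d_mat <- matrix(NA_real_, n_cells, length(models),
                  dimnames = list(NULL, names(models)))
  for (j in seq_along(models)) {
    d_mat[, j] <- pmin(pmax((upper[j] - preds[[j]]) / (upper[j] - lower[j]), 0),
                       1)^rep_len(spec$weight, 1L)
  }
  D <- exp(log(pmax(d_mat, 0)) %*% imp / sum(imp))
  D[apply(d_mat == 0, 1L, any)] <- 0
  D <- as.numeric(D)
  if (all(D == 0)) {
    warn("desirability is zero everywhere: responses never below their upper bounds",
         class = "ramanscreen_degenerate_warning")
  }
  best <- which.max(D)
  ramp <- dplyr::bind_cols(
    cells,
    tibble::as_tibble(purrr::map(preds, identity), .name_repair = "minimal"),
    tibble::as_tibble(as.data.frame(d_mat), .name_repair = "minimal") |>
      rlang::set_names(paste0("d_", names(models))),
    tibble::tibble(D = D)
  )
  structure(
    list(best = cells[best, ], D = D[best],
         predicted = purrr::map_dbl(preds, best),
         d = d_mat[best, ], ramp = ramp,
         importance = rlang::set_names(imp, names(models)),
         bounds = tibble::tibble(response = names(models),
                                 lower = lower, upper = upper)),
    class = "desirability_result"
  )
}

#' @exportS3Method base::print
print.desirability_result <- function(x, ...) {
  cat("<desirability_result>\n  best:", x$best$label, "\n")
  cat(sprintf("  overall D = %.4f over %d responses\n", x$D, length(x$d)))
  invisible(x)
}

#' Ramp plot for a desirability optimization
#'
#' Shows, per response, the predicted value at the optimal combination
#' on its \[L, U\] ramp together with its desirability.
#'
#' @param object a `desirability_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.desirability_result <- function(object, ...) {
  df <- object$bounds
  df$predicted <- unname(object$predicted)
  df$d <- unname(object$d)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower, xend = .data$upper,
                                       y = .data$response, yend = .data$response),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$predicted, y = .data$response,
                                     colour = .data$d), size = 3) +
    ggplot2::scale_colour_gradient(low = "red", high = "forestgreen",
                                   limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted response (L to U ramp)", y = NULL,
                  colour = "d",
                  title = paste("Optimal:", object$best$label),
                  subtitle = sprintf("Overall D = %.3f", object$D)) +
    ggplot2::theme_minimal()
}

#' Compare individually-optimal vs overall-optimal combinations
#'
#' For each parameter, a paired one-tailed t-test on the per-sample
#' absolute errors of the overall-optimal combination against the
#' individually-optimal one (`H1`: overall AE > individual AE, i.e. the
#' individual optimum is genuinely better).
#'
#' @param screen a `screen_table` with nested `errors`.
#' @param individual named list (by parameter) of `desirability_result`
#'   objects from per-parameter optimization.
#' @param overall a single `desirability_result` from overall
#'   optimization.
#' @param alpha significance level.
#' @return a tibble: one row per parameter with the two labels, their
#'   MAEs, and the t-test columns (`individual_lower` flags a
#'   significant improvement).
#' @export
compare_individual_vs_overall <- function(screen, individual, overall,
                                          alpha = 0.05) {
  df <- tibble::as_tibble(screen)
  get_errors <- function(param, lab) {
    row <- dplyr::filter(df, .data$parameter == .env$param,
                         .data$label == .env$lab,
                         .data$repetition == 1L)
    if (nrow(row) != 1L || row$failed) return(NULL)
    row$errors[[1L]]
  }
  purrr::map_dfr(names(individual), function(param) {
    lab_i <- individual[[param]]$best$label
    lab_o <- overall$best$label
    ei <- get_errors(param, lab_i)
    eo <- get_errors(param, lab_o)
    if (is.null(ei) || is.null(eo)) {
      return(tibble::tibble(parameter = param, individual = lab_i,
                            overall = lab_o, mae_individual = NA_real_,
                            mae_overall = NA_real_, t = NA_real_,
                            df = NA_real_, p_value = NA_real_,
                            individual_lower = NA))
    }
    if (identical(lab_i, lab_o)) {
      return(tibble::tibble(parameter = param, individual = lab_i,
                            overall = lab_o, mae_individual = mae(ei$ae),
                            mae_overall = mae(eo$ae), t = 0,
                            df = nrow(ei) - 1, p_value = 0.5,
                            individual_lower = FALSE))
    }
    m <- dplyr::inner_join(ei, eo, by = "sample_id", suffix = c("_i", "_o"))
    ht <- paired_t_one_tailed(m$ae_o, m$ae_i, alpha = alpha)
    tibble::tibble(parameter = param, individual = lab_i, overall = lab_o,
                   mae_individual = mae(ei$ae), mae_overall = mae(eo$ae),
                   t = ht$t, df = ht$df, p_value = ht$p_value,
                   individual_lower = ht$reject)
  })
}
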