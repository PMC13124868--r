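#' Enumerate the screening plan
#'
#' All 480 unique filter combinations (repetition 1) plus replicate
#' fits 2..10 of the raw (all-`none`) combination, appended after the
#' grid — 490 rows in total. The replicates re-fit the raw cell with a
#' different model seed and provide the pure-error estimate for the
#' factorial metric models.
#'
#' @param raw_repetitions number of additional raw-cell replicate fits
#'   appended after the grid (default 10, giving 490 rows).
#' @return a tibble with the four category columns, `label` and
#'   `repetition`.
#' @export
enumerate_screen <- function(raw_repetitions = 10L) {
  grid <- filter_combinations()
  grid$repetition <- 1L
  if (raw_repetitions > 0L) {
    reps <- raw_combination()[rep(1L, raw_repetitions), ]
    reps$repetition <- seq(2L, raw_repetitions + 1L)
    grid <- dplyr::bind_rows(grid, reps)
  }
  grid
}

#' Screen configuration
#'
#' Settings shared by every cell of a screen: the calibration split,
#' cross-validation, latent-variable selection, and where the metrics
#' are computed.
#'
#' @param cal_fraction calibration fraction of the 80/20 split.
#' @param cv_groups PLS cross-validation groups (default 7).
#' @param max_lv cap on PLS latent variables.
#' @param q2_gain minimum Q2cum gain to accept a component.
#' @param metrics_on `"validation"` (default) or `"calibration"`.
#' @param variance_target,n_pc_max PCA settings for the ANN technique.
#' @param ann_max_epochs,ann_patience ANN training schedule.
#' @param params a [filter_params()].
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(cal_fraction = 0.8, cv_groups = 7L, max_lv = 10L,
                          q2_gain = 0.01, metrics_on = c("validation", "calibration"),
                          variance_target = 0.99, n_pc_max = 25L,
                          ann_max_epochs = 500L, ann_patience = 20L,
                          params = filter_params()) {
  structure(
    list(cal_fraction = cal_fraction, cv_groups = cv_groups, max_lv = max_lv,
         q2_gain = q2_gain, metrics_on = match.arg(metrics_on),
         variance_target = variance_target, n_pc_max = n_pc_max,
         ann_max_epochs = ann_max_epochs, ann_patience = ann_patience,
         params = params),
    class = "screen_config"
  )
}

# Fit one technique on a preprocessed matrix and return the metric row
# pieces. `mat` is the full preprocessed matrix (rows = all samples).
screen_fit_one <- function(mat, yy, cal_idx, val_idx, technique, config,
                           fit_seed, K0 = NULL) {
  Xcal <- mat[cal_idx, , drop = FALSE]
  ycal <- yy[cal_idx]
  if (technique == "pls") {
    if (is.null(K0)) K0 <- tcrossprod(mat)
    model <- pls1_kernel_cv(K0, cal_idx, val_idx, ycal,
                            max_lv = config$max_lv,
                            cv_groups = config$cv_groups,
                            q2_gain = config$q2_gain, seed = fit_seed)
    eval_idx <- if (config$metrics_on == "validation") val_idx else cal_idx
    return(list(pred = model$predict(eval_idx), idx = eval_idx,
                size = model$n_lv))
  } else {
    basis <- fit_pca_scores(Xcal, variance_target = config$variance_target,
                            n_pc_max = config$n_pc_max)
    model <- ann_search(project_scores(basis, Xcal), ycal, seed = fit_seed,
                        max_epochs = config$ann_max_epochs,
                        patience = config$ann_patience)
    pred_all <- predict(model, mat, basis = basis)
    size <- model$n_hidden
  }
  eval_idx <- if (config$metrics_on == "validation") val_idx else cal_idx
  list(pred = pred_all[eval_idx], idx = eval_idx, size = size)
}

#' Run the exhaustive preprocessing screen
#'
#' For every enumerated cell (480 combinations + raw replicates) the
#' spectra are preprocessed, one calibration model per biochemical
#' parameter is fitted on the 80% calibration split, and MAE / SD_AE /
#' per-sample AE and RE are computed on the validation split. The same
#' calibration/validation split — drawn once from `seed`, stratified by
#' run — is reused for every cell so the cells are comparable;
#' replicate raw fits differ only by their model-fitting seed. A cell
#' whose preprocessing or fit degenerates is recorded as a failure row,
#' never aborts the screen.
#'
#' Preprocessing is cached stage-wise (smoothing, then baseline, then
#' normalization results are shared across the combinations that reuse
#' them), so the 490-cell screen costs far less than 490 full pipeline
#' passes.
#'
#' @param dataset a [spectral_dataset()].
#' @param references reference tibble (see [read_reference()]), joined
#'   to the dataset by `sample_id`.
#' @param technique `"pls"` or `"ann"`.
#' @param parameters which reference columns to model (default all
#'   seven).
#' @param config a [screen_config()].
#' @param seed master seed: drives the split and all model fits.
#' @param raw_repetitions additional raw-cell replicate fits (default
#'   10: 480 grid rows + 10 replicates = 490 rows per parameter).
#' @param progress print one line per smoothing stage.
#' @return a `screen_table` tibble: one row per (parameter, cell) with
#'   `parameter, technique, smoothing, baseline, normalization, other,
#'   label, repetition, model_size, n_eval, mae, sd_ae, failed` and a
#'   nested `errors` list-column (per-sample `sample_id, y_obs, y_pred,
#'   ae, re`). Attributes record seed, split and config.
#' @export
run_screen <- function(dataset, references, technique = c("pls", "ann"),
                       parameters = reference_parameters(),
                       config = screen_config(), seed = 1L,
                       raw_repetitions = 10L, progress = FALSE) {
  technique <- match.arg(technique)
  stopifnot(inherits(dataset, "spectral_dataset"))
  ids <- dataset$samples$sample_id
  if (!all(ids %in% references$sample_id)) {
    abort("every spectrum needs a reference row (join is by sample_id)",
          class = "ramanscreen_format_error")
  }
  refs <- references[match(ids, references$sample_id), , drop = FALSE]
  split <- split_calibration(dataset$samples, fraction = config$cal_fraction,
                             seed = seed)
  cal_idx <- match(split$cal, ids)
  val_idx <- match(split$val, ids)
  axis <- dataset$wavenumbers
  params <- config$params
  lv <- filter_levels()
  plan <- enumerate_screen(raw_repetitions)

  rows <- vector("list", nrow(plan) * length(parameters))
  ri <- 0L
  emit <- function(combo_row, rep_k, param, res, fail_msg = NULL) {
    ri <<- ri + 1L
    if (is.null(fail_msg)) {
      yy <- refs[[param]]
      obs <- yy[res$idx]
      pred <- res$pred
      keep <- is.finite(obs)
      obs <- obs[keep]; pred <- pred[keep]
      aev <- absolute_errors(obs, pred)
      rev_ <- suppressWarnings(relative_errors(obs, pred))
      rows[[ri]] <<- tibble::tibble(
        parameter = param, technique = technique,
        smoothing = combo_row$smoothing, baseline = combo_row$baseline,
        normalization = combo_row$normalization, other = combo_row$other,
        label = combo_row$label, repetition = rep_k,
        model_size = res$size, n_eval = length(obs),
        mae = mae(aev), sd_ae = sd_ae(aev), failed = FALSE,
        errors = list(tibble::tibble(
          sample_id = ids[res$idx][keep], y_obs = obs, y_pred = pred,
          ae = aev, re = rev_))
      )
    } else {
      rows[[ri]] <<- tibble::tibble(
        parameter = param, technique = technique,
        smoothing = combo_row$smoothing, baseline = combo_row$baseline,
        normalization = combo_row$normalization, other = combo_row$other,
        label = combo_row$label, repetition = rep_k,
        model_size = NA_integer_, n_eval = 0L,
        mae = NA_real_, sd_ae = NA_real_, failed = TRUE,
        errors = list(tibble::tibble(
          sample_id = character(), y_obs = numeric(), y_pred = numeric(),
          ae = numeric(), re = numeric()))
      )
    }
  }

  fit_cell <- function(mat, combo_row, rep_k) {
    fit_seed <- derive_seed(seed, paste0("fit_", combo_row$label, "_", rep_k))
    K0 <- if (technique == "pls") tcrossprod(mat) else NULL
    for (param in parameters) {
      yy <- refs[[param]]
      usable_cal <- cal_idx[is.finite(yy[cal_idx])]
      usable_val <- val_idx[is.finite(yy[val_idx])]
      res <- tryCatch(
        screen_fit_one(mat, yy, usable_cal, usable_val, technique, config,
                       derive_seed(fit_seed, param), K0 = K0),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        emit(combo_row, rep_k, param, NULL, fail_msg = conditionMessage(res))
      } else {
        emit(combo_row, rep_k, param, res)
      }
    }
  }

  # expected per-spectrum operator warnings (AsLS iteration cap, MSC
  # gain <= 0) are muffled so a 490-cell screen does not flood the
  # console; genuine errors still become failure rows
  quiet_stage <- function(expr) {
    tryCatch(
      withCallingHandlers(
        expr,
        warning = function(w) {
          if (inherits(w, c("ramanscreen_illconditioned_warning",
                            "ramanscreen_convergence_warning")))
            invokeRestart("muffleWarning")
        }),
      error = function(e) e)
  }
  for (sm in lv$smoothing) {
    if (progress) message("smoothing = ", sm)
    mat_s <- quiet_stage(apply_smoothing(dataset$intensities, sm, axis, params))
    for (bl in lv$baseline) {
      mat_b <- if (inherits(mat_s, "error")) mat_s else
        quiet_stage(apply_baseline(mat_s, bl, axis, params))
      for (nm in lv$normalization) {
        mat_n <- if (inherits(mat_b, "error")) mat_b else
          quiet_stage(apply_normalization(mat_b, nm, axis, params))
        for (ot in lv$other) {
          combo_row <- tibble::tibble(smoothing = sm, baseline = bl,
                                      normalization = nm, other = ot)
          combo_row$label <- combination_label(combo_row)
          is_raw <- identical(unname(unlist(combo_row[1, 1:4])),
                              rep("none", 4L))
          n_rep <- if (is_raw) raw_repetitions + 1L else 1L
          mat_o <- if (inherits(mat_n, "error")) mat_n else
            quiet_stage(apply_other(mat_n, ot, axis, params, cal_idx))
          for (rep_k in seq_len(n_rep)) {
            if (inherits(mat_o, "error")) {
              for (param in parameters) {
                emit(combo_row, rep_k, param, NULL,
                     fail_msg = conditionMessage(mat_o))
              }
            } else {
              fit_cell(mat_o, combo_row, rep_k)
            }
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  # enumeration order: grid rows first, raw replicates appended
  out <- dplyr::arrange(out, match(.data$parameter, parameters),
                        .data$repetition > 1L,
                        match(.data$label, filter_combinations()$label),
                        .data$repetition)
  attr(out, "seed") <- seed
  attr(out, "split") <- split
  attr(out, "config") <- config
  attr(out, "technique") <- technique
  class(out) <- c("screen_table", class(out))
  out
}

#' Write / read a screen metrics table
#'
#' `write_metrics()` writes the summary CSV (one row per parameter,
#' technique, combination, repetition) and a companion long CSV
#' (`<path stem>_errors.csv`) holding the per-sample AE/RE detail.
#' `read_metrics()` re-assembles the nested `screen_table`; the round
#' trip is lossless at full double precision.
#'
#' @param screen a `screen_table` from [run_screen()].
#' @param path summary CSV path.
#' @return `write_metrics()`: `path`, invisibly. `read_metrics()`: a
#'   `screen_table` tibble.
#' @export
write_metrics <- function(screen, path) {
  flat <- dplyr::select(tibble::as_tibble(screen), -dplyr::any_of("errors"))
  readr::write_csv(flat, path, progress = FALSE)
  if ("errors" %in% names(screen)) {
    detail <- tidyr::unnest(
      dplyr::select(tibble::as_tibble(screen), "parameter", "technique",
                    "label", "repetition", "errors"),
      "errors")
    readr::write_csv(detail, errors_path(path), progress = FALSE)
  }
  invisible(path)
}

errors_path <- function(path) {
  sub("\\.csv$", "_errors.csv", path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ep <- errors_path(path)
  if (file.exists(ep)) {
    detail <- readr::read_csv(ep, show_col_types = FALSE, progress = FALSE)
    detail$sample_id <- as.character(detail$sample_id)
    nested <- tidyr::nest(detail,
                          errors = c("sample_id", "y_obs", "y_pred", "ae", "re"))
    flat <- dplyr::left_join(flat, nested,
                             by = c("parameter", "technique", "label", "repetition"))
    empty <- tibble::tibble(sample_id = character(), y_obs = numeric(),
                            y_pred = numeric(), ae = numeric(), re = numeric())
    flat$errors <- lapply(flat$errors, function(e) if (is.null(e)) empty else e)
  }
  class(flat) <- c("screen_table", class(flat))
  flat
}

#' Plot a screen table
#'
#' MAE distribution per smoothing level (boxplots faceted by
#' parameter) — a quick look at which categories matter.
#'
#' @param object a `screen_table`.
#' @param response `"mae"` or `"sd_ae"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.screen_table <- function(object, response = c("mae", "sd_ae"), ...) {
  response <- match.arg(response)
  df <- dplyr::filter(tibble::as_tibble(object), !.data$failed)
  ggplot2::ggplot(df, ggplot2::aes(.data$smoothing, .data[[response]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Smoothing level", y = toupper(response)) +
    ggplot2::theme_minimal()
}
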