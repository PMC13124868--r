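#' Fit the calibration models for one filter combination
#'
#' Convenience wrapper used after the screen has chosen a combination:
#' preprocesses the dataset with the combination (MSC reference from
#' the calibration split), fits one model per parameter on the
#' calibration rows, and returns everything needed to predict new
#' spectra consistently.
#'
#' @param dataset a [spectral_dataset()].
#' @param references reference tibble.
#' @param combo combination (label, one-row tibble or list).
#' @param technique `"pls"` or `"ann"`.
#' @param parameters reference columns to model.
#' @param config a [screen_config()].
#' @param seed integer seed (split + fits).
#' @return an object of class `calibration_set`: per-parameter models,
#'   the split, the combination, and the preprocessing context.
#' @export
fit_combination_models <- function(dataset, references, combo,
                                   technique = c("pls", "ann"),
                                   parameters = reference_parameters(),
                                   config = screen_config(), seed = 1L) {
  technique <- match.arg(technique)
  if (is.character(combo)) combo <- parse_combination(combo)
  combo <- tibble::as_tibble(as.list(combo)[c("smoothing", "baseline",
                                              "normalization", "other")])
  ids <- dataset$samples$sample_id
  refs <- references[match(ids, references$sample_id), , drop = FALSE]
  split <- split_calibration(dataset$samples, fraction = config$cal_fraction,
                             seed = seed)
  pre <- apply_combination(dataset, combo, params = config$params,
                           cal_ids = split$cal)
  cal_idx <- match(split$cal, ids)
  label <- combination_label(combo)
  models <- list()
  for (param in parameters) {
    yy <- refs[[param]]
    use <- cal_idx[is.finite(yy[cal_idx])]
    fit_seed <- derive_seed(derive_seed(seed, paste0("fit_", label, "_", 1L)),
                            param)
    if (technique == "pls") {
      models[[param]] <- list(
        model = fit_pls(pre$intensities[use, , drop = FALSE], yy[use],
                        max_lv = config$max_lv, cv_groups = config$cv_groups,
                        q2_gain = config$q2_gain, seed = fit_seed),
        basis = NULL)
    } else {
      basis <- fit_pca_scores(pre$intensities[use, , drop = FALSE],
                              variance_target = config$variance_target,
                              n_pc_max = config$n_pc_max)
      models[[param]] <- list(
        model = ann_search(project_scores(basis, pre$intensities[use, , drop = FALSE]),
                           yy[use], seed = fit_seed,
                           max_epochs = config$ann_max_epochs,
                           patience = config$ann_patience),
        basis = basis)
    }
  }
  structure(
    list(models = models, technique = technique, combo = combo,
         label = label, split = split, config = config, seed = seed,
         cal_ids = split$cal),
    class = "calibration_set"
  )
}

#' Predict parameters for new spectra from a calibration set
#'
#' @param object a `calibration_set`.
#' @param newdata a [spectral_dataset()] sharing the calibration axis.
#' @param calibration the calibration [spectral_dataset()] (needed so
#'   the MSC reference is re-fitted on the same calibration rows).
#' @param ... unused.
#' @return a tibble `sample_id x parameter` (wide).
#' @export
predict.calibration_set <- function(object, newdata, calibration, ...) {
  if (!isTRUE(all.equal(newdata$wavenumbers, calibration$wavenumbers))) {
    abort("new spectra must share the calibration wavenumber axis",
          class = "ramanscreen_interface_error")
  }
  # temporary unique ids so new spectra may legitimately repeat
  # calibration sample ids
  tmp <- newdata
  tmp$samples$sample_id <- paste0(".new_", seq_len(nrow(tmp$intensities)))
  rownames(tmp$intensities) <- tmp$samples$sample_id
  joint <- rbind_spectra(calibration, tmp)
  pre <- apply_combination(joint, object$combo,
                           params = object$config$params,
                           cal_ids = object$cal_ids)
  new_idx <- match(tmp$samples$sample_id, joint$samples$sample_id)
  X <- pre$intensities[new_idx, , drop = FALSE]
  out <- tibble::tibble(sample_id = newdata$samples$sample_id)
  for (param in names(object$models)) {
    m <- object$models[[param]]
    out[[param]] <- if (object$technique == "pls") {
      predict(m$model, X)
    } else {
      predict(m$model, X, basis = m$basis)
    }
  }
  out
}

#' Simulate biochemical profiles from hourly spectra
#'
#' Validates a chosen filter combination + calibration models on
#' hourly spectra that never entered model fitting: preprocesses them
#' with the calibration-fitted context and predicts every parameter at
#' every hour.
#'
#' @param calset a `calibration_set` from [fit_combination_models()].
#' @param hourly a [spectral_dataset()] of hourly spectra (one run).
#' @param calibration the calibration [spectral_dataset()].
#' @param clamp_nonnegative clip negative predictions to zero.
#' @return a `profile_simulation` tibble: `run_id, time_h, parameter,
#'   predicted`, with provenance attributes (combination label, seed).
#' @export
simulate_profiles <- function(calset, hourly, calibration,
                              clamp_nonnegative = FALSE) {
  wide <- predict(calset, hourly, calibration)
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(hourly$samples[c("run_id", "time_h")], wide["sample_id"],
                     wide[setdiff(names(wide), "sample_id")]),
    cols = -c("run_id", "time_h", "sample_id"),
    names_to = "parameter", values_to = "predicted")
  if (clamp_nonnegative) long$predicted <- pmax(long$predicted, 0)
  attr(long, "combination") <- calset$label
  attr(long, "technique") <- calset$technique
  attr(long, "seed") <- calset$seed
  class(long) <- c("profile_simulation", class(long))
  long
}

#' Plot simulated profiles against observations
#'
#' @param object a `profile_simulation`.
#' @param observed optional reference tibble (points overlay).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.profile_simulation <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_h, .data$predicted)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Predicted value",
                  title = attr(object, "combination")) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    obs <- tidyr::pivot_longer(
      observed[c("time_h", intersect(reference_parameters(), names(observed)))],
      cols = -"time_h", names_to = "parameter", values_to = "value")
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(.data$time_h, .data$value),
                                 size = 0.8, colour = "black")
  }
  p
}

#' Summarize screening and optimization results
#'
#' Per parameter and optimization mode: the chosen filter levels,
#' model size (latent variables or hidden neurons), and MAE +/- SD_AE
#' read back from the screen.
#'
#' @param screen a `screen_table`.
#' @param individual named list (by parameter) of per-parameter
#'   `desirability_result`s.
#' @param overall an overall `desirability_result` (or `NULL`).
#' @return a tibble report; prints a readable summary.
#' @export
screen_report <- function(screen, individual = list(), overall = NULL) {
  df <- tibble::as_tibble(screen)
  if (nrow(df) == 0L) {
    message("no results: empty screen")
    return(tibble::tibble())
  }
  pull_row <- function(param, lab, mode) {
    row <- dplyr::filter(df, .data$parameter == .env$param,
                         .data$label == .env$lab,
                         .data$repetition == 1L)
    if (nrow(row) == 0L) return(NULL)
    tibble::tibble(
      parameter = param, mode = mode,
      smoothing = row$smoothing, baseline = row$baseline,
      normalization = row$normalization, other = row$other,
      model_size = row$model_size, mae = row$mae, sd_ae = row$sd_ae
    )
  }
  out <- list()
  for (param in names(individual)) {
    out[[length(out) + 1L]] <-
      pull_row(param, individual[[param]]$best$label, "individual")
  }
  if (!is.null(overall)) {
    for (param in unique(df$parameter)) {
      out[[length(out) + 1L]] <- pull_row(param, overall$best$label, "overall")
    }
  }
  dplyr::bind_rows(out)
}

#' Read a workflow configuration from YAML
#'
#' Optional `filters:` block overrides [filter_params()] defaults;
#' `screen:` overrides [screen_config()] defaults (split fractions,
#' cv_groups, max_lv, alpha-level settings live here).
#'
#' @param path YAML file path.
#' @return a [screen_config()].
#' @export
read_workflow_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fp <- do.call(filter_params, cfg$filters %||% list())
  sc <- cfg$screen %||% list()
  sc$params <- fp
  do.call(screen_config, sc)
}
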