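#' Filter category levels
#'
#' The four preprocessing categories and their levels, in the canonical
#' library order used for enumeration and factor coding.
#'
#' @return named list of character vectors.
#' @export
filter_levels <- function() {
  list(
    smoothing = c("SG", "EWMA", "WDS", "MW", "AsLS", "none"),
    baseline = c("rowcenter", "offset", "linear", "asls", "none"),
    normalization = c("snv", "peakheight", "peakarea", "none"),
    other = c("msc", "d1q", "d2c", "none")
  )
}

#' Enumerate all filter combinations
#'
#' Full factorial over the four categories: 6 smoothing x 5 baseline x
#' 4 normalization x 4 other = 480 unique combinations. Enumeration is
#' deterministic: category levels in library order, the last category
#' varying fastest, so the all-`none` (raw) combination is row 480.
#'
#' @return a tibble with columns `smoothing, baseline, normalization,
#'   other, label`.
#' @export
filter_combinations <- function() {
  lv <- filter_levels()
  grid <- tidyr::expand_grid(
    smoothing = lv$smoothing, baseline = lv$baseline,
    normalization = lv$normalization, other = lv$other
  )
  grid$label <- combination_label(grid)
  grid
}

#' Combination labels
#'
#' Canonical machine-readable label, e.g.
#' `smoothing=MW,baseline=offset,norm=none,other=none`.
#'
#' @param combo a tibble/data frame with the four category columns (one
#'   or more rows), or a named list for a single combination.
#' @return character vector of labels.
#' @export
combination_label <- function(combo) {
  combo <- tibble::as_tibble(as.list(combo)[c("smoothing", "baseline",
                                              "normalization", "other")])
  sprintf("smoothing=%s,baseline=%s,norm=%s,other=%s",
          combo$smoothing, combo$baseline, combo$normalization, combo$other)
}

#' Parse a combination label
#'
#' @param label character vector of labels from [combination_label()].
#' @return a tibble with the four category columns.
#' @export
parse_combination <- function(label) {
  parts <- strsplit(label, ",", fixed = TRUE)
  lv <- filter_levels()
  out <- purrr::map_dfr(parts, function(p) {
    kv <- strsplit(p, "=", fixed = TRUE)
    vals <- vapply(kv, `[`, "", 2L)
    names(vals) <- vapply(kv, `[`, "", 1L)
    tibble::tibble(smoothing = vals[["smoothing"]], baseline = vals[["baseline"]],
                   normalization = vals[["norm"]], other = vals[["other"]])
  })
  for (cat in names(lv)) {
    bad <- setdiff(out[[cat]], lv[[cat]])
    if (length(bad)) abort(paste0("unknown ", cat, " level: ", bad[1L]),
                           class = "ramanscreen_parameter_error")
  }
  out
}

#' The raw (all-none) combination
#' @return one-row tibble.
#' @export
raw_combination <- function() {
  tibble::tibble(smoothing = "none", baseline = "none",
                 normalization = "none", other = "none",
                 label = "smoothing=none,baseline=none,norm=none,other=none")
}

apply_op_matrix <- function(mat, fun, ...) {
  out <- t(apply(mat, 1L, fun, ...))
  dimnames(out) <- dimnames(mat)
  out
}

# Stage-wise application used by both apply_combination() and the
# cached screening loop. `cal_idx` marks calibration rows (MSC reference).
apply_smoothing <- function(mat, level, axis, params) {
  switch(level,
    none = mat,
    SG = apply_op_matrix(mat, sg_smooth, params = params),
    EWMA = apply_op_matrix(mat, ewma_smooth, params = params),
    WDS = apply_op_matrix(mat, wavelet_denoise, params = params),
    MW = apply_op_matrix(mat, moving_median, params = params),
    AsLS = apply_op_matrix(mat, asls_fit, params = params),
    abort(paste("unknown smoothing level:", level),
          class = "ramanscreen_parameter_error")
  )
}

apply_baseline <- function(mat, level, axis, params) {
  switch(level,
    none = mat,
    rowcenter = mat - rowMeans(mat),
    offset = mat - apply(mat, 1L, min),
    linear = apply_op_matrix(mat, baseline_linear, axis = axis),
    asls = apply_op_matrix(mat, baseline_asls, params = params),
    abort(paste("unknown baseline level:", level),
          class = "ramanscreen_parameter_error")
  )
}

apply_normalization <- function(mat, level, axis, params) {
  switch(level,
    none = mat,
    snv = apply_op_matrix(mat, snv),
    peakheight = apply_op_matrix(mat, norm_peak_height, axis = axis, params = params),
    peakarea = apply_op_matrix(mat, norm_peak_area, axis = axis, params = params),
    abort(paste("unknown normalization level:", level),
          class = "ramanscreen_parameter_error")
  )
}

apply_other <- function(mat, level, axis, params, cal_idx) {
  switch(level,
    none = mat,
    msc = {
      ref <- msc_fit(mat[cal_idx, , drop = FALSE])
      apply_op_matrix(mat, msc_apply, ref = ref)
    },
    d1q = apply_op_matrix(mat, deriv_first_quadratic, axis = axis, params = params),
    d2c = apply_op_matrix(mat, deriv_second_cubic, axis = axis, params = params),
    abort(paste("unknown other level:", level),
          class = "ramanscreen_parameter_error")
  )
}

#' Apply one preprocessing combination to a dataset
#'
#' Operators are applied in the fixed category order smoothing ->
#' baseline -> normalization -> other; `none` in a category is the
#' identity. Everything is strictly per-spectrum except the MSC
#' reference, which is the mean of the calibration rows only
#' (`cal_ids`) and is reused unchanged for all other rows.
#'
#' @param dataset a [spectral_dataset()].
#' @param combo one combination: a one-row tibble (see
#'   [filter_combinations()]), a label string, or a named list.
#' @param params a [filter_params()].
#' @param cal_ids sample ids forming the calibration set (MSC
#'   reference); default all samples.
#' @return a [spectral_dataset()] of the same shape with preprocessed
#'   intensities.
#' @export
apply_combination <- function(dataset, combo, params = filter_params(),
                              cal_ids = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (is.character(combo)) combo <- parse_combination(combo)
  combo <- tibble::as_tibble(as.list(combo)[c("smoothing", "baseline",
                                              "normalization", "other")])
  stopifnot(nrow(combo) == 1L)
  cal_ids <- cal_ids %||% dataset$samples$sample_id
  cal_idx <- match(cal_ids, dataset$samples$sample_id)
  if (anyNA(cal_idx)) abort("cal_ids not all present in the dataset",
                            class = "ramanscreen_format_error")
  axis <- dataset$wavenumbers
  mat <- dataset$intensities
  label <- combination_label(combo)
  step <- function(expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("combination [", label, "]: ", conditionMessage(e)),
              class = class(e)[1L], parent = e)
      }),
      warning = function(w) w
    )
  }
  mat <- step(apply_smoothing(mat, combo$smoothing, axis, params))
  mat <- step(apply_baseline(mat, combo$baseline, axis, params))
  mat <- step(apply_normalization(mat, combo$normalization, axis, params))
  mat <- step(apply_other(mat, combo$other, axis, params, cal_idx))
  out <- dataset
  out$intensities <- mat
  out
}
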