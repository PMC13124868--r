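#' Spectral dataset container
#'
#' Bundles a shared wavenumber axis, an intensity matrix (one row per
#' sample) and per-sample metadata. This is the X block of every
#' calibration model in the package. The axis is stored strictly
#' ascending with uniform spacing; files with descending axes are
#' flipped on read.
#'
#' @param intensities numeric matrix, `n_samples x n_wavenumbers`.
#' @param wavenumbers numeric vector of Raman shifts (cm^-1), strictly
#'   increasing, uniformly spaced.
#' @param sample_id character vector of unique sample identifiers.
#' @param run_id optional character vector of bioreactor run ids.
#' @param time_h optional numeric vector of sample times (hours).
#'
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavenumbers`, `intensities` (rownames = sample ids) and `samples`
#'   (a tibble with `sample_id`, `run_id`, `time_h`).
#' @export
spectral_dataset <- function(intensities, wavenumbers, sample_id,
                             run_id = NA_character_, time_h = NA_real_) {
  intensities <- as.matrix(intensities)
  wavenumbers <- as.numeric(wavenumbers)
  validate_axis(wavenumbers)
  if (ncol(intensities) != length(wavenumbers)) {
    abort(sprintf("intensity columns (%d) must match axis length (%d)",
                  ncol(intensities), length(wavenumbers)),
          class = "ramanscreen_format_error")
  }
  if (anyNA(intensities)) {
    abort("intensity matrix contains missing values",
          class = "ramanscreen_format_error")
  }
  n <- nrow(intensities)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n) {
    abort("sample_id length must equal the number of spectra",
          class = "ramanscreen_format_error")
  }
  if (anyDuplicated(sample_id)) {
    abort("sample ids must be unique", class = "ramanscreen_format_error")
  }
  samples <- tibble::tibble(
    sample_id = sample_id,
    run_id = rep_len(as.character(run_id), n),
    time_h = rep_len(as.numeric(time_h), n)
  )
  rownames(intensities) <- sample_id
  colnames(intensities) <- NULL
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities, samples = samples),
    class = "spectral_dataset"
  )
}

validate_axis <- function(wn, tol = 1e-6) {
  if (length(wn) < 2L) {
    abort("wavenumber axis needs at least two points",
          class = "ramanscreen_axis_error")
  }
  d <- diff(wn)
  if (any(d <= 0)) {
    abort("wavenumber axis must be strictly increasing (duplicates or reversals found)",
          class = "ramanscreen_axis_error")
  }
  if (diff(range(d)) > tol * max(abs(d))) {
    abort("wavenumber axis must be uniformly spaced",
          class = "ramanscreen_axis_error")
  }
  invisible(wn)
}

#' Default wavenumber axis
#'
#' Full-range probe axis: 100 to 3425 cm^-1 at 1 cm^-1 resolution
#' (3326 points).
#' @return numeric vector.
#' @export
default_axis <- function() seq(100, 3425, by = 1)

#' @exportS3Method base::print
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d spectra x %d wavenumbers (%.0f-%.0f cm^-1, step %.3g)\n",
    nrow(x$intensities), length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers), x$wavenumbers[2] - x$wavenumbers[1]
  ))
  runs <- unique(x$samples$run_id)
  if (!all(is.na(runs))) cat("  runs:", paste(runs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Subset a spectral dataset by sample
#'
#' @param x a [spectral_dataset()].
#' @param ids character vector of sample ids (order preserved).
#' @return a `spectral_dataset` with the selected rows.
#' @export
filter_samples <- function(x, ids) {
  stopifnot(inherits(x, "spectral_dataset"))
  miss <- setdiff(ids, x$samples$sample_id)
  if (length(miss)) {
    abort(paste("unknown sample ids:", paste(miss, collapse = ", ")),
          class = "ramanscreen_format_error")
  }
  idx <- match(ids, x$samples$sample_id)
  spectral_dataset(x$intensities[idx, , drop = FALSE], x$wavenumbers,
                   x$samples$sample_id[idx], x$samples$run_id[idx],
                   x$samples$time_h[idx])
}

#' Read a spectral matrix from CSV
#'
#' Two dialects are supported. `wide`: first column `wavenumber_cm-1`,
#' one subsequent column per sample id. `tidy`: long format with columns
#' `sample_id, wavenumber_cm-1, intensity`. Descending axes are flipped
#' to the internal ascending convention.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"tidy"`.
#' @return a [spectral_dataset()] (run/time metadata unset; join a
#'   reference table for those).
#' @export
read_spectra <- function(path, dialect = c("wide", "tidy")) {
  dialect <- match.arg(dialect)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "wide") {
    wn <- as.numeric(df[[1L]])
    if (anyNA(wn)) {
      abort("wavenumber column is not numeric", class = "ramanscreen_format_error")
    }
    mat <- t(as.matrix(df[-1L]))
    if (all(diff(wn) < 0)) { # descending export: flip
      wn <- rev(wn)
      mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
    }
    validate_axis(wn)
    spectral_dataset(mat, wn, colnames(df)[-1L])
  } else {
    need <- c("sample_id", "wavenumber_cm-1", "intensity")
    if (!all(need %in% names(df))) {
      abort(paste("tidy spectra CSV needs columns:", paste(need, collapse = ", ")),
            class = "ramanscreen_format_error")
    }
    wide <- tidyr::pivot_wider(df, names_from = "sample_id",
                               values_from = "intensity")
    wide <- dplyr::arrange(wide, .data[["wavenumber_cm-1"]])
    wn <- wide[["wavenumber_cm-1"]]
    mat <- t(as.matrix(wide[setdiff(names(wide), "wavenumber_cm-1")]))
    if (anyNA(mat)) {
      abort("ragged tidy spectra: not every sample covers every wavenumber",
            class = "ramanscreen_format_error")
    }
    validate_axis(wn)
    spectral_dataset(mat, wn, rownames(mat))
  }
}

#' Write a spectral dataset to wide CSV
#'
#' Column 1 is `wavenumber_cm-1`; one column per sample id. Round-trips
#' losslessly through [read_spectra()] at full double precision.
#'
#' @param x a [spectral_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectral_dataset"))
  df <- tibble::as_tibble(t(x$intensities), .name_repair = "minimal")
  names(df) <- x$samples$sample_id
  df <- dplyr::bind_cols(tibble::tibble(`wavenumber_cm-1` = x$wavenumbers), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a reference (offline measurement) table
#'
#' Expected columns: `sample_id, run_id, time_h, Xv_1e5_cells_per_mL,
#' CV_pct, Gluc_g_L, Lac_g_L, Gln_g_L, Glu_g_L, NH4_g_L`. Viability is
#' checked to lie in \[0, 100\] and concentrations to be non-negative.
#' Missing values are allowed (that sample is simply excluded from the
#' affected parameter's models).
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_reference <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", reference_parameters())
  if (!all(need %in% names(df))) {
    abort(paste("reference CSV needs columns:",
                paste(setdiff(need, names(df)), collapse = ", ")),
          class = "ramanscreen_format_error")
  }
  cv <- df$CV_pct
  if (any(cv < 0 | cv > 100, na.rm = TRUE)) {
    abort("CV_pct outside [0, 100]", class = "ramanscreen_format_error")
  }
  conc <- c("Gluc_g_L", "Lac_g_L", "Gln_g_L", "Glu_g_L", "NH4_g_L",
            "Xv_1e5_cells_per_mL")
  for (cc in conc) {
    if (any(df[[cc]] < 0, na.rm = TRUE)) {
      abort(paste(cc, "has negative values"), class = "ramanscreen_format_error")
    }
  }
  df$sample_id <- as.character(df$sample_id)
  tibble::as_tibble(df)
}

#' The seven modelled biochemical parameters
#'
#' Column names used throughout: viable cell density, viability, and the
#' five nutrient/metabolite concentrations.
#' @return character vector of reference-table column names.
#' @export
reference_parameters <- function() {
  c("Xv_1e5_cells_per_mL", "CV_pct", "Gluc_g_L", "Lac_g_L",
    "Gln_g_L", "Glu_g_L", "NH4_g_L")
}

#' Average the spectra collected immediately before each sampling moment
#'
#' For every sampling time, takes the arithmetic mean of the `n_spectra`
#' most recent spectra with timestamp at or before that time — the
#' standard way one calibration spectrum is formed from continuously
#' acquired inline spectra.
#'
#' @param raw a [spectral_dataset()] with `time_h` set, ordered or not.
#' @param sampling_times numeric vector of sampling moments (h).
#' @param n_spectra window size (default 6).
#' @param sample_id ids for the averaged spectra (default `avg_<k>`).
#' @param run_id run id(s) for the averaged spectra.
#' @return a [spectral_dataset()] with one spectrum per sampling time.
#' @export
average_presample_spectra <- function(raw, sampling_times, n_spectra = 6L,
                                      sample_id = NULL, run_id = NA_character_) {
  stopifnot(inherits(raw, "spectral_dataset"))
  if (n_spectra < 1L) {
    abort("n_spectra must be >= 1", class = "ramanscreen_window_error")
  }
  ord <- order(raw$samples$time_h)
  tt <- raw$samples$time_h[ord]
  mat <- raw$intensities[ord, , drop = FALSE]
  out <- matrix(NA_real_, length(sampling_times), ncol(mat))
  for (k in seq_along(sampling_times)) {
    idx <- which(tt <= sampling_times[k])
    if (length(idx) < n_spectra) {
      abort(sprintf("only %d spectra precede sampling time %.3g h (need %d)",
                    length(idx), sampling_times[k], n_spectra),
            class = "ramanscreen_window_error")
    }
    win <- tail(idx, n_spectra)
    out[k, ] <- colMeans(mat[win, , drop = FALSE])
  }
  if (is.null(sample_id)) sample_id <- sprintf("avg_%02d", seq_along(sampling_times))
  spectral_dataset(out, raw$wavenumbers, sample_id, run_id, sampling_times)
}

#' Plot spectra
#'
#' One line per sample, coloured by run where available.
#'
#' @param object a [spectral_dataset()].
#' @param samples optional sample ids to restrict to.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spectral_dataset <- function(object, samples = NULL, ...) {
  x <- if (is.null(samples)) object else filter_samples(object, samples)
  long <- tibble::tibble(
    sample_id = rep(x$samples$sample_id, each = length(x$wavenumbers)),
    run_id = rep(x$samples$run_id, each = length(x$wavenumbers)),
    wavenumber = rep(x$wavenumbers, nrow(x$intensities)),
    intensity = as.vector(t(x$intensities))
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     group = .data$sample_id,
                                     colour = .data$run_id)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Intensity (counts)", colour = "Run") +
    ggplot2::theme_minimal()
}
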