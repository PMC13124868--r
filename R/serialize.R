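#' Serialize fitted models to JSON
#'
#' Writes a `pls_model` or `ann_model` as plain JSON — scalars, split
#' ids, and flattened weight arrays with shape tags — so fitted models
#' can be archived or exchanged without binary formats.
#' `read_model_json()` reconstructs an object whose predictions are
#' identical to the original's.
#'
#' @param model a `pls_model` or `ann_model`.
#' @param path output path (`.json`).
#' @return `write_model_json()`: `path`, invisibly;
#'   `read_model_json()`: the reconstructed model object.
#' @export
write_model_json <- function(model, path) {
  flat <- function(x) list(dim = dim(x) %||% length(x), data = as.numeric(x))
  payload <- if (inherits(model, "pls_model")) {
    list(
      type = "pls_model", n_lv = model$n_lv, max_lv = model$max_lv,
      cv_groups = model$cv_groups, seed = model$seed,
      coefficients = flat(model$coefficients), intercept = model$intercept,
      x_center = flat(model$x_center), y_center = model$y_center,
      r2cum = model$r2cum, q2cum = model$q2cum
    )
  } else if (inherits(model, "ann_model")) {
    list(
      type = "ann_model", n_pc = model$n_pc, n_hidden = model$n_hidden,
      hidden_activation = model$hidden_activation,
      output_activation = model$output_activation, seed = model$seed,
      weights = lapply(model$weights, flat),
      x_center = flat(model$x_center), x_scale = flat(model$x_scale),
      y_center = model$y_center, y_scale = model$y_scale,
      split = model$split, correlations = as.list(model$correlations)
    )
  } else {
    abort("only pls_model and ann_model can be serialized",
          class = "ramanscreen_format_error")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  unflat <- function(f) {
    if (length(f$dim) == 2L) matrix(f$data, f$dim[1L], f$dim[2L]) else f$data
  }
  if (identical(p$type, "pls_model")) {
    structure(
      list(n_lv = as.integer(p$n_lv), coefficients = unflat(p$coefficients),
           intercept = p$intercept, x_center = unflat(p$x_center),
           y_center = p$y_center, r2cum = p$r2cum, q2cum = p$q2cum,
           max_lv = p$max_lv, cv_groups = p$cv_groups, seed = p$seed),
      class = "pls_model")
  } else if (identical(p$type, "ann_model")) {
    structure(
      list(n_pc = as.integer(p$n_pc), n_hidden = as.integer(p$n_hidden),
           hidden_activation = p$hidden_activation,
           output_activation = p$output_activation,
           weights = lapply(p$weights, unflat),
           x_center = unflat(p$x_center), x_scale = unflat(p$x_scale),
           y_center = p$y_center, y_scale = p$y_scale,
           split = p$split, correlations = unlist(p$correlations),
           log = tibble::tibble(), seed = p$seed),
      class = "ann_model")
  } else {
    abort("unrecognized model JSON", class = "ramanscreen_format_error")
  }
}
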