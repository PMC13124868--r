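#' @importFrom rlang %||% abort warn .data .env
#' @importFrom stats median sd lm coef predict rnorm runif var quantile
#' @importFrom utils head tail
NULL

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 69069 + h * 1013 + 1) %% 2147483562) + 1L
}

# Evaluate `expr` with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
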