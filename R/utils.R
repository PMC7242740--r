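#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats dnorm pnorm rnorm rpois sd var quantile median convolve
#' @importFrom stats lm as.formula uniroot setNames wilcox.test cor complete.cases
#' @importFrom utils write.csv read.csv head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib omihet, .registration = TRUE
NULL

# Run code under a local RNG state seeded with `seed`; NULL leaves the global
# stream untouched. All package randomness funnels through here.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "omihet_invalid_parameter")
  }
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
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "omihet_invalid_parameter")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1].", name),
          class = "omihet_invalid_parameter")
  }
  invisible(x)
}
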