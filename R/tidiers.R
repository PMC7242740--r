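#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted Gaussian mixture
#'
#' @param x An `omihet_gmm`.
#' @param ... Unused.
#' @return One row per component: `component`, `pi`, `mu`, `sigma`,
#'   `variance`.
#' @method tidy omihet_gmm
#' @export
tidy.omihet_gmm <- function(x, ...) {
  tibble::tibble(component = seq_len(x$g), pi = x$pi, mu = x$mu,
                 sigma = sqrt(x$V), variance = x$V)
}

#' One-row model summary of a fitted Gaussian mixture
#'
#' @param x An `omihet_gmm`.
#' @param ... Unused.
#' @return One-row tibble: `g`, `log_likelihood`, `aic`, `n_cells`,
#'   `wh_index`.
#' @method glance omihet_gmm
#' @export
glance.omihet_gmm <- function(x, ...) {
  tibble::tibble(g = x$g, log_likelihood = x$log_likelihood, aic = x$aic,
                 n_cells = x$n_cells, wh_index = wh_index(x))
}
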