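#' Construct a TCSPC decay stack
#'
#' A decay stack holds the per-pixel photon-arrival histograms of one
#' fluorescence channel: a 3-D array of non-negative counts indexed by
#' (row, column, time bin), the width of a time bin in nanoseconds, the
#' channel identity, and the instrument response function (IRF) sampled on
#' the same time grid.
#'
#' @param counts 3-D numeric array of non-negative photon counts with
#'   dimensions (rows, columns, time bins).
#' @param bin_width Width of one time bin in nanoseconds.
#' @param channel Channel name, `"NADPH"` or `"FAD"`.
#' @param irf Numeric vector of length `dim(counts)[3]` summing to 1; the
#'   discretized instrument response function.
#' @return An object of class `decay_stack`.
#' @examples
#' irf <- generate_irf(fwhm = 0.25, n_bins = 64, bin_width = 0.05)
#' st <- decay_stack(array(1, c(4, 4, 64)), bin_width = 0.05,
#'                   channel = "NADPH", irf = irf)
#' dim(st$counts)
#' @export
decay_stack <- function(counts, bin_width, channel = c("NADPH", "FAD"), irf) {
  channel <- match.arg(channel)
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    abort("`counts` must be a 3-D array (row, column, time bin).",
          class = "omihet_invalid_parameter")
  }
  if (any(counts < 0)) {
    abort("`counts` must be non-negative.", class = "omihet_invalid_parameter")
  }
  check_positive(bin_width, "bin_width")
  n_bins <- dim(counts)[3]
  if (length(irf) != n_bins) {
    abort("`irf` length must equal the number of time bins.",
          class = "omihet_invalid_parameter")
  }
  if (abs(sum(irf) - 1) > 1e-9) {
    abort("`irf` must sum to 1.", class = "omihet_invalid_parameter")
  }
  structure(
    list(counts = counts, bin_width = bin_width, n_time_bins = n_bins,
         channel = channel, irf = as.numeric(irf)),
    class = "decay_stack"
  )
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_stack> %s: %d x %d pixels, %d time bins of %.4g ns (%.4g ns window)\n",
              x$channel, d[1], d[2], d[3], x$bin_width, d[3] * x$bin_width))
  cat(sprintf("  total photons: %.4g, max pixel: %.4g\n",
              sum(x$counts), max(apply(x$counts, c(1, 2), sum))))
  invisible(x)
}

#' Write / read a decay stack as multi-page TIFF plus JSON sidecar
#'
#' The stack is stored as one 16-bit unsigned TIFF page per time bin, with a
#' JSON sidecar (`<path>.json`) carrying the bin width, channel name and IRF
#' vector needed to reconstruct the object.
#'
#' @param stack A [decay_stack()].
#' @param path Output TIFF path; the sidecar is written at `paste0(path, ".json")`.
#' @return `write_decay_stack()` returns `path` invisibly; `read_decay_stack()`
#'   returns a [decay_stack()].
#' @export
write_decay_stack <- function(stack, path) {
  stopifnot(inherits(stack, "decay_stack"))
  d <- dim(stack$counts)
  if (max(stack$counts) > 65535) {
    abort("counts exceed 16-bit TIFF range", class = "omihet_invalid_parameter")
  }
  pages <- lapply(seq_len(d[3]), function(k) stack$counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(bin_width_ns = stack$bin_width, channel = stack$channel,
                  n_time_bins = d[3], irf = stack$irf)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decay_stack
#' @export
read_decay_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  counts <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- round(pages[[k]] * 65535)
  decay_stack(counts, bin_width = meta$bin_width_ns, channel = meta$channel,
              irf = meta$irf)
}

#' Write / read a 16-bit label mask TIFF (0 = background)
#' @param mask Integer matrix of region labels.
#' @param path TIFF path.
#' @return `write_label_mask()` returns `path` invisibly; `read_label_mask()`
#'   an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}
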