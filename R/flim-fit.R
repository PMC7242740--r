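#' Spatially bin decay histograms
#'
#' TCSPC images are photon-starved per pixel, so per-pixel decays are summed
#' over a square window before fitting: with the default `radius = 1` each
#' pixel's histogram becomes the sum over itself and its 8 neighbours.
#' Windows are truncated at the image border; `radius = 0` is the identity.
#'
#' @param stack A [decay_stack()].
#' @param radius Window half-width in pixels (window is `(2 * radius + 1)^2`).
#' @return A [decay_stack()] with binned counts.
#' @export
bin_decays <- function(stack, radius = 1) {
  stopifnot(inherits(stack, "decay_stack"))
  if (radius < 0) abort("`radius` must be >= 0.", class = "omihet_invalid_parameter")
  radius <- as.integer(radius)
  if (radius == 0L) return(stack)
  d <- dim(stack$counts)
  out <- array(0, d)
  for (dy in -radius:radius) {
    rs <- max(1, 1 - dy):min(d[1], d[1] - dy)  # destination rows
    for (dx in -radius:radius) {
      cs <- max(1, 1 - dx):min(d[2], d[2] - dx)
      out[rs, cs, ] <- out[rs, cs, ] + stack$counts[rs + dy, cs + dx, , drop = FALSE]
    }
  }
  storage.mode(out) <- storage.mode(stack$counts)  # window sums of ints are ints
  decay_stack(out, stack$bin_width, stack$channel, stack$irf)
}

#' Fitting options for per-pixel decay analysis
#'
#' Defaults follow common TCSPC practice for NAD(P)H and FAD autofluorescence:
#' Neyman-weighted least squares, literature-typical lifetime initial values,
#' box bounds that keep the two components identifiable, and a minimum photon
#' threshold below which two-exponential fits are ill-conditioned.
#'
#' @param min_photons Minimum total photons in a (binned) pixel for fitting.
#' @param tau_init Initial `(tau1, tau2)` in ns; defaults depend on channel:
#'   (0.3, 2.5) for NAD(P)H, (0.3, 2.0) for FAD.
#' @param alpha1_init Initial short-component fraction.
#' @param tau1_bounds,tau2_bounds Box bounds on the lifetimes, ns.
#' @param max_restarts Deterministic multi-start perturbations tried when the
#'   optimizer fails to converge.
#' @param maxit Maximum Levenberg-Marquardt iterations.
#' @param ftol Relative reduction tolerance on the weighted loss.
#' @return A `fit_options` list.
#' @export
fit_options <- function(min_photons = 500, tau_init = NULL, alpha1_init = 0.7,
                        tau1_bounds = c(0.05, 1.5), tau2_bounds = c(0.8, 10),
                        max_restarts = 3, maxit = 500, ftol = 1e-8) {
  structure(list(min_photons = min_photons, tau_init = tau_init,
                 alpha1_init = alpha1_init, tau1_bounds = tau1_bounds,
                 tau2_bounds = tau2_bounds, max_restarts = max_restarts,
                 maxit = maxit, ftol = ftol),
            class = "fit_options")
}

default_tau_init <- function(channel) {
  if (identical(channel, "FAD")) c(0.3, 2.0) else c(0.3, 2.5)
}

# model curve: A * [IRF (*) (f1 e^{-t/tau1} + (1-f1) e^{-t/tau2})] + C
decay_model <- function(p, t, irf) {
  shape <- p[["f1"]] * exp(-t / p[["tau1"]]) +
    (1 - p[["f1"]]) * exp(-t / p[["tau2"]])
  p[["A"]] * convolve_irf(irf, shape) + p[["C"]]
}

#' Fit a two-exponential decay to one pixel's histogram
#'
#' Minimizes the Neyman-weighted residual (weights `1 / max(count, 1)`)
#' between the measured histogram and the IRF-re-convolved two-exponential
#' model with constant background, by bounded Levenberg-Marquardt. The
#' returned components are ordered `tau1 < tau2` (post-fit swap) and
#' amplitudes are reported as fractions of their sum.
#'
#' @param decay Photon-count histogram.
#' @param irf Unit-sum IRF on the same grid.
#' @param bin_width Bin width, ns.
#' @param options A [fit_options()].
#' @param channel Channel name used only to pick default initial lifetimes.
#' @return One-row tibble with `alpha1_frac`, `alpha2_frac`, `tau1`, `tau2`,
#'   `background_c`, `tau_m`, `chi2_reduced`, `valid`, `note`. Pixels below
#'   the photon threshold or with non-convergent fits come back
#'   `valid = FALSE` with a diagnostic note, never an error.
#' @export
fit_pixel_decay <- function(decay, irf, bin_width, options = fit_options(),
                            channel = "NADPH") {
  n <- length(decay)
  total <- sum(decay)
  invalid <- function(note) {
    tibble::tibble(alpha1_frac = NA_real_, alpha2_frac = NA_real_,
                   tau1 = NA_real_, tau2 = NA_real_, background_c = NA_real_,
                   tau_m = NA_real_, chi2_reduced = NA_real_,
                   valid = FALSE, note = note)
  }
  if (total < options$min_photons) return(invalid("below_photon_threshold"))

  t <- (seq_len(n) - 1) * bin_width
  w <- 1 / pmax(decay, 1)
  sw <- sqrt(w)
  resid_fn <- function(par) {
    p <- list(tau1 = par[1], tau2 = par[2], f1 = par[3], A = par[4], C = par[5])
    (decay - decay_model(p, t, irf)) * sw
  }
  tinit <- options$tau_init %||% default_tau_init(channel)
  c_init <- mean(tail(decay, 5))
  a_init <- max(total - n * c_init, 1)
  lower <- c(options$tau1_bounds[1], options$tau2_bounds[1], 0, 0, 0)
  upper <- c(options$tau1_bounds[2], options$tau2_bounds[2], 1, Inf, Inf)
  # fixed restart schedule keeps the fit deterministic
  perturb <- list(c(1, 1), c(0.7, 1.3), c(1.4, 0.8), c(0.85, 1.15))

  best <- NULL
  for (r in seq_len(1 + options$max_restarts)) {
    start <- c(tau1 = min(max(tinit[1] * perturb[[r]][1], lower[1]), upper[1]),
               tau2 = min(max(tinit[2] * perturb[[r]][2], lower[2]), upper[2]),
               f1 = options$alpha1_init, A = a_init, C = c_init)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxit, ftol = options$ftol,
                           ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    converged <- fit$info %in% 1:4
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best$converged <- converged
    }
    if (converged) break
  }
  if (is.null(best)) return(invalid("optimizer_failure"))
  if (!isTRUE(best$converged)) return(invalid("non_convergence"))

  p <- best$par
  tau1 <- p[["tau1"]]; tau2 <- p[["tau2"]]; f1 <- p[["f1"]]
  if (tau1 > tau2) {  # enforce short/long ordering
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    f1 <- 1 - f1
  }
  chi2 <- best$deviance / (n - 5)
  tibble::tibble(alpha1_frac = f1, alpha2_frac = 1 - f1, tau1 = tau1,
                 tau2 = tau2, background_c = p[["C"]],
                 tau_m = f1 * tau1 + (1 - f1) * tau2,
                 chi2_reduced = chi2, valid = TRUE, note = "ok")
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' The mean lifetime is the weighted average of the short (free/bound) and
#' long component lifetimes: `tau_m = alpha1 * tau1 + alpha2 * tau2`.
#' All arguments are vectorized.
#'
#' @param alpha1_frac,alpha2_frac Fractional contributions (must sum to 1
#'   within 1e-6).
#' @param tau1,tau2 Component lifetimes, ns (positive).
#' @return Mean lifetime(s), ns.
#' @examples
#' mean_lifetime(0.7, 0.3, 0.3, 2.5)  # 0.96
#' @export
mean_lifetime <- function(alpha1_frac, tau1, alpha2_frac, tau2) {
  if (any(abs(alpha1_frac + alpha2_frac - 1) > 1e-6)) {
    abort("`alpha1_frac + alpha2_frac` must equal 1 (tolerance 1e-6).",
          class = "omihet_invalid_parameter")
  }
  if (any(tau1 <= 0) || any(tau2 <= 0)) {
    abort("lifetimes must be positive.", class = "omihet_invalid_parameter")
  }
  alpha1_frac * tau1 + alpha2_frac * tau2
}

#' Integrate photon counts into an intensity image
#'
#' @param stack A [decay_stack()].
#' @param background_c Background counts per bin to subtract, a scalar or a
#'   per-pixel matrix (default 0). Result is floored at 0.
#' @return Numeric matrix of per-pixel total photons.
#' @export
integrate_intensity <- function(stack, background_c = 0) {
  stopifnot(inherits(stack, "decay_stack"))
  total <- apply(stack$counts, c(1, 2), sum)
  pmax(total - stack$n_time_bins * background_c, 0)
}

#' Per-pixel optical redox ratio image
#'
#' Elementwise NAD(P)H intensity divided by FAD intensity. Pixels whose FAD
#' intensity falls below `fad_floor` are returned as `NA` (invalid) rather
#' than infinite.
#'
#' @param nadph_intensity,fad_intensity Intensity matrices of equal shape.
#' @param fad_floor Minimum FAD photons for a valid ratio (default 1).
#' @return Matrix of ratios with `NA` at invalid pixels.
#' @export
redox_ratio_image <- function(nadph_intensity, fad_intensity, fad_floor = 1) {
  if (!identical(dim(nadph_intensity), dim(fad_intensity))) {
    abort("intensity images must share a shape.", class = "omihet_invalid_input")
  }
  out <- nadph_intensity / fad_intensity
  out[fad_intensity < fad_floor] <- NA_real_
  out
}

#' Fit lifetimes for every pixel of a decay stack
#'
#' Applies spatial binning then [fit_pixel_decay()] to each pixel, returning
#' a tidy per-pixel table (one row per pixel) with fit parameters, the mean
#' lifetime, the *unbinned* integrated intensity, and a validity flag.
#'
#' @param stack A [decay_stack()].
#' @param bin_radius Spatial binning radius passed to [bin_decays()]
#'   (default 1, the 3x3 window).
#' @param options A [fit_options()].
#' @return Tibble with columns `row`, `col`, the [fit_pixel_decay()] outputs,
#'   and `intensity`; attribute `"image_dim"` carries the image shape and
#'   `"channel"` the channel.
#' @export
fit_lifetime_image <- function(stack, bin_radius = 1, options = fit_options()) {
  stopifnot(inherits(stack, "decay_stack"))
  binned <- bin_decays(stack, bin_radius)
  d <- dim(stack$counts)
  intensity <- integrate_intensity(stack)
  totals <- apply(binned$counts, c(1, 2), sum)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    r <- grid$row[i]; cc <- grid$col[i]
    if (totals[r, cc] < options$min_photons) {
      return(tibble::tibble(alpha1_frac = NA_real_, alpha2_frac = NA_real_,
                            tau1 = NA_real_, tau2 = NA_real_,
                            background_c = NA_real_, tau_m = NA_real_,
                            chi2_reduced = NA_real_, valid = FALSE,
                            note = "below_photon_threshold"))
    }
    fit_pixel_decay(binned$counts[r, cc, ], binned$irf, binned$bin_width,
                    options, channel = binned$channel)
  })
  out <- dplyr::bind_cols(tibble::as_tibble(grid), res)
  out$intensity <- intensity[cbind(out$row, out$col)]
  attr(out, "image_dim") <- d[1:2]
  attr(out, "channel") <- stack$channel
  out
}
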