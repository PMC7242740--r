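#' Generate a discretized Gaussian instrument response function
#'
#' TCSPC instruments broaden the true fluorescence decay by their instrument
#' response function (IRF). For simulation and fitting we model the IRF as a
#' Gaussian pulse sampled on the acquisition time grid, normalized to unit sum,
#' with its peak placed a configurable fraction into the time window.
#'
#' @param fwhm Full width at half maximum of the pulse, nanoseconds.
#' @param n_bins Number of time bins (>= 16).
#' @param bin_width Width of one bin, nanoseconds.
#' @param peak_frac Location of the pulse peak as a fraction of the full
#'   window (default 0.1).
#' @return Numeric vector of length `n_bins` summing to 1.
#' @examples
#' irf <- generate_irf(0.25, n_bins = 256, bin_width = 0.048)
#' sum(irf)
#' @export
generate_irf <- function(fwhm, n_bins = 256, bin_width = 0.048, peak_frac = 0.1) {
  check_positive(fwhm, "fwhm")
  check_positive(bin_width, "bin_width")
  if (n_bins < 16) abort("`n_bins` must be >= 16.", class = "omihet_invalid_parameter")
  t <- (seq_len(n_bins) - 1) * bin_width
  center <- peak_frac * n_bins * bin_width
  if (fwhm < bin_width / 10) {
    # delta-function limit: a pulse narrower than the grid is a single spike
    k <- numeric(n_bins)
    k[round(center / bin_width) + 1L] <- 1
    return(k)
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  k <- dnorm(t, mean = center, sd = sigma)
  k / sum(k)
}

# Causal discrete convolution of a kernel with a signal on the same grid,
# truncated to the signal length (photons scattered past the window are lost).
convolve_irf <- function(kernel, x) {
  n <- length(x)
  convolve(x, rev(kernel), type = "open")[seq_len(n)]
}

#' Simulate a TCSPC two-exponential photon-count decay
#'
#' Expected counts per bin are the IRF-convolved two-exponential decay
#' `a1 * exp(-t / tau1) + a2 * exp(-t / tau2)` scaled so the decay component
#' carries `total_photons` expected photons, plus a flat background. Observed
#' counts are Poisson draws; with `noise = FALSE` the expectation is returned
#' exactly.
#'
#' @param tau1,tau2 Short and long lifetime components, nanoseconds
#'   (`tau1 < tau2`).
#' @param alpha1_frac Fractional contribution of the short component, in
#'   \[0, 1\].
#' @param total_photons Expected number of decay photons in the histogram.
#' @param background_rate Expected background counts per bin.
#' @param irf Unit-sum IRF vector (see [generate_irf()]); its length sets the
#'   number of bins.
#' @param bin_width Bin width, nanoseconds.
#' @param noise Draw Poisson counts (`TRUE`) or return the expectation.
#' @param seed Optional seed for the Poisson draw.
#' @return Numeric vector of counts, length `length(irf)`.
#' @examples
#' irf <- generate_irf(0.25, 128, 0.1)
#' y <- simulate_decay(0.4, 2.5, 0.75, 5000, irf = irf, bin_width = 0.1,
#'                     noise = FALSE)
#' @export
simulate_decay <- function(tau1, tau2, alpha1_frac, total_photons,
                           background_rate = 0, irf, bin_width,
                           noise = TRUE, seed = NULL) {
  check_positive(tau1, "tau1")
  check_positive(tau2, "tau2")
  if (tau1 >= tau2) {
    abort("`tau1` must be strictly less than `tau2`.",
          class = "omihet_invalid_parameter")
  }
  check_fraction(alpha1_frac, "alpha1_frac")
  if (total_photons < 0) {
    abort("`total_photons` must be non-negative.",
          class = "omihet_invalid_parameter")
  }
  if (background_rate < 0) {
    abort("`background_rate` must be non-negative.",
          class = "omihet_invalid_parameter")
  }
  n <- length(irf)
  t <- (seq_len(n) - 1) * bin_width
  shape <- alpha1_frac * exp(-t / tau1) + (1 - alpha1_frac) * exp(-t / tau2)
  if (total_photons > 0) {
    shape <- shape * (total_photons / sum(shape))
  } else {
    shape <- shape * 0
  }
  expected <- convolve_irf(irf, shape) + background_rate
  expected <- pmax(expected, 0)
  if (!noise) return(expected)
  local_seed(seed, rpois(n, expected))
}

#' Cell geometry and ground truth for FLIM simulation
#'
#' Describes one simulated cell as a disc (solid) or annulus (hollow, with a
#' background-only lumen) together with per-channel generating lifetime
#' parameters and a per-pixel photon budget.
#'
#' @param center_x,center_y Cell center, pixels (1-based).
#' @param radius Outer radius, pixels.
#' @param hollow Is the cell a hollow sphere cross-section (lumen inside)?
#' @param lumen_radius Lumen radius for hollow cells (default half the outer
#'   radius).
#' @param nadph,fad Named lists with `tau1`, `tau2`, `alpha1_frac`,
#'   `total_photons` (per pixel) for each channel.
#' @return A `cell_geometry` list.
#' @export
cell_geometry <- function(center_x, center_y, radius, hollow = FALSE,
                          lumen_radius = radius / 2,
                          nadph = list(tau1 = 0.4, tau2 = 2.5,
                                       alpha1_frac = 0.75, total_photons = 555),
                          fad = list(tau1 = 0.3, tau2 = 2.2,
                                     alpha1_frac = 0.85, total_photons = 400)) {
  check_positive(radius, "radius")
  for (ch in list(nadph, fad)) {
    if (ch$tau1 >= ch$tau2) {
      abort("per-channel `tau1` must be < `tau2`.", class = "omihet_invalid_parameter")
    }
    check_fraction(ch$alpha1_frac, "alpha1_frac")
  }
  structure(list(center_x = center_x, center_y = center_y, radius = radius,
                 hollow = hollow, lumen_radius = lumen_radius,
                 nadph = nadph, fad = fad),
            class = "cell_geometry")
}

#' Specification for a simulated FLIM image pair
#'
#' @param image_width,image_height Image size, pixels.
#' @param n_time_bins Number of TCSPC time bins (default 256).
#' @param bin_width Bin width, nanoseconds (default 0.048, a 12.3 ns window).
#' @param irf_fwhm IRF width, nanoseconds.
#' @param irf_peak_frac IRF peak location as fraction of the window.
#' @param background_rate Background counts per bin per pixel.
#' @param cells List of [cell_geometry()] objects; later cells overwrite
#'   earlier ones where they overlap.
#' @param seed Seed driving all Poisson noise in the stack.
#' @param noise Draw Poisson noise (default `TRUE`).
#' @return A `flim_sim_spec` list.
#' @export
flim_sim_spec <- function(image_width, image_height, n_time_bins = 256,
                          bin_width = 0.048, irf_fwhm = 0.25,
                          irf_peak_frac = 0.1, background_rate = 0.05,
                          cells = list(), seed = 1, noise = TRUE) {
  check_positive(bin_width, "bin_width")
  check_positive(irf_fwhm, "irf_fwhm")
  if (background_rate < 0) {
    abort("`background_rate` must be non-negative.",
          class = "omihet_invalid_parameter")
  }
  window <- n_time_bins * bin_width
  for (cell in cells) {
    stopifnot(inherits(cell, "cell_geometry"))
    for (ch in list(cell$nadph, cell$fad)) {
      if (window < 3 * ch$tau2) {
        abort("time window must cover at least 3 * tau2.",
              class = "omihet_invalid_parameter")
      }
    }
    if (cell$center_x - cell$radius < 1 || cell$center_x + cell$radius > image_width ||
        cell$center_y - cell$radius < 1 || cell$center_y + cell$radius > image_height) {
      abort("cell geometry does not fit within the image.",
            class = "omihet_invalid_parameter")
    }
  }
  structure(list(image_width = image_width, image_height = image_height,
                 n_time_bins = n_time_bins, bin_width = bin_width,
                 irf_fwhm = irf_fwhm, irf_peak_frac = irf_peak_frac,
                 background_rate = background_rate, cells = cells,
                 seed = seed, noise = noise),
            class = "flim_sim_spec")
}

#' Generate a two-channel FLIM decay stack with ground truth
#'
#' Renders every cell of the spec into NAD(P)H and FAD decay stacks: pixels
#' inside a cell carry that cell's IRF-convolved two-exponential decay model,
#' lumen pixels of hollow cells carry background only, and all pixels receive
#' Poisson noise from the spec's seed. Also returns the ground-truth cytoplasm
#' label mask and a per-cell parameter table including the amplitude-weighted
#' mean lifetime.
#'
#' @param spec A [flim_sim_spec()].
#' @return List with elements `nadph` and `fad` ([decay_stack()]s), `mask`
#'   (integer label matrix, 0 = background), and `truth` (tibble of generating
#'   parameters per cell and channel).
#' @export
generate_flim_stack <- function(spec) {
  stopifnot(inherits(spec, "flim_sim_spec"))
  h <- spec$image_height; w <- spec$image_width; nb <- spec$n_time_bins
  irf <- generate_irf(spec$irf_fwhm, nb, spec$bin_width, spec$irf_peak_frac)
  if (length(spec$cells) == 0) {
    warn("empty cell list: generating a pure-background stack and empty mask.")
  }
  mask <- matrix(0L, h, w)
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)

  # expected-count arrays per channel, filled cell by cell
  make_expected <- function(channel) {
    ex <- array(spec$background_rate, c(h, w, nb))
    for (i in seq_along(spec$cells)) {
      cell <- spec$cells[[i]]
      pars <- cell[[channel]]
      curve <- simulate_decay(pars$tau1, pars$tau2, pars$alpha1_frac,
                              pars$total_photons, background_rate = 0,
                              irf = irf, bin_width = spec$bin_width,
                              noise = FALSE)
      d2 <- (rowg - cell$center_y)^2 + (colg - cell$center_x)^2
      inside <- d2 <= cell$radius^2
      if (cell$hollow) {
        lumen <- d2 <= cell$lumen_radius^2
        shell <- inside & !lumen
      } else {
        lumen <- inside & FALSE
        shell <- inside
      }
      idx <- which(shell)
      for (k in seq_len(nb)) {
        slab <- ex[, , k]
        slab[idx] <- curve[k] + spec$background_rate
        slab[which(lumen)] <- spec$background_rate
        ex[, , k] <- slab
      }
      if (channel == "nadph") {
        mask[shell] <<- i
        mask[lumen] <<- 0L
      }
    }
    ex
  }

  ex_n <- make_expected("nadph")
  ex_f <- make_expected("fad")
  if (spec$noise) {
    counts <- local_seed(spec$seed, {
      list(n = array(rpois(length(ex_n), ex_n), dim(ex_n)),
           f = array(rpois(length(ex_f), ex_f), dim(ex_f)))
    })
  } else {
    counts <- list(n = ex_n, f = ex_f)
  }

  truth <- purrr::map_dfr(seq_along(spec$cells), function(i) {
    cell <- spec$cells[[i]]
    purrr::map_dfr(c("nadph", "fad"), function(ch) {
      p <- cell[[ch]]
      tibble::tibble(
        cell_id = i, channel = toupper(sub("nadph", "NADPH", ch)),
        hollow = cell$hollow, tau1 = p$tau1, tau2 = p$tau2,
        alpha1_frac = p$alpha1_frac, total_photons = p$total_photons,
        tau_m = p$alpha1_frac * p$tau1 + (1 - p$alpha1_frac) * p$tau2)
    })
  })

  list(
    nadph = decay_stack(counts$n, spec$bin_width, "NADPH", irf),
    fad = decay_stack(counts$f, spec$bin_width, "FAD", irf),
    mask = mask,
    truth = truth
  )
}

#' Treatment arm of a simulated cohort
#'
#' @param name Treatment name (`"control"` is reserved for untreated cells).
#' @param shift Named numeric vector of per-endpoint mean shifts in units of
#'   the control cell-level standard deviation; names among
#'   `redox_ratio_raw`, `nadph_tau_m`, `fad_tau_m` (missing endpoints shift 0).
#' @param sd_scale Multiplier on the treated cells' cell-level noise SD
#'   (default 1); values below 1 plant a treatment that contracts
#'   heterogeneity, as observed in responding patients.
#' @param mixture Optional list of components, each
#'   `list(proportion =, shift =, sd_multiplier =)`, planting treated-arm
#'   subpopulations; proportions must sum to 1. `shift` is again in control-SD
#'   units and may be a single number (applied to every endpoint) or named.
#' @return A `treatment_effect` list.
#' @export
treatment_effect <- function(name, shift = c(omi = 0), sd_scale = 1,
                             mixture = NULL) {
  if (!is.null(mixture)) {
    props <- vapply(mixture, function(m) m$proportion, numeric(1))
    if (abs(sum(props) - 1) > 1e-9) {
      abort("mixture proportions must sum to 1.", class = "omihet_invalid_parameter")
    }
  }
  check_positive(sd_scale, "sd_scale")
  structure(list(name = name, shift = shift, sd_scale = sd_scale,
                 mixture = mixture),
            class = "treatment_effect")
}

#' Specification for a simulated hierarchical single-cell cohort
#'
#' Emulates the nested structure of organoid imaging data: cells within
#' organoids within patients, with additive Gaussian variance components at
#' each level, plus treatment arms that shift cell means (in control-SD units)
#' or draw cells from planted mixture subpopulations.
#'
#' @param n_patients,organoids_per_patient,cells_per_organoid Cohort sizes.
#' @param patient_means Named vector of grand means for the three raw
#'   endpoints: `redox_ratio_raw` (unitless), `nadph_tau_m` (ns),
#'   `fad_tau_m` (ns).
#' @param var_patient,var_organoid,var_cell Named vectors of variance
#'   components per endpoint (same names as `patient_means`); scalars are
#'   recycled across endpoints.
#' @param treatments List of [treatment_effect()]s (a control arm is always
#'   generated).
#' @param timepoint_h Imaging timepoint in hours (single value; default 72).
#' @param seed Seed driving all draws.
#' @return A `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_patients = 2, organoids_per_patient = 3,
                            cells_per_organoid = 50,
                            patient_means = c(redox_ratio_raw = 1.2,
                                              nadph_tau_m = 0.90,
                                              fad_tau_m = 0.55),
                            var_patient = c(redox_ratio_raw = 0.030,
                                            nadph_tau_m = 0.012,
                                            fad_tau_m = 0.006),
                            var_organoid = c(redox_ratio_raw = 0.012,
                                             nadph_tau_m = 0.005,
                                             fad_tau_m = 0.0025),
                            var_cell = c(redox_ratio_raw = 0.036,
                                         nadph_tau_m = 0.015,
                                         fad_tau_m = 0.0075),
                            treatments = list(), timepoint_h = 72, seed = 1) {
  ep <- names(patient_means)
  expand <- function(v) {
    if (length(v) == 1 && is.null(names(v))) v <- setNames(rep(v, length(ep)), ep)
    if (any(v < 0)) abort("variances must be >= 0.", class = "omihet_invalid_parameter")
    v[ep]
  }
  if (any(patient_means[c("nadph_tau_m", "fad_tau_m")] <= 0)) {
    abort("lifetime means must be positive.", class = "omihet_invalid_parameter")
  }
  for (tr in treatments) stopifnot(inherits(tr, "treatment_effect"))
  structure(list(n_patients = n_patients,
                 organoids_per_patient = organoids_per_patient,
                 cells_per_organoid = cells_per_organoid,
                 patient_means = patient_means,
                 var_patient = expand(var_patient),
                 var_organoid = expand(var_organoid),
                 var_cell = expand(var_cell),
                 treatments = treatments, timepoint_h = timepoint_h,
                 seed = seed, endpoints = ep),
            class = "cohort_sim_spec")
}

#' Generate a hierarchical single-cell endpoint table
#'
#' Draws cells according to the cohort spec: a control cell's endpoint is
#' `patient mean + organoid effect ~ N(0, var_organoid) + cell noise
#' ~ N(0, var_cell)`; treated cells are additionally shifted by
#' `shift * control SD` (with control SD = `sqrt(var_organoid + var_cell)`)
#' or drawn from the treatment's planted mixture. Each treatment arm gets its
#' own organoids, mirroring separately cultured wells. True organoid, patient
#' and mixture-component labels are retained for recovery tests.
#'
#' @param spec A [cohort_sim_spec()].
#' @return Tibble with keys `patient_id`, `organoid_id`, `cell_id`,
#'   `treatment`, `timepoint_h`, the raw endpoint columns, and
#'   `true_component`.
#' @examples
#' cells <- generate_cell_table(cohort_sim_spec(seed = 7))
#' dplyr::count(cells, patient_id, treatment)
#' @export
generate_cell_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  ep <- spec$endpoints
  arms <- c(list(treatment_effect("control")), spec$treatments)
  control_sd <- sqrt(spec$var_organoid + spec$var_cell)

  local_seed(spec$seed, {
    rows <- list()
    for (p in seq_len(spec$n_patients)) {
      pmean <- spec$patient_means +
        rnorm(length(ep), 0, sqrt(spec$var_patient))
      org_counter <- 0L
      for (arm in arms) {
        shift <- setNames(rep(0, length(ep)), ep)
        sh <- arm$shift
        if (!is.null(names(sh))) {
          keep <- intersect(names(sh), ep)
          shift[keep] <- sh[keep]
        } else if (length(sh) == 1) {
          shift[] <- sh
        }
        for (o in seq_len(spec$organoids_per_patient)) {
          org_counter <- org_counter + 1L
          oeff <- rnorm(length(ep), 0, sqrt(spec$var_organoid))
          n <- spec$cells_per_organoid
          if (is.null(arm$mixture)) {
            comp <- rep(1L, n)
            # sd_scale contracts the whole treated spread (organoid and
            # cell level): a homogeneous response pulls all cells toward a
            # common treated phenotype
            vals <- sapply(seq_along(ep), function(e) {
              sc <- arm$sd_scale %||% 1
              pmean[e] + sc * oeff[e] + shift[e] * control_sd[e] +
                rnorm(n, 0, sc * sqrt(spec$var_cell[e]))
            })
          } else {
            props <- vapply(arm$mixture, `[[`, numeric(1), "proportion")
            comp <- sample.int(length(props), n, replace = TRUE, prob = props)
            vals <- sapply(seq_along(ep), function(e) {
              cs <- vapply(arm$mixture, function(m) {
                s <- m$shift
                if (!is.null(names(s))) (if (ep[e] %in% names(s)) s[[ep[e]]] else 0)
                else s[[1]]
              }, numeric(1))
              sdm <- vapply(arm$mixture, function(m) m$sd_multiplier %||% 1,
                            numeric(1))
              pmean[e] + oeff[e] + shift[e] * control_sd[e] +
                cs[comp] * control_sd[e] +
                rnorm(n, 0, sdm[comp] * sqrt(spec$var_cell[e]))
            })
          }
          colnames(vals) <- ep
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(
              patient_id = sprintf("P%02d", p),
              organoid_id = sprintf("P%02d_O%02d", p, org_counter),
              cell_id = seq_len(n),
              treatment = arm$name,
              timepoint_h = spec$timepoint_h,
              true_component = comp),
            tibble::as_tibble(vals))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write / read a cell endpoint table as long-format CSV
#'
#' The on-disk schema is one row per (cell, endpoint):
#' `patient_id,organoid_id,cell_id,treatment,timepoint_h,endpoint,value,true_component`.
#'
#' @param cells Wide cell tibble (endpoint columns).
#' @param path CSV path.
#' @return `write_cell_table()` returns `path` invisibly; `read_cell_table()`
#'   the wide tibble.
#' @export
write_cell_table <- function(cells, path) {
  keys <- intersect(c("patient_id", "organoid_id", "cell_id", "treatment",
                      "timepoint_h", "true_component"), names(cells))
  long <- tidyr::pivot_longer(cells, cols = -dplyr::all_of(keys),
                              names_to = "endpoint", values_to = "value")
  long <- long[, c(setdiff(keys, "true_component"), "endpoint", "value",
                   intersect("true_component", keys))]
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  long <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  tidyr::pivot_wider(long, names_from = "endpoint", values_from = "value")
}
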