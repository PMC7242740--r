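#' Segment cell cytoplasms from an NAD(P)H intensity image
#'
#' Simplified cytoplasm segmentation: Gaussian smoothing, global Otsu
#' threshold, removal of small objects, marker-based watershed splitting of
#' touching cells, and exclusion of interior low-intensity (nuclear or lumen)
#' pixels from each label.
#'
#' @param intensity 2-D non-negative intensity image (matrix).
#' @param smooth_sigma Gaussian smoothing sigma, pixels.
#' @param min_area Minimum object area kept, pixels.
#' @param threshold `"otsu"` or a numeric intensity threshold.
#' @param interior_frac Interior pixels dimmer than this fraction of the
#'   label's median smoothed intensity are excluded (default 0.5).
#' @param watershed_tolerance Minimum water depth between two objects for
#'   the watershed to keep them separate (default 0.5 px of the distance
#'   transform; small enough to split tangent cells).
#' @return Integer label matrix (0 = background). A blank image yields an
#'   empty mask with a warning.
#' @export
segment_cytoplasms <- function(intensity, smooth_sigma = 2, min_area = 50,
                               threshold = "otsu", interior_frac = 0.5,
                               watershed_tolerance = 0.5) {
  if (any(intensity < 0)) {
    abort("`intensity` must be non-negative.", class = "omihet_invalid_input")
  }
  if (max(intensity) == 0) {
    warn("blank intensity image: returning an empty mask.")
    return(matrix(0L, nrow(intensity), ncol(intensity)))
  }
  img <- EBImage::Image(intensity / max(intensity))
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(sm, range = c(0, 1))
  } else {
    threshold / max(intensity)
  }
  bw <- sm > thr
  # split touching cells on the distance transform
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(intensity))

  smm <- matrix(as.numeric(EBImage::imageData(sm)), nrow(intensity))
  keep <- 0L
  out <- matrix(0L, nrow(intensity), ncol(intensity))
  for (l in setdiff(sort(unique(as.vector(labm))), 0L)) {
    px <- labm == l
    if (sum(px) < min_area) next
    med <- median(smm[px])
    px[px & smm < interior_frac * med] <- FALSE  # drop dim interior pixels
    if (sum(px) < min_area) next
    keep <- keep + 1L
    out[px] <- keep
  }
  if (keep == 0L) warn("no objects above `min_area`: empty mask.")
  out
}

#' Extract per-cell endpoint averages from fitted images
#'
#' One row per mask label: each lifetime endpoint is the mean over that
#' label's valid fitted pixels; the raw optical redox ratio is the cell's
#' mean NAD(P)H intensity divided by its mean FAD intensity (ratio of means,
#' robust to dim-pixel noise). Cells with fewer valid pixels than
#' `min_valid_pixels` are dropped, with the dropped count recorded in the
#' `"dropped"` attribute.
#'
#' @param mask Integer label matrix.
#' @param nadph_fit,fad_fit Per-pixel tibbles from [fit_lifetime_image()].
#' @param metadata Named list or one-row data frame of key columns to attach
#'   (e.g. `patient_id`, `organoid_id`, `treatment`, `timepoint_h`,
#'   `morphology`).
#' @param min_valid_pixels Minimum valid fitted pixels per kept cell.
#' @return Tibble of per-cell endpoints keyed by `cell_id` (= mask label).
#' @export
extract_cell_endpoints <- function(mask, nadph_fit, fad_fit,
                                   metadata = list(), min_valid_pixels = 20) {
  dn <- attr(nadph_fit, "image_dim")
  if (!is.null(dn) && !identical(as.integer(dn), as.integer(dim(mask)))) {
    abort("mask and fitted images must share a shape.",
          class = "omihet_invalid_input")
  }
  labels <- setdiff(sort(unique(as.vector(mask))), 0L)
  dropped <- 0L
  rows <- purrr::map_dfr(labels, function(l) {
    idx <- which(mask == l)
    nf <- nadph_fit[match(idx, (nadph_fit$col - 1) * nrow(mask) + nadph_fit$row), ]
    ff <- fad_fit[match(idx, (fad_fit$col - 1) * nrow(mask) + fad_fit$row), ]
    ok <- nf$valid & ff$valid
    if (sum(ok, na.rm = TRUE) < min_valid_pixels) {
      dropped <<- dropped + 1L
      return(NULL)
    }
    nf <- nf[which(ok), ]; ff <- ff[which(ok), ]
    tibble::tibble(
      cell_id = l,
      n_pixels = nrow(nf),
      redox_ratio_raw = mean(nf$intensity) / mean(ff$intensity),
      nadph_tau1 = mean(nf$tau1), nadph_tau2 = mean(nf$tau2),
      nadph_alpha1_frac = mean(nf$alpha1_frac), nadph_tau_m = mean(nf$tau_m),
      fad_tau1 = mean(ff$tau1), fad_tau2 = mean(ff$tau2),
      fad_alpha1_frac = mean(ff$alpha1_frac), fad_tau_m = mean(ff$tau_m))
  })
  if (length(metadata) > 0 && nrow(rows) > 0) {
    rows <- dplyr::bind_cols(tibble::as_tibble(metadata), rows)
  }
  attr(rows, "dropped") <- dropped
  rows
}

#' Normalize redox ratios to stratum control means
#'
#' Adds `redox_ratio_norm = redox_ratio_raw / mean(control redox_ratio_raw)`
#' within each (patient, timepoint) stratum, so control cells average to 1.
#' Strata without control cells are flagged (`norm_flag = "no_control"`) and
#' left unnormalized; if no stratum has controls this is an error.
#'
#' @param cells Cell tibble with `patient_id`, `timepoint_h`, `treatment`,
#'   `redox_ratio_raw`.
#' @param control_label Treatment label marking untreated cells.
#' @return The tibble with `redox_ratio_norm` and `norm_flag` columns.
#' @export
normalize_to_control <- function(cells, control_label = "control") {
  if (!any(cells$treatment == control_label)) {
    abort("no control cells found in any stratum.", class = "omihet_no_control")
  }
  out <- cells |>
    dplyr::group_by(.data$patient_id, .data$timepoint_h) |>
    dplyr::mutate(
      .ctrl = mean(.data$redox_ratio_raw[.data$treatment == control_label]),
      redox_ratio_norm = ifelse(is.nan(.data$.ctrl), NA_real_,
                                .data$redox_ratio_raw / .data$.ctrl),
      norm_flag = ifelse(is.nan(.data$.ctrl), "no_control", "ok")) |>
    dplyr::ungroup() |>
    dplyr::select(-".ctrl")
  if (any(out$norm_flag == "no_control")) {
    warn("some (patient, timepoint) strata lack controls; left unnormalized.")
  }
  out
}

#' Compute the per-cell OMI index
#'
#' The OMI index combines the three metabolic endpoints — optical redox
#' ratio, NAD(P)H mean lifetime, FAD mean lifetime — with coefficients
#' (1, 1, -1), after centering each endpoint around the average value of
#' control cells of the same patient and timepoint. Each endpoint is divided
#' by its stratum control mean and then has 1 subtracted, so the three
#' addends are unitless fractional deviations and control cells average to
#' an OMI index of 0. A decrease relative to control indicates drug
#' response.
#'
#' @inheritParams normalize_to_control
#' @return The tibble with `redox_ratio_norm`, `norm_flag` and `omi_index`
#'   columns added.
#' @examples
#' cells <- generate_cell_table(cohort_sim_spec(seed = 3))
#' cells <- omi_index(cells)
#' mean(cells$omi_index[cells$treatment == "control"])  # 0 by construction
#' @export
omi_index <- function(cells, control_label = "control") {
  cells <- normalize_to_control(cells, control_label)
  cells |>
    dplyr::group_by(.data$patient_id, .data$timepoint_h) |>
    dplyr::mutate(
      .rr = mean(.data$redox_ratio_raw[.data$treatment == control_label]),
      .nt = mean(.data$nadph_tau_m[.data$treatment == control_label]),
      .ft = mean(.data$fad_tau_m[.data$treatment == control_label]),
      omi_index = ifelse(
        is.nan(.data$.rr), NA_real_,
        (.data$redox_ratio_raw / .data$.rr - 1) +
          (.data$nadph_tau_m / .data$.nt - 1) -
          (.data$fad_tau_m / .data$.ft - 1))) |>
    dplyr::ungroup() |>
    dplyr::select(-".rr", -".nt", -".ft")
}
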