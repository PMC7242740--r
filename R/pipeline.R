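#' Pipeline configuration
#'
#' Flat, serializable configuration for the end-to-end pipeline: simulated
#' cohort sizes, imaging/fit options, heterogeneity options and response
#' options. All values are plain scalars so a config round-trips through the
#' key-value text format of [write_config()].
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_patients,organoids_per_patient,cells_per_organoid Cohort sizes
#'   for the simulated endpoint table.
#' @param image_size Simulated FLIM image side length, pixels.
#' @param n_time_bins,bin_width,irf_fwhm TCSPC grid and IRF width.
#' @param cells_per_image Simulated cells per FLIM image.
#' @param photons_per_pixel NAD(P)H photon budget per pixel (FAD uses 72%).
#' @param background_rate Background counts per bin.
#' @param bin_radius Spatial binning radius for fitting.
#' @param min_photons Fit photon threshold.
#' @param min_valid_pixels Minimum valid pixels per kept cell.
#' @param smooth_sigma,min_area Segmentation options.
#' @param het_n_bins Quadratic-entropy bins.
#' @param n_boot Bootstrap resamples for wH uncertainty in reports.
#' @param gmax Largest mixture size considered.
#' @param delta_threshold Responder effect-size cutoff.
#' @param treatment_shift Planted OMI-endpoint shift (control-SD units) of
#'   the simulated treated arm (applied as redox down, NAD(P)H tau_m down,
#'   FAD tau_m up).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "omihet-out", seed = 1,
                            n_patients = 2, organoids_per_patient = 3,
                            cells_per_organoid = 40,
                            image_size = 28, n_time_bins = 256,
                            bin_width = 0.048, irf_fwhm = 0.25,
                            cells_per_image = 3, photons_per_pixel = 555,
                            background_rate = 0.05,
                            bin_radius = 1, min_photons = 500,
                            min_valid_pixels = 10,
                            smooth_sigma = 2, min_area = 20,
                            het_n_bins = 20, n_boot = 0, gmax = 3,
                            delta_threshold = 0.75,
                            treatment_shift = 1.0) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline config as flat key-value text
#'
#' @param config A [pipeline_config()].
#' @param path Text file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, as.character(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- pipeline_config()
  for (p in kv) {
    val <- p[2]
    cfg[[p[1]]] <- if (p[1] == "out_dir") val else as.numeric(val)
  }
  cfg$out_dir <- as.character(cfg$out_dir)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  keep <- setdiff(names(config), "out_dir")  # paths don't change the science
  txt <- paste(keep, vapply(config[keep], as.character, character(1)),
               collapse = ";")
  # small deterministic rolling hash; enough to fingerprint a config in logs
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_stage_csv <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(sprintf("# omihet config_hash=%s seed=%s", config_hash(config),
                     as.character(config$seed)), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a pipeline stage CSV (skipping the metadata header)
#' @param path CSV written by [run_pipeline()].
#' @return Tibble.
#' @export
read_stage_csv <- function(path) {
  tibble::as_tibble(read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE))
}

pipeline_log <- function(stage, msg) {
  inform(sprintf("[omihet:%s] %s", stage, msg))
}

stage_fail <- function(stage, input, parent) {
  abort(sprintf("pipeline stage '%s' failed on input '%s'.", stage, input),
        class = "omihet_stage_failure", parent = parent)
}

# Build the per-organoid image spec used by the simulate stage.
organoid_image_spec <- function(config, shift_frac, organoid_seed) {
  s <- config$image_size
  n_cells <- config$cells_per_image
  # quadrant layout with 1-px jitter: keeps cells disjoint so the watershed
  # recovers one label per cell
  anchors <- list(c(0.28, 0.28), c(0.72, 0.28), c(0.28, 0.72), c(0.72, 0.72))
  centers <- local_seed(organoid_seed, {
    r <- max(4, floor(s / 8))
    lapply(seq_len(min(n_cells, 4L)), function(i) {
      list(x = round(anchors[[i]][1] * s) + sample(-1:1, 1),
           y = round(anchors[[i]][2] * s) + sample(-1:1, 1),
           r = r, hollow = i %% 3 == 0)
    })
  })
  # a responding treatment lowers NAD(P)H tau_m (alpha1 up) and the redox
  # ratio (FAD intensity up) and raises FAD tau_m (FAD alpha1 down)
  cells <- lapply(centers, function(ct) {
    cell_geometry(
      ct$x, ct$y, ct$r, hollow = ct$hollow,
      nadph = list(tau1 = 0.4, tau2 = 2.5,
                   alpha1_frac = min(max(0.75 + 0.5 * shift_frac, 0), 1),
                   total_photons = config$photons_per_pixel),
      fad = list(tau1 = 0.3, tau2 = 2.2,
                 alpha1_frac = min(max(0.85 - 0.25 * shift_frac, 0), 1),
                 total_photons = round(config$photons_per_pixel * 0.72 *
                                         (1 + 0.5 * shift_frac))))
  })
  flim_sim_spec(s, s, config$n_time_bins, config$bin_width, config$irf_fwhm,
                background_rate = config$background_rate, cells = cells,
                seed = organoid_seed)
}

#' Run the end-to-end organoid OMI pipeline
#'
#' Orchestrates simulate -> fit -> segment -> quantify -> heterogeneity ->
#' respond on a simulated cohort: FLIM stacks are generated per organoid
#' (treated arms carry a planted metabolic shift), fitted pixel-by-pixel,
#' segmented from NAD(P)H intensity, reduced to per-cell endpoints,
#' normalized, combined into the OMI index, profiled for heterogeneity, and
#' summarized into a response report with responder calls. Every stage
#' writes a CSV (with a config-hash/seed metadata header) under
#' `config$out_dir` and logs its counts; any stage failure aborts with the
#' stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-cell table (`cells`), the
#'   heterogeneity profiles (`profiles`), the response report (`report`),
#'   and the output paths (`paths`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  arms <- c("control", "treatment_A")
  paths <- list()

  # simulate + fit + segment + quantify, organoid by organoid
  all_cells <- list()
  fit_opts <- fit_options(min_photons = config$min_photons)
  n_fit_pixels <- 0L; n_dropped <- 0L
  for (p in seq_len(config$n_patients)) {
    for (arm_i in seq_along(arms)) {
      shift_frac <- if (arms[arm_i] == "control") 0 else
        0.1 * config$treatment_shift
      for (o in seq_len(config$organoids_per_patient)) {
        oseed <- derive_seed(config$seed, p * 1000 + arm_i * 100 + o)
        spec <- organoid_image_spec(config, shift_frac, oseed)
        sim <- tryCatch(generate_flim_stack(spec),
                        error = function(e) stage_fail("simulate",
                                                       sprintf("P%02d/%s/O%d", p, arms[arm_i], o), e))
        fits <- tryCatch(list(
          n = fit_lifetime_image(sim$nadph, config$bin_radius, fit_opts),
          f = fit_lifetime_image(sim$fad, config$bin_radius, fit_opts)),
          error = function(e) stage_fail("fit",
                                         sprintf("P%02d/%s/O%d", p, arms[arm_i], o), e))
        n_fit_pixels <- n_fit_pixels + sum(fits$n$valid)
        nad_int <- integrate_intensity(bin_decays(sim$nadph, config$bin_radius))
        mask <- tryCatch(
          suppressWarnings(segment_cytoplasms(nad_int,
                                              smooth_sigma = config$smooth_sigma,
                                              min_area = config$min_area)),
          error = function(e) stage_fail("segment",
                                         sprintf("P%02d/%s/O%d", p, arms[arm_i], o), e))
        meta <- list(patient_id = sprintf("P%02d", p),
                     organoid_id = sprintf("P%02d_O%02d_%s", p, o, arms[arm_i]),
                     treatment = arms[arm_i], timepoint_h = 72)
        cells <- tryCatch(
          extract_cell_endpoints(mask, fits$n, fits$f, metadata = meta,
                                 min_valid_pixels = config$min_valid_pixels),
          error = function(e) stage_fail("quantify",
                                         sprintf("P%02d/%s/O%d", p, arms[arm_i], o), e))
        n_dropped <- n_dropped + (attr(cells, "dropped") %||% 0L)
        all_cells[[length(all_cells) + 1L]] <- cells
      }
    }
  }
  cells <- dplyr::bind_rows(all_cells)
  pipeline_log("fit", sprintf("%d pixels fit across %d images", n_fit_pixels,
                              length(all_cells)))
  pipeline_log("quantify", sprintf("%d cells kept, %d dropped", nrow(cells),
                                   n_dropped))
  if (nrow(cells) == 0) {
    stage_fail("quantify", "all images", simpleError("no cells recovered"))
  }
  cells <- tryCatch(omi_index(cells),
                    error = function(e) stage_fail("quantify",
                                                   "control normalization", e))
  paths$cells <- write_stage_csv(cells, file.path(config$out_dir, "cells.csv"),
                                 config)

  # heterogeneity per (patient, treatment)
  profiles <- cells |>
    dplyr::group_by(.data$patient_id, .data$treatment, .data$timepoint_h) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 8) return(tibble::tibble())
      heterogeneity_profile(d, value = "omi_index",
                            seed = derive_seed(config$seed,
                                               sum(utf8ToInt(paste(key[1, ],
                                                                   collapse = "_")))),
                            n_bins = config$het_n_bins) |>
        dplyr::select(-"model")
    }) |>
    dplyr::ungroup()
  pipeline_log("heterogeneity", sprintf("%d group profiles", nrow(profiles)))
  paths$profiles <- write_stage_csv(profiles,
                                    file.path(config$out_dir, "heterogeneity.csv"),
                                    config)

  # response report
  report <- tryCatch(
    response_report(cells, endpoints = c("omi_index", "redox_ratio_norm",
                                         "nadph_tau_m", "fad_tau_m"),
                    threshold = config$delta_threshold,
                    seed = config$seed, n_boot = config$n_boot),
    error = function(e) stage_fail("respond", "cell table", e))
  pipeline_log("respond", sprintf("%d report rows; classifications: %s",
                                  nrow(report),
                                  paste(unique(report$classification),
                                        collapse = ", ")))
  paths$report <- write_stage_csv(report,
                                  file.path(config$out_dir, "response.csv"),
                                  config)

  # figure CSV twins
  paths$heatmap <- write_stage_csv(delta_heatmap_data(report,
                                                      threshold = config$delta_threshold),
                                   file.path(config$out_dir, "heatmap.csv"),
                                   config)
  invisible(list(cells = cells, profiles = profiles, report = report,
                 paths = paths))
}
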