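# Shared fixture builders: everything is generated in code at test time.

# a small TCSPC grid that keeps per-test fits fast
quick_irf <- function(n_bins = 128, bin_width = 0.096, fwhm = 0.25) {
  generate_irf(fwhm, n_bins, bin_width)
}

quick_stack <- function(seed = 1, size = 32, cells = NULL, noise = TRUE,
                        background_rate = 0.05) {
  cells <- cells %||% list(
    cell_geometry(9, 9, 5),
    cell_geometry(23, 23, 5))
  spec <- flim_sim_spec(size, size, n_time_bins = 128, bin_width = 0.096,
                        cells = cells, seed = seed, noise = noise,
                        background_rate = background_rate)
  generate_flim_stack(spec)
}

# cohort with one responding and one non-responding arm
quick_cohort <- function(seed = 1, cells_per_organoid = 60) {
  spec <- cohort_sim_spec(
    n_patients = 2, organoids_per_patient = 3,
    cells_per_organoid = cells_per_organoid,
    treatments = list(
      treatment_effect("strong_drug",
                       shift = c(redox_ratio_raw = -0.8, nadph_tau_m = -0.8,
                                 fad_tau_m = 0.6),
                       sd_scale = 0.7),
      treatment_effect("weak_drug",
                       shift = c(redox_ratio_raw = -0.05, nadph_tau_m = -0.05,
                                 fad_tau_m = 0.05))),
    seed = seed)
  generate_cell_table(spec)
}

`%||%` <- rlang::`%||%`
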