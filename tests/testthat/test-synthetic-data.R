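test_that("generated IRF is unit-sum, correctly located and correctly wide", {
  irf <- generate_irf(0.2, 256, 0.039)
  expect_equal(sum(irf), 1, tolerance = 1e-12)
  # measured FWHM on the grid matches the requested width within one bin
  half <- max(irf) / 2
  measured <- sum(irf >= half) * 0.039
  expect_lt(abs(measured - 0.2), 0.039 + 1e-12)
  # delta-function limit collapses to a single spike at the offset bin
  spike <- generate_irf(1e-6, 64, 0.05, peak_frac = 0.25)
  expect_equal(sum(spike == 1), 1)
  expect_equal(which(spike == 1), 0.25 * 64 + 1)
  expect_error(generate_irf(-1, 64, 0.05), class = "omihet_invalid_parameter")
})

test_that("noise-free decays follow the two-exponential model exactly", {
  n <- 128; bw <- 0.096
  spike <- generate_irf(1e-9, n, bw, peak_frac = 0)
  # mono-exponential: log of the tail is linear with slope -bw / tau1
  y <- simulate_decay(0.8, 2.5, 1, 1e4, irf = spike, bin_width = bw,
                      noise = FALSE)
  tail_idx <- 10:60
  slopes <- diff(log(y[tail_idx]))
  expect_equal(slopes, rep(-bw / 0.8, length(slopes)), tolerance = 1e-9)
  # generating-parameter mean lifetime is the amplitude-weighted average
  expect_equal(mean_lifetime(0.7, 0.3, 0.3, 2.5), 0.96)
  # photon budget: expected counts sum to total_photons (up to the photons
  # the IRF convolution scatters past the window)
  irf <- quick_irf()
  y2 <- simulate_decay(0.4, 2.5, 0.75, 5000, irf = irf, bin_width = bw,
                       noise = FALSE)
  expect_equal(sum(y2), 5000, tolerance = 0.005)
  expect_error(simulate_decay(2.5, 0.4, 0.5, 100, irf = irf, bin_width = bw),
               class = "omihet_invalid_parameter")
  expect_error(simulate_decay(0.4, 2.5, 0.5, -5, irf = irf, bin_width = bw),
               class = "omihet_invalid_parameter")
})

test_that("Poisson channel reproduces the specified photon budget and variance", {
  irf <- quick_irf()
  sums <- vapply(1:500, function(s) {
    sum(simulate_decay(0.4, 2.5, 0.75, 10000, irf = irf, bin_width = 0.096,
                       seed = s))
  }, numeric(1))
  expected <- sum(simulate_decay(0.4, 2.5, 0.75, 10000, irf = irf,
                                 bin_width = 0.096, noise = FALSE))
  se <- sd(sums) / sqrt(length(sums))
  expect_lt(abs(mean(sums) - expected), 3 * se)

  # per-bin variance ~ per-bin mean for bins with mean >= 5
  reps <- vapply(1:300, function(s) {
    simulate_decay(0.4, 2.5, 0.75, 5000, irf = irf, bin_width = 0.096,
                   seed = 1000 + s)
  }, numeric(128))
  mu <- rowMeans(reps); v <- apply(reps, 1, var)
  keep <- mu >= 5
  ratio <- v[keep] / mu[keep]
  expect_true(all(abs(ratio - 1) < 0.35))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("FLIM stacks carry per-cell decay models, lumens and determinism", {
  # noise off: all pixels of a solid cell are identical
  sim <- quick_stack(noise = FALSE, background_rate = 0,
                     cells = list(cell_geometry(9, 9, 5)))
  px <- which(sim$mask == 1, arr.ind = TRUE)
  first <- sim$nadph$counts[px[1, 1], px[1, 2], ]
  for (i in seq_len(nrow(px))) {
    expect_identical(sim$nadph$counts[px[i, 1], px[i, 2], ], first)
  }
  # hollow cells: lumen photon counts << shell counts
  simh <- quick_stack(seed = 3, cells = list(
    cell_geometry(16, 16, 8, hollow = TRUE, lumen_radius = 4)))
  tot <- apply(simh$nadph$counts, c(1, 2), sum)
  d2 <- outer(1:32, 1:32, function(r, c) (r - 16)^2 + (c - 16)^2)
  lumen_mean <- mean(tot[d2 <= 4^2])
  shell_mean <- mean(tot[d2 > 4^2 & d2 <= 8^2])
  expect_lt(lumen_mean, 0.1 * shell_mean)
  # fixed seed reproduces the stack bit for bit
  s1 <- quick_stack(seed = 9); s2 <- quick_stack(seed = 9)
  expect_identical(s1$nadph$counts, s2$nadph$counts)
  expect_identical(s1$fad$counts, s2$fad$counts)
  expect_identical(s1$mask, s2$mask)
  # ground truth table carries the generating mean lifetime
  expect_equal(sim$truth$tau_m[sim$truth$channel == "NADPH"],
               0.75 * 0.4 + 0.25 * 2.5)
  expect_warning(generate_flim_stack(flim_sim_spec(8, 8, 64, 0.1, cells = list())),
                 "empty cell list")
})

test_that("hierarchical cell tables realize the planted variance structure", {
  # zero-variance collapse: every control cell equals its patient mean
  spec0 <- cohort_sim_spec(n_patients = 2, organoids_per_patient = 3,
                           cells_per_organoid = 10, var_patient = 0,
                           var_organoid = 0, var_cell = 0, seed = 4)
  t0 <- generate_cell_table(spec0)
  for (e in c("redox_ratio_raw", "nadph_tau_m", "fad_tau_m")) {
    expect_equal(unique(t0[[e]]), unname(spec0$patient_means[e]))
  }
  # organoid-level variance fraction is recovered empirically
  spec <- cohort_sim_spec(n_patients = 1, organoids_per_patient = 50,
                          cells_per_organoid = 100, var_patient = 0,
                          var_organoid = 0.3, var_cell = 0.7, seed = 21)
  tab <- generate_cell_table(spec)
  fit <- stats::aov(redox_ratio_raw ~ organoid_id, data = tab)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  var_between <- (ms[1] - ms[2]) / 100
  frac <- var_between / (var_between + ms[2])
  expect_lt(abs(frac - 0.30), 0.05)
  # determinism
  expect_identical(generate_cell_table(spec0), generate_cell_table(spec0))
})

test_that("planted mixtures yield bimodal treated arms with true labels", {
  spec <- cohort_sim_spec(
    n_patients = 1, organoids_per_patient = 4, cells_per_organoid = 250,
    treatments = list(treatment_effect(
      "mix", mixture = list(list(proportion = 0.5, shift = -2, sd_multiplier = 1),
                            list(proportion = 0.5, shift = 2, sd_multiplier = 1)))),
    seed = 8)
  tab <- generate_cell_table(spec)
  trt <- tab[tab$treatment == "mix", ]
  expect_setequal(unique(trt$true_component), c(1L, 2L))
  expect_lt(abs(mean(trt$true_component == 1) - 0.5), 0.05)
  # valley between the modes: the midpoint bin is sparser than the modes
  x <- trt$redox_ratio_raw
  h <- hist(x, breaks = 24, plot = FALSE)$counts
  thirds <- split(h, cut(seq_along(h), 3))
  expect_lt(min(thirds[[2]]), 0.75 * max(thirds[[1]]))
  expect_lt(min(thirds[[2]]), 0.75 * max(thirds[[3]]))
  expect_error(
    treatment_effect("bad", mixture = list(list(proportion = 0.6, shift = 0),
                                           list(proportion = 0.6, shift = 1))),
    class = "omihet_invalid_parameter")
})

test_that("cell tables round-trip through the long CSV schema", {
  tab <- quick_cohort(seed = 2, cells_per_organoid = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(tab, path)
  header <- readLines(path, n = 1)
  expect_identical(
    header,
    "patient_id,organoid_id,cell_id,treatment,timepoint_h,endpoint,value,true_component")
  back <- read_cell_table(path)
  expect_equal(
    dplyr::arrange(back[names(tab)], patient_id, organoid_id, cell_id, treatment),
    dplyr::arrange(tab, patient_id, organoid_id, cell_id, treatment),
    tolerance = 1e-12, ignore_attr = TRUE)
})
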