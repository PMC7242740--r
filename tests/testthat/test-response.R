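test_that("Glass's delta follows the control-SD convention", {
  expect_equal(glass_delta(c(0, 1, 2), c(1, 2, 3)), 1)
  expect_equal(glass_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(glass_delta(c(1, 2), c(2, 2)), class = "omihet_invalid_parameter")
  expect_error(glass_delta(1, c(1, 2)), class = "omihet_too_few_cells")
  # recovery of a planted -0.75 control-SD shift on the OMI index
  set.seed(17)
  deltas <- vapply(1:20, function(s) {
    ctrl <- rnorm(500)
    trt <- rnorm(500, -0.75)
    glass_delta(trt, ctrl)
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 0.75), 0.15)
  # antisymmetry in the planted shift direction
  set.seed(18)
  ctrl <- rnorm(500); up <- rnorm(500, 0.5); down <- rnorm(500, -0.5)
  expect_lt(abs(glass_delta(up, ctrl) + glass_delta(down, ctrl)), 0.2)
})

test_that("Wilcoxon p-values match exact enumeration and large-sample limits", {
  # full enumeration oracle at n = 3 + 3: all C(6,3) = 20 group assignments
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  pooled <- c(a, b)
  w_obs <- sum(rank(pooled)[1:3])
  combs <- utils::combn(6, 3)
  w_all <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  p_oracle <- mean(abs(w_all - 10.5) >= abs(w_obs - 10.5))
  expect_equal(wilcoxon_rank_sum(a, b), p_oracle)  # = 0.1
  expect_equal(wilcoxon_rank_sum(a, b), 0.1)
  # identical samples -> p capped at 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  # exact and normal-approximation paths agree at n = 10 without ties
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  p_exact <- wilcoxon_rank_sum(x, y)
  p_approx <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_approx), 0.01)
  # large planted shift is overwhelmingly significant
  set.seed(6)
  expect_lt(wilcoxon_rank_sum(rnorm(100, 2), rnorm(100)), 1e-6)
  expect_error(wilcoxon_rank_sum(1:2, 1:5), class = "omihet_too_few_cells")
})

test_that("responder classification applies the inclusive cutoff rule", {
  expect_equal(classify_response(1.9, 1.0, 0.9), "predicted_responder")
  expect_equal(classify_response(0.3, 1.0, 1.2), "predicted_non_responder")
  # boundary: delta exactly at 0.75 with contracting heterogeneity responds
  expect_equal(classify_response(0.75, 1.0, 0.99), "predicted_responder")
  # passing effect size but unchanged heterogeneity is indeterminate
  expect_equal(classify_response(1.5, 1.0, 1.0), "indeterminate")
  # expanding heterogeneity vetoes the call regardless of effect size
  expect_equal(classify_response(2.5, 1.0, 1.4), "predicted_non_responder")
  expect_error(classify_response(Inf, 1, 1), class = "omihet_invalid_parameter")
})

test_that("variance partitioning recovers planted fractions", {
  # saturated fit: no within-group noise
  g <- rep(letters[1:5], each = 4)
  v <- rep(1:5, each = 4)
  expect_equal(suppressWarnings(variance_explained(v, g)), 100)
  # null: equal group means, noise only
  set.seed(23)
  expect_lt(abs(variance_explained(rnorm(500), rep(1:50, each = 10))), 5)
  # planted 30% organoid-level fraction at 50 x 100
  spec <- cohort_sim_spec(n_patients = 1, organoids_per_patient = 50,
                          cells_per_organoid = 100, var_patient = 0,
                          var_organoid = 0.3, var_cell = 0.7, seed = 77)
  tab <- generate_cell_table(spec)
  ve <- variance_explained(tab$redox_ratio_raw, tab$organoid_id)
  expect_lt(abs(ve - 30), 5)
  expect_error(variance_explained(1:10, rep("a", 10)),
               class = "omihet_invalid_parameter")
})

test_that("variance_partition reports organoid and patient strata", {
  tab <- quick_cohort(seed = 41, cells_per_organoid = 30)
  vp <- variance_partition(tab)
  expect_setequal(unique(vp$level), c("organoid", "patient"))
  org <- vp[vp$level == "organoid", ]
  expect_equal(nrow(org), 2 * 3)  # 2 patients x 3 endpoints
  expect_true(all(vp$pct_explained <= 100))
  # patient-level separation exceeds the organoid level on average,
  # mirroring the planted variance hierarchy
  pat <- vp[vp$level == "patient", ]
  expect_gt(mean(pat$pct_explained), mean(org$pct_explained))
})

test_that("correlation maps are symmetric with guarded partner counts", {
  set.seed(3)
  x <- rnorm(100)
  d <- tibble::tibble(a = x, b = 2 * x + 1, c = rnorm(100), d = rnorm(100))
  cm <- correlation_map(d)
  expect_equal(cm$r_squared["a", "b"], 1, tolerance = 1e-12)
  expect_equal(cm$r_squared, t(cm$r_squared))
  expect_equal(unname(diag(cm$r_squared)), rep(1, 4))
  expect_equal(unname(cm$n_partners["a"]), 1)
  expect_equal(unname(cm$n_partners["c"]), 0)
  # independent columns: off-diagonal R^2 small
  set.seed(4)
  big <- as.data.frame(matrix(rnorm(1000 * 4), 1000))
  cb <- correlation_map(big)
  off <- cb$r_squared[upper.tri(cb$r_squared)]
  expect_true(all(off < 0.05))
  # constant column reported as missing
  cc <- correlation_map(tibble::tibble(a = rnorm(50), b = rep(1, 50),
                                       c = rnorm(50)))
  expect_true(all(is.na(cc$r_squared["b", c("a", "c")])))
})

test_that("multivariate regression returns adjusted R^2 with rank guard", {
  set.seed(8)
  X <- matrix(rnorm(200 * 3), 200)
  y <- X %*% c(1, -2, 0.5)
  expect_equal(suppressWarnings(multivariate_regression(as.numeric(y), X)), 1,
               tolerance = 1e-9)
  # pure-noise dependent: adjusted R^2 near (possibly below) zero
  r2 <- vapply(1:20, function(s) {
    set.seed(s)
    multivariate_regression(rnorm(200), matrix(rnorm(200 * 5), 200))
  }, numeric(1))
  expect_lt(abs(mean(r2)), 0.05)
  Xc <- cbind(X, X[, 1] + X[, 2])
  colnames(Xc) <- c("a", "b", "c", "d")
  expect_error(multivariate_regression(as.numeric(y), Xc),
               class = "omihet_rank_deficient")
  expect_error(multivariate_regression(rnorm(4), matrix(rnorm(12), 4)),
               class = "omihet_invalid_input")
})

test_that("cohort summaries reproduce integer success rates", {
  expect_equal(cohort_summary(22, 14)$success_rate_pct, 64)
  expect_equal(cohort_summary(24, 13)$success_rate_pct, 54)
  expect_equal(cohort_summary(10, 10)$success_rate_pct, 100)
  both <- cohort_summary(c(22, 24), c(14, 13),
                         group = c("pancreatic", "breast"))
  expect_equal(both$success_rate_pct, c(64, 54, floor(100 * 27 / 46 + 0.5)))
  expect_error(cohort_summary(0, 0), class = "omihet_invalid_parameter")
  expect_error(cohort_summary(5, 6), class = "omihet_invalid_parameter")
})

test_that("response reports combine effect size, p-value and wH change", {
  tab <- omi_index(quick_cohort(seed = 55))
  rep <- response_report(tab, endpoints = c("omi_index", "redox_ratio_norm"),
                         seed = 9)
  expect_setequal(unique(rep$treatment), c("strong_drug", "weak_drug"))
  expect_equal(nrow(rep), 2 * 2 * 2)  # patients x treatments x endpoints
  omi <- rep[rep$endpoint == "omi_index", ]
  strong <- omi[omi$treatment == "strong_drug", ]
  weak <- omi[omi$treatment == "weak_drug", ]
  expect_true(all(strong$glass_delta > weak$glass_delta))
  expect_true(all(strong$responds_flag))
  expect_true(all(strong$classification == "predicted_responder"))
  expect_true(all(weak$classification == "predicted_non_responder"))
  expect_true(all(rep$wilcoxon_p > 0 & rep$wilcoxon_p <= 1))
  # determinism
  rep2 <- response_report(tab, endpoints = c("omi_index", "redox_ratio_norm"),
                          seed = 9)
  expect_identical(rep, rep2)
})
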