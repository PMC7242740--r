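test_that("EM recovers planted mixture parameters and dominates the truth", {
  set.seed(101)
  x <- c(rnorm(500, 0), rnorm(500, 6))
  m <- fit_gmm(x, 2, seed = 1)
  expect_equal(m$g, 2L)
  expect_lt(abs(m$mu[1] - 0), 0.2)
  expect_lt(abs(m$mu[2] - 6), 0.2)
  expect_lt(abs(m$pi[1] - 0.5), 0.05)
  # returned likelihood >= likelihood of the generating parameters
  ll_truth <- sum(log(0.5 * dnorm(x, 0, 1) + 0.5 * dnorm(x, 6, 1)))
  expect_gte(m$log_likelihood, ll_truth - 1e-6)
  # components sorted by mean, proportions sum to 1
  expect_true(all(diff(m$mu) > 0))
  expect_equal(sum(m$pi), 1, tolerance = 1e-9)
})

test_that("point-mass and degenerate inputs collapse to a single component", {
  expect_warning(m <- fit_gmm(rep(3, 20), 1), "degenerate")
  expect_equal(m$mu, 3)
  expect_equal(m$pi, 1)
  expect_warning(ms <- select_model(rep(1.5, 10)), "degenerate")
  expect_equal(ms$g, 1L)
  expect_error(fit_gmm(rnorm(8), 2), class = "omihet_too_few_cells")
})

test_that("the AIC identity holds for every fitted model", {
  set.seed(7)
  for (g in 1:3) {
    x <- c(rnorm(150), rnorm(100, 5), rnorm(80, 10))
    m <- fit_gmm(x, g, seed = g)
    expect_equal(m$aic, 2 * (3 * g - 1) - 2 * m$log_likelihood)
  }
})

test_that("model selection separates unimodal from well-separated bimodal", {
  picks <- vapply(1:20, function(s) {
    set.seed(s)
    c(select_model(rnorm(500), seed = s)$g,
      select_model(c(rnorm(250), rnorm(250, 6)), seed = s)$g)
  }, numeric(2))
  expect_gte(mean(picks[1, ] == 1), 0.9)
  expect_gte(mean(picks[2, ] == 2), 0.9)
})

test_that("EM agrees with an independent mixture implementation", {
  library(mclust)
  set.seed(42)
  x <- c(rnorm(300, 0), rnorm(300, 4, 1.5))
  m <- fit_gmm(x, 2, seed = 3)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(m$log_likelihood - ref$loglik), 0.01 * abs(ref$loglik))
  expect_equal(sort(m$mu), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
})

test_that("the wH-index matches its closed forms and scaling laws", {
  # single component: wH = (1 - ln 2) * sigma
  m1 <- fit_gmm(rnorm(200), 1)
  expect_equal(wh_index(m1), (1 - log(2)) * sqrt(m1$V), tolerance = 1e-12)
  m2 <- omihet:::new_gmm(1L, 1, 0, 4, 0, 100)
  expect_equal(wh_index(m2), (1 - log(2)) * 2, tolerance = 1e-12)
  # symmetric two-component hand oracle: m = 0 by symmetry,
  # wH = 2 * (1 - 0.5 ln 1.5) * (1 + 2)
  msym <- omihet:::new_gmm(2L, c(0.5, 0.5), c(-2, 2), c(1, 1), 0, 100)
  expect_equal(wh_index(msym), 2 * (1 - 0.5 * log(1.5)) * 3,
               tolerance = 1e-9)
  # translation invariance and linear scaling at the model level
  set.seed(3)
  base <- fit_gmm(c(rnorm(200), rnorm(200, 5)), 2, seed = 1)
  shifted <- omihet:::new_gmm(2L, base$pi, base$mu + 7, base$V,
                              base$log_likelihood, base$n_cells)
  scaled <- omihet:::new_gmm(2L, base$pi, 3 * base$mu, 9 * base$V,
                             base$log_likelihood, base$n_cells)
  expect_equal(wh_index(shifted), wh_index(base), tolerance = 1e-9)
  expect_equal(wh_index(scaled), 3 * wh_index(base), tolerance = 1e-9)
})

test_that("quadratic entropy matches hand cases and a brute-force oracle", {
  expect_equal(quadratic_entropy(rep(2, 50)), 0)
  # half the mass in each extreme bin: QE = 2 * 0.25 * d(bin1, bin20)
  x <- c(rep(0, 50), rep(1, 50))
  expect_equal(quadratic_entropy(x, n_bins = 20), 2 * 0.25 * (19 / 20))
  set.seed(9)
  v <- rnorm(400)
  qe <- quadratic_entropy(v, 20)
  # explicit double loop over bins
  breaks <- seq(min(v), max(v), length.out = 21)
  idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1), 20)
  p <- tabulate(idx, 20) / length(v)
  centers <- (breaks[-1] + breaks[-21]) / 2
  acc <- 0
  for (i in 1:20) for (j in 1:20) {
    acc <- acc + p[i] * p[j] * abs(centers[i] - centers[j]) / diff(range(v))
  }
  expect_equal(qe, acc, tolerance = 1e-12)
  expect_gte(qe, 0); expect_lte(qe, 1)
})

test_that("KS distance matches a direct sup-distance oracle", {
  set.seed(4)
  big <- rnorm(5000)
  expect_lt(ks_normality(big), 0.03)
  bimod <- c(rnorm(500, -3, 0.5), rnorm(500, 3, 0.5))
  expect_gt(ks_normality(bimod), 0.1)
  v <- rnorm(200, 2, 3)
  d <- ks_normality(v)
  x <- sort(v); n <- length(v)
  F_ <- pnorm(x, mean(v), sd(v))
  oracle <- max(c(seq_len(n) / n - F_, F_ - (seq_len(n) - 1) / n))
  expect_equal(d, oracle, tolerance = 1e-15)
  expect_warning(expect_equal(ks_normality(rep(1, 10)), 0), "constant")
})

test_that("outlier percentage applies exact Tukey fences", {
  expect_equal(outlier_pct(1:100), 0)
  expect_equal(outlier_pct(c(rep(0, 99), 1000)), 1)
  set.seed(12)
  v <- c(rnorm(200), 8, -9)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  oracle <- 100 * mean(v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr)
  expect_equal(outlier_pct(v), oracle)
})

test_that("all heterogeneity measures hit their degenerate values together", {
  v <- rep(2.5, 40)
  expect_equal(quadratic_entropy(v), 0)
  expect_warning(expect_equal(ks_normality(v), 0), "constant")
  expect_equal(outlier_pct(v), 0)
  expect_warning(m <- select_model(v), "degenerate")
  expect_lt(wh_index(m), 1e-5)
})

test_that("the wH bootstrap is consistent, deterministic and degenerate-safe", {
  set.seed(33)
  x <- rnorm(300)
  b1 <- bootstrap_wh(x, n_boot = 60, seed = 5)
  b2 <- bootstrap_wh(x, n_boot = 60, seed = 5)
  expect_identical(b1, b2)
  expect_lt(abs(b1$boot_mean - b1$point) / b1$point, 0.1)
  expect_true(b1$ci_lower <= b1$boot_mean && b1$boot_mean <= b1$ci_upper)
  suppressWarnings(bc <- bootstrap_wh(rep(1, 30), n_boot = 20, seed = 1))
  expect_equal(bc$boot_sd, 0)
})

test_that("density curves integrate to one and sum over components", {
  set.seed(2)
  m <- fit_gmm(c(rnorm(200), rnorm(200, 5)), 2, seed = 4)
  d <- density_curves(m)
  total <- d[d$component == "total", ]
  dx <- diff(total$x[1:2])
  expect_equal(sum(total$density) * dx, 1, tolerance = 1e-3)
  comps <- tidyr::pivot_wider(d[d$component != "total", ],
                              names_from = "component",
                              values_from = "density")
  expect_equal(comps$`1` + comps$`2`, total$density, tolerance = 1e-12)
  # widening the grid changes the integral negligibly beyond mu +/- 8 sd
  wide <- seq(min(m$mu) - 12 * max(sqrt(m$V)),
              max(m$mu) + 12 * max(sqrt(m$V)), length.out = 4096)
  dwide <- density_curves(m, wide)
  tw <- dwide[dwide$component == "total", ]
  expect_equal(sum(tw$density) * diff(wide[1:2]), 1, tolerance = 1e-6)
  # single-component curve peaks at the mean
  m1 <- fit_gmm(rnorm(100), 1)
  d1 <- density_curves(m1)
  t1 <- d1[d1$component == "total", ]
  expect_lt(abs(t1$x[which.max(t1$density)] - m1$mu), diff(t1$x[1:2]) * 2)
})

test_that("heterogeneity profiles bundle the distribution descriptors", {
  set.seed(6)
  v <- rnorm(200, 5)
  prof <- heterogeneity_profile(tibble::tibble(value = v), seed = 2)
  expect_equal(prof$n, 200)
  expect_equal(prof$g, 1)
  expect_equal(prof$sd, sd(v))
  expect_equal(prof$cv, sd(v) / mean(v))
  expect_equal(prof$qe, quadratic_entropy(v))
  expect_equal(prof$ks, ks_normality(v))
  expect_equal(prof$ol_pct, outlier_pct(v))
  expect_s3_class(prof$model[[1]], "omihet_gmm")
  expect_equal(prof$wh_index, wh_index(prof$model[[1]]))
  # tidy / glance / autoplot round out the model interface
  td <- tidy(prof$model[[1]])
  expect_equal(nrow(td), 1)
  gl <- glance(prof$model[[1]])
  expect_equal(gl$wh_index, prof$wh_index)
  expect_s3_class(ggplot2::autoplot(prof$model[[1]]), "ggplot")
})
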