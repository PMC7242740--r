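#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Fits the g-component mixture `f(y) = sum_i pi_i * phi(y; mu_i, V_i)` to a
#' vector of single-cell values by expectation-maximization, taking the best
#' of several k-means++-style initializations. Component variances are
#' floored at `1e-6` times the sample variance; components are returned
#' sorted by mean. The AIC is `2k - 2 logL` with `k = 3g - 1` free parameters
#' (g means, g variances, g - 1 proportions).
#'
#' @param values Numeric vector of cell values (needs `n >= 5 * g`).
#' @param g Number of components (1-3 in routine use).
#' @param seed Seed for the restarts.
#' @param n_restarts Number of EM initializations (default 10).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations per restart.
#' @return An object of class `omihet_gmm`: list with `g`, `pi`, `mu`, `V`,
#'   `log_likelihood`, `aic`, `n_cells`.
#' @examples
#' x <- c(rnorm(100, 0), rnorm(100, 6))
#' fit_gmm(x, g = 2, seed = 1)
#' @export
fit_gmm <- function(values, g, seed = NULL, n_restarts = 10, tol = 1e-8,
                    max_iter = 1000) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    abort("`values` must be finite.", class = "omihet_invalid_parameter")
  }
  n <- length(values)
  if (n < 5 * g) {
    abort(sprintf("need at least %d values to fit g = %d components.", 5 * g, g),
          class = "omihet_too_few_cells")
  }
  sample_var <- var(values)
  if (!is.finite(sample_var) || sample_var == 0) {
    warn("degenerate (constant) values: returning a single point-mass component.")
    floorv <- 1e-12
    ll <- sum(dnorm(values, values[1], sqrt(floorv), log = TRUE))
    return(new_gmm(1L, 1, values[1], floorv, ll, n))
  }
  vfloor <- 1e-6 * sample_var

  if (g == 1) {
    mu <- mean(values)
    V <- max(sum((values - mu)^2) / n, vfloor)  # MLE variance
    ll <- sum(dnorm(values, mu, sqrt(V), log = TRUE))
    return(new_gmm(1L, 1, mu, V, ll, n))
  }

  run_em <- function(mu0, pi0 = rep(1 / g, g),
                     V0 = rep(max(sample_var / g, vfloor), g), iters = max_iter) {
    em_gmm_1d(values, mu0, pi0, V0, tol, iters, vfloor)
  }

  # k-means++-style seeding: spread initial means by squared distance
  seed_means <- function() {
    mu0 <- numeric(g)
    mu0[1] <- values[sample.int(n, 1)]
    for (i in 2:g) {
      d2 <- vapply(values, function(v) min((v - mu0[1:(i - 1)])^2), numeric(1))
      if (sum(d2) == 0) mu0[i] <- values[sample.int(n, 1)]
      else mu0[i] <- values[sample.int(n, 1, prob = d2)]
    }
    mu0
  }

  # A solution is degenerate when a component collapses onto a likelihood
  # spike (variance pinned at the floor) or describes a "subpopulation" of
  # fewer than max(5, 5% of n) effective cells -- too few to interpret as a
  # metabolic subpopulation and the classic failure mode of 1-D mixture
  # likelihoods. Such solutions are rejected unless nothing else converged.
  # Additionally, a pair of components is only a resolvable pair of
  # subpopulations when Ashman's D = |mu_i - mu_j| / sqrt((V_i + V_j) / 2)
  # reaches 2, the classic bimodality-resolution threshold; solutions
  # below it are an overlapping re-description of one subpopulation.
  # Finally, g interpretable subpopulations must manifest as g distinct
  # modes of the fitted density: solutions that slice one mode into
  # overlapping components are re-descriptions, not subpopulations.
  nk_floor <- max(5, 0.10 * n)
  is_degenerate <- function(fit) {
    if (any(fit$V <= 2 * vfloor) || any(fit$nk < nk_floor)) return(TRUE)
    if (g > 1) {
      s <- sqrt(fit$V)
      for (i in 1:(g - 1)) for (j in (i + 1):g) {
        D <- abs(fit$mu[i] - fit$mu[j]) / sqrt((fit$V[i] + fit$V[j]) / 2)
        if (D < 2) return(TRUE)
      }
      grid <- seq(min(fit$mu - 4 * s), max(fit$mu + 4 * s), length.out = 512)
      dens <- rowSums(vapply(seq_len(g), function(i) {
        fit$pi[i] * dnorm(grid, fit$mu[i], s[i])
      }, numeric(512)))
      d1 <- diff(dens)
      n_modes <- sum(d1[-length(d1)] > 0 & d1[-1] <= 0)
      if (n_modes != g) return(TRUE)
    }
    FALSE
  }
  # restarts run on a short iteration budget; only the best candidate is
  # polished to full convergence
  best <- local_seed(seed, {
    best <- NULL; best_bad <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- run_em(seed_means(), iters = min(max_iter, 150L))
      if (fit$empty || !is.finite(fit$ll)) next
      if (is_degenerate(fit)) {
        if (is.null(best_bad) || fit$ll > best_bad$ll) best_bad <- fit
      } else if (is.null(best) || fit$ll > best$ll) {
        best <- fit
      }
    }
    list(good = best, bad = best_bad)
  })
  degenerate <- is.null(best$good)
  best <- best$good %||% best$bad
  if (!is.null(best) && !degenerate) {
    polished <- run_em(best$mu, best$pi, best$V)
    if (!polished$empty && is.finite(polished$ll) &&
        !is_degenerate(polished) && polished$ll >= best$ll) {
      best <- polished
    }
  }
  if (is.null(best)) {
    warn("EM failed on every restart: falling back to a single component.")
    return(fit_gmm(values, 1))
  }
  ord <- order(best$mu)
  new_gmm(as.integer(g), best$pi[ord], best$mu[ord], best$V[ord], best$ll, n,
          degenerate = degenerate)
}

new_gmm <- function(g, pi_, mu, V, ll, n, degenerate = FALSE) {
  structure(list(g = g, pi = pi_, mu = mu, V = V, log_likelihood = ll,
                 aic = 2 * (3 * g - 1) - 2 * ll, n_cells = n,
                 degenerate = degenerate),
            class = "omihet_gmm")
}

#' @export
print.omihet_gmm <- function(x, ...) {
  cat(sprintf("<omihet_gmm> g = %d, n = %d, logL = %.3f, AIC = %.3f\n",
              x$g, x$n_cells, x$log_likelihood, x$aic))
  print(tibble::tibble(component = seq_len(x$g), pi = x$pi, mu = x$mu,
                       sigma = sqrt(x$V)))
  invisible(x)
}

#' Select the number of metabolic subpopulations by AIC
#'
#' Fits mixtures with 1, 2 and 3 components and returns the fit with the
#' lowest AIC; ties break toward fewer components. Components whose minimum
#' cell count (`5 * g`) exceeds the sample are not attempted.
#'
#' @inheritParams fit_gmm
#' @param g_max Largest component count considered (default 3).
#' @return The winning `omihet_gmm`.
#' @export
select_model <- function(values, seed = NULL, g_max = 3, n_restarts = 10) {
  if (length(values) < 5) {
    abort("need at least 5 values for subpopulation modeling.",
          class = "omihet_too_few_cells")
  }
  if (var(as.numeric(values)) == 0 || is.na(var(as.numeric(values)))) {
    return(fit_gmm(values, 1))
  }
  fits <- list()
  for (g in seq_len(g_max)) {
    if (length(values) < 5 * g) break
    fits[[g]] <- fit_gmm(values, g, seed = derive_seed(seed, g),
                         n_restarts = n_restarts)
  }
  # degenerate fits (every restart collapsed or unresolvable) do not
  # compete unless nothing else is on the table
  ok <- !vapply(fits, `[[`, logical(1), "degenerate")
  if (any(ok)) fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  fits[[which.min(aics)]]  # which.min takes the first (smallest g) on ties
}

# median of the fitted mixture: root of F(x) = 0.5
mixture_median <- function(model) {
  if (model$g == 1) return(model$mu[1])
  s <- sqrt(model$V)
  lo <- min(model$mu - 10 * s); hi <- max(model$mu + 10 * s)
  f <- function(x) sum(model$pi * pnorm(x, model$mu, s)) - 0.5
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Weighted heterogeneity index (wH-index)
#'
#' A modified Shannon diversity index computed on a fitted Gaussian mixture:
#' `wH = sum_i (1 - p_i * ln(p_i + 1)) * (sigma_i + d_i)`, where `p_i` is the
#' mixing proportion, `sigma_i = sqrt(V_i)` the subpopulation SD, and `d_i`
#' the distance between the subpopulation median (its mean, by Gaussian
#' symmetry) and the median of the full mixture distribution (found as the
#' root of the mixture CDF at 0.5). Larger values indicate more heterogeneous
#' populations; for a single homogeneous component the index reduces to
#' `(1 - ln 2) * sigma`.
#'
#' @param model An `omihet_gmm`.
#' @return Non-negative scalar in endpoint units.
#' @examples
#' wh_index(fit_gmm(rnorm(200), 1))
#' @export
wh_index <- function(model) {
  stopifnot(inherits(model, "omihet_gmm"))
  m <- mixture_median(model)
  d <- abs(model$mu - m)
  sum((1 - model$pi * log(model$pi + 1)) * (sqrt(model$V) + d))
}

#' Quadratic entropy of a cell-value distribution
#'
#' Values are binned into `n_bins` equal-width bins over their range;
#' `QE = sum_ij p_i p_j d_ij` with `p` the bin occupancy fractions and
#' `d_ij` the distance between bin centers normalized by the range, giving a
#' bounded \[0, 1\] heterogeneity measure (0 for a constant sample).
#'
#' @param values Numeric vector (`n >= 2`).
#' @param n_bins Number of bins (default 20).
#' @return Scalar in \[0, 1\].
#' @export
quadratic_entropy <- function(values, n_bins = 20) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("need n >= 2.", class = "omihet_too_few_cells")
  rng <- range(values)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  p <- tabulate(idx, n_bins) / length(values)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  d <- abs(outer(centers, centers, "-")) / diff(rng)
  as.numeric(t(p) %*% d %*% p)
}

#' Kolmogorov-Smirnov normality distance
#'
#' The sup-distance between the empirical CDF of the sample and the normal
#' CDF with the sample's own mean and SD — a descriptive measure of how far
#' the distribution departs from normality (not a test p-value).
#'
#' @param values Numeric vector (`n >= 8`).
#' @return Scalar in \[0, 1\]; 0 (with a warning) for a constant sample.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 8) abort("need n >= 8.", class = "omihet_too_few_cells")
  s <- sd(values)
  if (s == 0) {
    warn("constant sample: KS distance defined as 0.")
    return(0)
  }
  x <- sort(values)
  F_ <- pnorm(x, mean(values), s)
  max(seq_len(n) / n - F_, F_ - (seq_len(n) - 1) / n)
}

#' Outlier percentage under Tukey fences
#'
#' Percentage of values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#'
#' @param values Numeric vector (`n >= 4`).
#' @return Percentage in \[0, 100\].
#' @export
outlier_pct <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) abort("need n >= 4.", class = "omihet_too_few_cells")
  q <- quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  100 * mean(values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr)
}

#' Bootstrap uncertainty of the wH-index
#'
#' Resamples the cell values with replacement `n_boot` times; each resample
#' goes through full AIC model selection ([select_model()]) and
#' [wh_index()], so model-choice uncertainty propagates into the summary.
#'
#' @param values Numeric vector (`n >= 15`).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Seed for the resampling.
#' @param n_restarts EM restarts per fit (default 10).
#' @return One-row tibble: `point` (wH of the full sample), `boot_mean`,
#'   `boot_sd`, `ci_lower`, `ci_upper` (2.5/97.5 percentiles), `n_boot`.
#' @export
bootstrap_wh <- function(values, n_boot = 1000, seed = NULL, n_restarts = 10) {
  values <- as.numeric(values)
  if (length(values) < 15) abort("need n >= 15.", class = "omihet_too_few_cells")
  point <- wh_index(select_model(values, seed = derive_seed(seed, 0),
                                 n_restarts = n_restarts))
  # variance-corrected smoothed bootstrap: plain resampling duplicates
  # values, and duplicated points masquerade as tight subpopulations under
  # re-fitted mixtures; adding kernel noise at the Silverman bandwidth and
  # rescaling to the sample variance restores continuous data
  n <- length(values)
  h <- 1.06 * sd(values) * n^(-1 / 5)
  v0 <- var(values)
  wh <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      res <- values[sample.int(n, replace = TRUE)]
      if (h > 0) {
        res <- mean(res) + (res - mean(res) + h * rnorm(n)) /
          sqrt(1 + h^2 / v0)
      }
      suppressWarnings(
        wh_index(select_model(res, seed = derive_seed(seed, b),
                              n_restarts = n_restarts)))
    }, numeric(1))
  })
  ci <- quantile(wh, c(0.025, 0.975), names = FALSE)
  tibble::tibble(point = point, boot_mean = mean(wh), boot_sd = sd(wh),
                 ci_lower = ci[1], ci_upper = ci[2], n_boot = n_boot)
}

#' Evaluate mixture density curves on a grid
#'
#' Returns the per-component densities (scaled by their mixing proportions)
#' and their pointwise sum, area-normalized so the total curve integrates
#' to 1 — the form used to overlay treated vs. control subpopulation
#' distributions.
#'
#' @param model An `omihet_gmm`.
#' @param grid Evaluation points; default 512 points spanning the component
#'   means +/- 8 SD.
#' @return Tibble with `x`, `component` (`"1"`, `"2"`, ..., `"total"`),
#'   `density`.
#' @export
density_curves <- function(model, grid = NULL) {
  stopifnot(inherits(model, "omihet_gmm"))
  s <- sqrt(model$V)
  if (is.null(grid)) {
    grid <- seq(min(model$mu - 8 * s), max(model$mu + 8 * s), length.out = 512)
  }
  comp <- purrr::map_dfr(seq_len(model$g), function(i) {
    tibble::tibble(x = grid, component = as.character(i),
                   density = model$pi[i] * dnorm(grid, model$mu[i], s[i]))
  })
  total <- comp |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop") |>
    dplyr::mutate(component = "total")
  dplyr::bind_rows(comp, total[, c("x", "component", "density")])
}

#' Heterogeneity profile of a cell group
#'
#' One-stop summary of a group's value distribution: AIC-selected mixture
#' model, wH-index, quadratic entropy, KS normality distance, outlier
#' percentage, SD and coefficient of variation.
#'
#' @param data Data frame with the value column, or a bare numeric vector.
#' @param value Column name holding the values (default `"value"`); ignored
#'   for vector input.
#' @param seed Seed for model selection.
#' @param n_bins Bins for quadratic entropy.
#' @return One-row tibble: `n`, `g`, `wh_index`, `qe`, `ks`, `ol_pct`, `sd`,
#'   `cv`, and a `model` list-column with the fitted `omihet_gmm`.
#' @export
heterogeneity_profile <- function(data, value = "value", seed = NULL,
                                  n_bins = 20) {
  values <- if (is.data.frame(data)) data[[value]] else as.numeric(data)
  model <- select_model(values, seed = seed)
  tibble::tibble(
    n = length(values), g = model$g,
    wh_index = wh_index(model),
    qe = quadratic_entropy(values, n_bins),
    ks = ks_normality(values),
    ol_pct = outlier_pct(values),
    sd = sd(values), cv = sd(values) / mean(values),
    model = list(model))
}
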