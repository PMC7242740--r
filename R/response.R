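#' Glass's delta treatment effect size
#'
#' `Delta = (mean(control) - mean(treated)) / sd(control)` with the sample
#' (n - 1) control SD. The sign convention makes a treatment-induced
#' *decrease* positive, so drug response (a drop in OMI index relative to
#' control) yields positive effect sizes and responders have the larger
#' Delta.
#'
#' @param treated,control Numeric vectors (`n >= 2` each; control SD must be
#'   positive).
#' @return Scalar effect size.
#' @examples
#' glass_delta(c(0, 1, 2), c(1, 2, 3))  # 1
#' @export
glass_delta <- function(treated, control) {
  if (length(treated) < 2 || length(control) < 2) {
    abort("need n >= 2 in each group.", class = "omihet_too_few_cells")
  }
  s <- sd(control)
  if (s == 0) abort("control SD is zero.", class = "omihet_invalid_parameter")
  (mean(control) - mean(treated)) / s
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most 10 observations and no
#' ties; otherwise the normal approximation with tie and continuity
#' correction. The p-value is capped at 1.
#'
#' @param a,b Numeric vectors (`n >= 3` each).
#' @return p-value in (0, 1\].
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    abort("need n >= 3 per group.", class = "omihet_too_few_cells")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- length(a) <= 10 && length(b) <= 10 && !ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Classify predicted treatment response
#'
#' A patient-treatment pair is a `predicted_responder` when the OMI-index
#' effect size meets the cutoff (`Delta >= 0.75`, inclusive) *and* treatment
#' contracts heterogeneity (`wh_treated - wh_control < 0`);
#' `predicted_non_responder` when the effect size misses the cutoff or
#' heterogeneity expands; exactly unchanged heterogeneity with a passing
#' effect size is `indeterminate`.
#'
#' @param delta Glass's delta of the OMI index (vectorized).
#' @param wh_control,wh_treated wH-index of the control and treated cells.
#' @param threshold Effect-size cutoff (default 0.75).
#' @return Character vector in
#'   `c("predicted_responder", "predicted_non_responder", "indeterminate")`.
#' @export
classify_response <- function(delta, wh_control, wh_treated, threshold = 0.75) {
  if (any(!is.finite(c(delta, wh_control, wh_treated)))) {
    abort("inputs must be finite.", class = "omihet_invalid_parameter")
  }
  delta_wh <- wh_treated - wh_control
  dplyr::case_when(
    delta >= threshold & delta_wh < 0 ~ "predicted_responder",
    delta < threshold | delta_wh > 0 ~ "predicted_non_responder",
    .default = "indeterminate")
}

#' Percent variance explained by a grouping (adjusted R-squared)
#'
#' OLS of the values on group indicators; returns 100 times the adjusted
#' coefficient of determination (adjusted for `n - 1` over `n - k - 1` with
#' `k = groups - 1`). Adjusted R-squared can be slightly negative under the
#' null; it is reported raw here.
#'
#' @param values Numeric vector.
#' @param groups Grouping labels, same length (>= 2 distinct groups, each
#'   with >= 2 values).
#' @return Percent of variance explained (may be < 0).
#' @export
variance_explained <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) {
    abort("need >= 2 groups.", class = "omihet_invalid_parameter")
  }
  if (any(table(groups) < 2)) {
    abort("every group needs >= 2 values.", class = "omihet_invalid_parameter")
  }
  fit <- lm(values ~ groups)
  100 * summary(fit)$adj.r.squared
}

#' Hierarchical variance partition of a cell table
#'
#' Reproduces the two strata of the baseline heterogeneity analysis on
#' untreated cells at the first timepoint: per patient, the percent of
#' single-cell variance explained by organoid membership; and across
#' patients, the percent explained by patient membership.
#'
#' @param cells Cell tibble with `patient_id`, `organoid_id`, `treatment`,
#'   `timepoint_h` and the endpoint columns.
#' @param endpoints Endpoint column names to partition.
#' @param control_label Untreated arm label.
#' @return Tibble with `level` (`"organoid"` rows per patient,
#'   `"patient"` rows across the cohort), `patient_id` (`NA` for patient
#'   level), `endpoint`, `pct_explained`, `n_cells`, `n_groups`.
#' @export
variance_partition <- function(cells, endpoints = c("redox_ratio_raw",
                                                    "nadph_tau_m",
                                                    "fad_tau_m"),
                               control_label = "control") {
  base <- cells |>
    dplyr::filter(.data$treatment == control_label,
                  .data$timepoint_h == min(.data$timepoint_h))
  org <- purrr::map_dfr(unique(base$patient_id), function(p) {
    sub <- base[base$patient_id == p, ]
    purrr::map_dfr(endpoints, function(e) {
      tibble::tibble(level = "organoid", patient_id = p, endpoint = e,
                     pct_explained = variance_explained(sub[[e]], sub$organoid_id),
                     n_cells = nrow(sub),
                     n_groups = dplyr::n_distinct(sub$organoid_id))
    })
  })
  pat <- purrr::map_dfr(endpoints, function(e) {
    tibble::tibble(level = "patient", patient_id = NA_character_, endpoint = e,
                   pct_explained = variance_explained(base[[e]], base$patient_id),
                   n_cells = nrow(base),
                   n_groups = dplyr::n_distinct(base$patient_id))
  })
  dplyr::bind_rows(org, pat)
}

#' Pairwise squared-correlation map
#'
#' Squared Pearson correlations between every pair of measurement columns
#' (pairwise-complete observations), plus the count of partners each
#' measurement correlates with at `R^2 >` cutoff (diagonal excluded).
#' Constant columns have undefined correlations, reported as `NA`.
#'
#' @param data Data frame of numeric measurement columns.
#' @param cutoff Partner-count threshold on R^2 (default 0.5).
#' @return List with `r_squared` (symmetric matrix, unit diagonal) and
#'   `n_partners` (named integer vector).
#' @export
correlation_map <- function(data, cutoff = 0.5) {
  m <- as.matrix(data[vapply(data, is.numeric, logical(1))])
  if (ncol(m) < 2) abort("need >= 2 numeric columns.", class = "omihet_invalid_input")
  n_ok <- crossprod(!is.na(m))
  if (any(n_ok[upper.tri(n_ok)] < 3)) {
    abort("need >= 3 complete observations per pair.", class = "omihet_invalid_input")
  }
  r2 <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  off <- r2
  diag(off) <- NA
  n_partners <- apply(off, 1, function(x) sum(x > cutoff, na.rm = TRUE))
  list(r_squared = r2, n_partners = n_partners)
}

#' Multivariate OLS adjusted R-squared
#'
#' Fits `dependent ~ independents` (with intercept) by ordinary least
#' squares and returns the adjusted coefficient of determination.
#'
#' @param dependent Numeric vector.
#' @param independents Numeric matrix or data frame of predictors
#'   (`n > p + 1` required; full column rank).
#' @return Adjusted R-squared (may be negative).
#' @export
multivariate_regression <- function(dependent, independents) {
  X <- as.matrix(independents)
  n <- length(dependent); p <- ncol(X)
  if (n != nrow(X)) abort("lengths differ.", class = "omihet_invalid_input")
  if (n <= p + 1) abort("need n > p + 1.", class = "omihet_invalid_input")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    bad <- colnames(X, do.NULL = FALSE, prefix = "x")[
      setdiff(seq_len(p) + 1, qrX$pivot[seq_len(qrX$rank)]) - 1]
    abort(paste0("rank-deficient design; collinear columns: ",
                 paste(bad, collapse = ", ")),
          class = "omihet_rank_deficient")
  }
  fit <- lm(dependent ~ X)
  summary(fit)$adj.r.squared
}

#' Organoid-formation success-rate summary
#'
#' Success rate as an integer percent (`round(100 * successful / attempted)`,
#' halves away from zero), with an optional per-group breakdown.
#'
#' @param attempted,successful Counts, scalars or parallel vectors.
#' @param group Optional group labels for a breakdown table.
#' @return Tibble with one row per group plus an `"overall"` row:
#'   `group`, `attempted`, `successful`, `success_rate_pct`.
#' @examples
#' cohort_summary(22, 14)  # 64
#' @export
cohort_summary <- function(attempted, successful, group = NULL) {
  if (any(attempted <= 0)) abort("`attempted` must be > 0.",
                                 class = "omihet_invalid_parameter")
  if (any(successful < 0) || any(successful > attempted)) {
    abort("`successful` must lie in [0, attempted].",
          class = "omihet_invalid_parameter")
  }
  pct <- function(s, a) floor(100 * s / a + 0.5)  # half away from zero (counts >= 0)
  rows <- tibble::tibble(
    group = group %||% paste0("group", seq_along(attempted)),
    attempted = attempted, successful = successful,
    success_rate_pct = pct(successful, attempted))
  if (length(attempted) > 1) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      group = "overall", attempted = sum(attempted),
      successful = sum(successful),
      success_rate_pct = pct(sum(successful), sum(attempted))))
  }
  rows
}

#' Per-treatment response report for a cell table
#'
#' For each (patient, treatment, timepoint) arm versus the matched control
#' cells: Glass's delta and Wilcoxon rank-sum p for each requested endpoint,
#' the wH-index of control and treated cells (with AIC-selected mixtures),
#' the wH change, and the responder classification driven by the OMI-index
#' effect size and the heterogeneity change.
#'
#' @param cells Cell tibble carrying `omi_index` (see [omi_index()]).
#' @param endpoints Endpoints to report effect sizes for (first must be the
#'   classification endpoint, default `omi_index`).
#' @param threshold Responder effect-size cutoff (default 0.75).
#' @param control_label Untreated arm label.
#' @param seed Seed for mixture model selection.
#' @param n_boot Bootstrap resamples for wH uncertainty (0 disables).
#' @return Tibble with one row per (patient, treatment, timepoint, endpoint)
#'   carrying `glass_delta`, `wilcoxon_p`, `responds_flag`, and the
#'   arm-level `wh_control`, `wh_treated`, `delta_wh`, `classification`
#'   (repeated across the arm's endpoint rows), plus bootstrap columns when
#'   `n_boot > 0`.
#' @export
response_report <- function(cells, endpoints = "omi_index", threshold = 0.75,
                            control_label = "control", seed = NULL,
                            n_boot = 0) {
  arms <- cells |>
    dplyr::filter(.data$treatment != control_label) |>
    dplyr::distinct(.data$patient_id, .data$treatment, .data$timepoint_h)
  if (nrow(arms) == 0) {
    abort("no treated arms in the cell table.", class = "omihet_invalid_input")
  }
  purrr::map_dfr(seq_len(nrow(arms)), function(i) {
    key <- arms[i, ]
    ctrl <- cells |>
      dplyr::filter(.data$patient_id == key$patient_id,
                    .data$timepoint_h == key$timepoint_h,
                    .data$treatment == control_label)
    trt <- cells |>
      dplyr::filter(.data$patient_id == key$patient_id,
                    .data$timepoint_h == key$timepoint_h,
                    .data$treatment == key$treatment)
    seed_i <- derive_seed(seed, i)
    m_ctrl <- select_model(ctrl[[endpoints[1]]], seed = derive_seed(seed_i, 1))
    m_trt <- select_model(trt[[endpoints[1]]], seed = derive_seed(seed_i, 2))
    whc <- wh_index(m_ctrl); wht <- wh_index(m_trt)
    ep_rows <- purrr::map_dfr(endpoints, function(e) {
      d <- glass_delta(trt[[e]], ctrl[[e]])
      tibble::tibble(endpoint = e, glass_delta = d,
                     wilcoxon_p = wilcoxon_rank_sum(trt[[e]], ctrl[[e]]),
                     responds_flag = d >= threshold)
    })
    out <- dplyr::bind_cols(
      key[rep(1, nrow(ep_rows)), ], ep_rows,
      tibble::tibble(wh_control = whc, wh_treated = wht,
                     delta_wh = wht - whc,
                     g_control = m_ctrl$g, g_treated = m_trt$g,
                     classification = classify_response(
                       ep_rows$glass_delta[1], whc, wht, threshold))[
                         rep(1, nrow(ep_rows)), ])
    if (n_boot > 0) {
      bc <- bootstrap_wh(ctrl[[endpoints[1]]], n_boot, derive_seed(seed_i, 3))
      bt <- bootstrap_wh(trt[[endpoints[1]]], n_boot, derive_seed(seed_i, 4))
      out$wh_control_boot_sd <- bc$boot_sd
      out$wh_treated_boot_sd <- bt$boot_sd
    }
    out
  })
}
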