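# omihet

Single-cell **optical metabolic imaging (OMI)** heterogeneity analysis for
patient-derived tumor organoids, in R.

Label-free multiphoton imaging of the endogenous co-enzymes NAD(P)H and FAD
reads out cellular metabolism without stains: the **optical redox ratio**
(NAD(P)H intensity / FAD intensity) and the fluorescence lifetimes of both
co-enzymes shift when tumor cells respond to drug treatment. Because every
cell in an image is measured individually, the same data also reveal
*metabolic heterogeneity* — coexisting subpopulations of cells that respond
differently to the same drug — which is invisible to bulk assays and
predictive of treatment failure. `omihet` implements the full analysis chain
for this kind of experiment, plus a synthetic-data module that simulates
TCSPC imaging and hierarchical single-cell cohorts so every stage can be
validated against known ground truth.

## What it computes

**Per-pixel lifetime fitting.** TCSPC decay stacks (x, y, 256 time bins) are
spatially binned (3×3), then each pixel's photon histogram is fit by bounded
Levenberg–Marquardt to a two-exponential decay re-convolved with the
instrument response function:

    I(t) = A · [ IRF ⊛ ( α₁ e^(−t/τ₁) + α₂ e^(−t/τ₂) ) ] + C,   τ₁ < τ₂

with Neyman weights 1/max(count, 1). The mean lifetime is the
amplitude-weighted average **τₘ = α₁τ₁ + α₂τ₂**.

**Per-cell endpoints and the OMI index.** Cell cytoplasms are segmented from
NAD(P)H intensity (Gaussian smoothing → Otsu → watershed), endpoints are
averaged per cell, redox ratios are normalized to control cells of the same
patient and timepoint, and the **OMI index** is the (1, 1, −1) combination of
the control-centered redox ratio, NAD(P)H τₘ and FAD τₘ. A decrease versus
control indicates drug response.

**Subpopulation modeling and the wH-index.** For any cell group, 1-, 2- and
3-component Gaussian mixtures are fit by EM and the best model is chosen by
AIC (k = 3g − 1). Heterogeneity is quantified by the weighted heterogeneity
index

    wH = Σᵢ (1 − pᵢ ln(pᵢ + 1)) · (σᵢ + dᵢ)

(pᵢ mixing proportion, σᵢ subpopulation SD, dᵢ distance from the
subpopulation median to the mixture median), alongside quadratic entropy,
the Kolmogorov–Smirnov normality distance, and the Tukey-fence outlier
percentage, with bootstrap uncertainty.

**Treatment response.** Glass's Δ = (mean(control) − mean(treated)) /
SD(control) per endpoint, Wilcoxon rank-sum p-values, hierarchical variance
partitioning (adjusted R² of cells on organoid / patient indicators),
correlation maps, and the responder rule: **predicted responder ⇔ Δ(OMI
index) ≥ 0.75 and the wH-index decreases with treatment**.

## Worked example

```r
library(omihet)

# simulate a small cohort: 1 patient, 5 organoids/arm, 100 cells/organoid,
# one strongly responding drug arm
spec <- cohort_sim_spec(
  n_patients = 1, organoids_per_patient = 5, cells_per_organoid = 100,
  treatments = list(treatment_effect(
    "drug", shift = c(redox_ratio_raw = -0.8, nadph_tau_m = -0.8,
                      fad_tau_m = 0.6), sd_scale = 0.6)),
  seed = 7)
cells <- omi_index(generate_cell_table(spec))
report <- response_report(cells, seed = 7)
report[, c("treatment", "glass_delta", "wilcoxon_p", "delta_wh",
           "classification")]
#> # A tibble: 1 × 5
#>   treatment glass_delta wilcoxon_p delta_wh classification
#>   <chr>           <dbl>      <dbl>    <dbl> <chr>
#> 1 drug             1.27   5.32e-86  -0.0330 predicted_responder
```

The drug arm shows a Glass's Δ of 1.27 on the OMI index (well above the 0.75
responder cutoff), an overwhelming Wilcoxon p, and a heterogeneity
*contraction* (Δ wH = −0.033), so the arm is called a predicted responder.
Mixture models for any group are available directly:

```r
m <- select_model(cells$omi_index[cells$treatment == "drug"], seed = 1)
glance(m)      # g, log-likelihood, AIC, wH-index
tidy(m)        # per-subpopulation proportions, means, SDs
autoplot(m)    # normalized density curves
```

The imaging side works the same way from simulated decay stacks — see
`generate_flim_stack()`, `fit_lifetime_image()`, `segment_cytoplasms()`,
`extract_cell_endpoints()`, and `run_pipeline()` for the end-to-end driver
(a thin CLI over it is installed at `inst/cli/omihet`).

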