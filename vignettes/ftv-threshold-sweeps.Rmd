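---
title: "Functional tumor volume threshold sweeps: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional tumor volume threshold sweeps: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftvsweep)
```

## The problem

In breast cancer treated with neoadjuvant chemotherapy (NACT), serial
dynamic contrast-enhanced MRI (DCE-MRI) is used to follow tumor response.
The imaging biomarker at the center of this package is **functional tumor
volume (FTV)**: the volume of tissue inside a volume of interest (VOI) that
enhances strongly and early after contrast injection and, optionally,
washes out quickly afterwards. FTV depends on two tunable thresholds:

* `PE_t` — the minimum **early percent enhancement**,
  $PE = (S_t - S_0)/S_0 \times 100$, computed at the early post-contrast
  timepoint;
* `SER_t` — the minimum **signal enhancement ratio**,
  $SER = PE_{early}/PE_{late}$, the early-to-late enhancement ratio. Values
  above 1 indicate washout, a kinetic pattern associated with malignancy.

The question the package answers is not "what is the FTV" but "**which
threshold pair makes FTV-derived predictors most prognostic**". For each
cell of a grid of threshold pairs (`PE_t` from 30% to 200% in steps of 10%,
`SER_t` from 0.0 to 2.0 in steps of 0.2 — 198 cells), three predictors are
computed per patient from the visits MRI_1 (baseline), MRI_2 (after one
chemotherapy cycle) and MRI_f (pre-surgery):

* `delta_ftv2` — percent FTV change, baseline to MRI_2;
* `delta_ftvf` — percent FTV change, baseline to MRI_f;
* `ftv_f` — absolute FTV at MRI_f in cc;

and a univariate Cox proportional-hazards model is fitted against
recurrence-free survival (RFS), within the full cohort and within receptor
subtypes (HR+/HER2−, HER2+, triple negative). The *optimized* cell is the
one with the lowest likelihood-ratio p-value; it is compared with the
conventional default `PE_t = 70%, SER_t = 0` and visualized as hazard-ratio
and p-value heat maps over the grid.

## The FTV computation, step by step

1. **Enhancement maps** (`compute_pe_maps()`, `compute_ser_map()`).
   Voxelwise `PE_early`, `PE_late` and `SER` from the three timepoints.
   Two numerical decisions the PE/SER definitions leave open:
   * *Baseline validity floor.* Fat-suppressed background signal sits at
     the noise level and division by it produces arbitrary PE values. A
     voxel is valid only if `s0` exceeds a floor, by default 5% of the 98th
     percentile of the `s0` volume (`default_s0_floor()`); the floor is
     scale-free so it survives scanner intensity rescaling. Invalid voxels
     are excluded from every downstream mask.
   * *Complete washout.* `SER` is undefined where the late signal has
     dropped to or below baseline (`pe_late <= 0`) while the voxel did
     enhance early. Those voxels are the extreme of the washout behavior
     SER is meant to flag, so they are capped at `Inf` (configurable via
     `washout_cap`), which passes every SER threshold, rather than being
     discarded. Non-enhancing voxels (`pe_early <= 0`) get `SER = 0`.
2. **VOI** (`voi_spec()`, `voi_mask()`). The VOI is the intersection of two
   rectangular ROIs back-projected along two different axes — the
   declarative equivalent of drawing rectangles on two orthogonal
   maximum-intensity projections — minus exclusion regions (axis-aligned
   boxes or swept 2D polygons standing in for the interactively drawn
   "irregular ROI" around vessels or heart). Coordinates are 0-based,
   half-open `[lo, hi)` in array order; which two axes to project along is
   free, since any two distinct axes define a valid intersection.
3. **Threshold gating** (`enhancing_mask()`, `compute_ftv()`). The order of
   operations is fixed: PE threshold first, then a connectivity test that
   removes components smaller than `min_cluster_voxels`, then the SER
   threshold on the surviving voxels. Comparisons are closed (`>=`), so
   `SER_t = 0` gates out nothing with non-negative SER — which is exactly
   the documented behavior of the default setting.
   * *Connectivity* defaults to the most permissive standard neighborhood,
     26 in 3D, configurable to 6 or 18; the filter runs in 3D (a 2D
     per-slice variant would simply correspond to a different neighborhood
     definition and was not adopted).
   * *Minimum cluster size* defaults to 8 voxels, the count closest to a
     0.01 cc cluster at the 0.7 × 0.94 × 2.0 mm voxel geometry
     (`default_min_cluster_voxels()`); "very small regions" is otherwise
     unquantified.
4. **Predictors** (`build_predictors()`). Percent change is
   `(later − baseline)/baseline × 100`, so negative values mean shrinkage.
   Cells with zero baseline FTV give missing deltas; a missing MRI_2 exam
   gives an all-missing `delta_ftv2` while `ftv_f` stays defined.

## The survival stage

`fit_cox()` maximizes the Cox partial likelihood with the **Efron tie
correction** (the default of standard survival software) by Newton
iteration with step-halving, and reports the hazard ratio per `scale` units
of the predictor, its Wald 95% CI, and the likelihood-ratio p-value against
chi-square(1). The per-unit scale matters for interpretability: hazard
ratios are reported per **10 percentage points** for the percent-change
predictors and per **1 cc** for `ftv_f` by default, and the scale in use is
carried on every result.

Small subsets invite **monotone likelihood** (perfect separation of events
along the covariate): the partial likelihood then increases without bound
in |β| and the reported HR and CI explode. Fits with |β| > 15 (on the
scaled covariate) or SE > 10 are flagged `degenerate`; they are displayed
in heat maps but excluded from optimum selection. Cells whose fit cannot be
attempted at all (no events, constant covariate, fewer than two subjects)
carry flagged placeholder results. No multiple-testing correction is
applied across the 198 cells — the sweep is exploratory by design — but the
number of fits and the count of cells with p < 0.05 are always reported.

`select_optimized()` returns the eligible cell with the lowest p-value;
exact ties are broken deterministically (higher HR, then lower `PE_t`, then
lower `SER_t`) and the tie is recorded.

## The synthetic cohort generator

No clinical images ship with the package; `simulate_cohort()` generates
cohorts with known ground truth so that every stage — and the central
claim, that the sweep can locate a threshold pair that truly matters — is
testable. Defaults mirror the emulated study design: 64 patients, subtype
mix 21 : 15 : 11 : 17 (HR+/HER2− : HER2+ : TN : unknown), three visits with
about 20% of MRI_2 exams missing, voxels of 0.7 × 0.94 × 2.0 mm.

Each phantom is three tissue classes: fat background with suppressed
baseline and no enhancement, a parenchyma ellipsoid with weak enhancement,
and a tumor ellipsoid with strong enhancement whose washout differs by
subtype. Voxelwise `PE_early` and `SER` are drawn around per-patient means
(patient random effects); the post-contrast volumes are reconstructed by
inverting the enhancement definitions, `s_early = s0(1 + PE/100)`,
`s_late = s0(1 + (PE/SER)/100)`, so with zero noise the enhancement module
recovers the configured kinetics exactly. Treatment response scales the
tumor radii per visit; survival times are exponential with hazard
$h_0 \exp(\beta\, z / s)$ where $z$ is one FTV predictor evaluated at the
**true thresholds** `(PE* = 100%, SER* = 1.0)` — and only there. Censoring
is the earlier of a 120-month administrative horizon and random dropout.

Design choices worth stating explicitly:

* **Default phantom size is 32 × 32 × 16 voxels.** That keeps a
  200-patient replicate affordable on one CPU while leaving the tumor tens
  to hundreds of voxels across visits; it also means simulated tumors are
  tenths of a cc where clinical tumors are tens. The hazard unit for the
  absolute-volume predictor is therefore **0.1 cc** in the generator
  (analysis defaults remain per 1 cc); percent-change predictors are
  scale-free and keep their per-10-point unit.
* **The hazard-driving predictor defaults to `ftv_f`.** For a
  percent-change predictor, a patient's kinetic gating fraction appears in
  both numerator and denominator and largely cancels, so measured values
  at different grid cells are almost perfectly correlated and no threshold
  pair is identifiable even in principle. The absolute final volume
  retains the patient-specific fraction of tumor passing the thresholds,
  which is what makes "the sweep should find `(PE*, SER*)`" a falsifiable
  property. (The emulated study likewise found the absolute final volume
  its most robust predictor.)
* **Identifiability comes from patient heterogeneity.** Tumor kinetic
  means vary across patients (PE mean SD 50 points, SER mean SD 0.25)
  while voxel-level SDs (12 points, 0.15) are comparable to one grid step,
  so measuring FTV one cell away from the truth distorts the covariate
  enough for the likelihood to notice. Voxel noise makes neighboring cells
  correlated, as in real data, so the minimum-p cell occasionally lands on
  a neighbor of the truth — the recovery property is stated as "within one
  grid step".
* **Baseline hazard 0.005/month** with the effect above yields roughly
  55–60% events (about 40% censoring) at the default configuration, a
  realistic follow-up profile for this disease setting.
* All randomness flows through R's RNG seeded once from `cfg$seed`;
  identical configuration and seed give a bit-identical cohort, including
  the files written to disk.

What the generator does **not** emulate: MR physics (coil inhomogeneity,
k-space artifacts, fat-suppression failure), motion between timepoints,
pharmacokinetic curve shapes beyond the three-timepoint summary,
regimen-dependent response, or correlation between subtype and tumor size.
Passing tests therefore demonstrate that the *computational pipeline* is
correct and that the *statistical machinery* recovers known truth under a
plausible data-generating process — not that any particular clinical
cohort's optimized thresholds are right.

## Numerical and degenerate-input behavior

* The FTV surface is computed by thresholding once per `PE_t` row and
  counting SER survivors for the whole `SER_t` row at once; it is exactly
  the per-cell computation (tests spot-check random cells) and is monotone
  non-increasing along both axes by construction.
* Connected-component labeling runs on the bounding box of the foreground
  (components cannot cross an all-background boundary), in compiled code,
  with a union-find labeler validated against a flood-fill oracle.
* An empty VOI is legal and yields zero FTV everywhere with a warning
  flag; an empty subset, a zero-event subset, or an all-degenerate sweep
  produce structured errors or flagged results, never crashes.
* Newton iteration starts at β = 0 and step-halves to guarantee ascent;
  non-convergence is reported via `converged = FALSE`, never an exception.

## Problem sizes used by the checks

The test suite and the acceptance script regenerate everything they need:
oracle comparisons run on volumes up to 16³ voxels; calibration and
recovery studies use 200-patient cohorts at the 32 × 32 × 16 phantom size
(50 sweep replicates and 100 effect-size replicates for recovery, 100
survival replicates against one imaged cohort for null calibration); the
end-to-end run in `scripts/acceptance.R` uses the study-sized 64-patient
cohort. These sizes were chosen to give stable Monte-Carlo estimates on a
single CPU.

## Known limitations

* The per-unit scaling behind any clinically reported hazard ratio is not
  recoverable from threshold settings alone; results always carry their
  scale, and comparisons across scales are the user's responsibility.
* The washout cap and the s0 floor are this package's choices where the
  original semi-automated workflow left behavior undocumented; both are
  exposed in configuration.
* Heat maps use a per-cell raster (deterministic and testable) rather than
  interpolated filled contours; p-values are colored on a log10 scale over
  0.001–0.1 since three decades are displayed.
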