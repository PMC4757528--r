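# ftvsweep

Threshold optimization for DCE-MRI functional tumor volume as a predictor
of recurrence-free survival in breast cancer under neoadjuvant
chemotherapy.

## What this solves

Functional tumor volume (FTV) is a DCE-MRI biomarker: the volume of tissue
in a volume of interest whose early percent enhancement exceeds a threshold
`PE_t` (after removal of very small connected regions) and whose signal
enhancement ratio — early-to-late enhancement, `SER = PE_early / PE_late` —
exceeds a threshold `SER_t`:

    PE_early = (S_E - S_0) / S_0 x 100        PE_late = (S_L - S_0) / S_0 x 100
    SER      = PE_early / PE_late
    FTV(PE_t, SER_t) = volume of VOI voxels with PE_early >= PE_t (small
                       components removed) and SER >= SER_t

The conventional operating point is `PE_t = 70%, SER_t = 0`, but the
prognostic strength of FTV-derived predictors depends on the thresholds,
and differently so in each breast-cancer subtype. `ftvsweep` computes, for
every cell of an 18 × 11 grid (`PE_t` 30–200% by 10, `SER_t` 0–2 by 0.2),
three predictors per patient — percent FTV change baseline → early
treatment (`delta_ftv2`), baseline → pre-surgery (`delta_ftvf`), and
absolute final FTV (`ftv_f`) — fits a univariate Cox proportional-hazards
model for recurrence-free survival per cell (Efron ties, Wald 95% CI,
likelihood-ratio p), locates the minimum-p "optimized" cell, and renders
hazard-ratio / p-value heat maps with the default and optimized cells
marked. Sweeps run on the full cohort and within HR+/HER2−, HER2+ and
triple-negative subsets.

Because no imaging cohort ships with the package, a first-class synthetic
generator (`simulate_cohort()`) produces DCE-MRI phantom cohorts — tissue
classes, subtype-dependent washout kinetics, tumor shrinkage across visits,
survival whose hazard depends on the FTV predictor at a known true
threshold pair — so threshold recovery is a testable property, not an
anecdote.

## Worked example

```r
library(ftvsweep)

# a small synthetic cohort, written in the formats the pipeline reads
cfg <- sim_config(n_patients = 40, seed = 42)
simulate_cohort(cfg, dir = "cohort")

rcfg <- run_config("cohort/clinical.csv", "cohort/images", "cohort/voi",
                   out_dir = "run", predictors = "ftv_f", subsets = "full",
                   scales = list(ftv_f = 0.1))  # HR per 0.1 cc at phantom scale
run_analysis(rcfg, quiet = TRUE)
run_report("run")$full[, c("predictor", "opt_pe_t", "opt_ser_t",
                           "opt_hr", "opt_p", "def_hr", "def_p")]
```

```
  predictor opt_pe_t opt_ser_t   opt_hr       opt_p    def_hr     def_p
1     ftv_f      110       1.2 3.390966 0.005733651 0.9544045 0.6596768
```

Reading: this cohort was generated with survival driven by final FTV at
the true pair `(100%, 1.0)`. The sweep's optimized cell lands one grid
step away at `PE_t = 110%, SER_t = 1.2`, where the hazard ratio per
0.1 cc of final FTV is 3.39 with LR p = 0.006 — against 0.95 (p = 0.66)
at the default setting, which at this sample size carries no signal at
all. `run/` also contains per-cell sweep
CSVs, heat-map PNGs with circle (default) and star (optimized) markers, a
machine-readable `report.json` and a `manifest.json` with input hashes.

The numbered scripts under `analysis/` run the same workflow at the
emulated study's scale (64 patients), plus a threshold-recovery experiment:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_run_ftv_sweeps.R
Rscript analysis/03_threshold_recovery.R
Rscript analysis/04_summarize.R
```

outputs land under `results/`.

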