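#!/usr/bin/env Rscript

# Step 3 — does the sweep find the generating thresholds?
#
# Repeatedly simulates cohorts (n = 200 for stable Cox fits) whose hazard
# depends on final FTV measured at (PE* = 100%, SER* = 1.0) only, runs the
# full sweep, and records where the minimum-p cell lands plus the fitted
# log-hazard at the true cell. Writes one row per replicate to
# results/recovery.csv.

suppressPackageStartupMessages(library(ftvsweep))

n_rep <- 20
rows <- vector("list", n_rep)
for (r in seq_len(n_rep)) {
  cfg <- sim_config(n_patients = 200, true_beta = 0.5, seed = 3000 + r)
  coh <- simulate_cohort(cfg, keep_studies = TRUE,
                         visits = c("MRI_1", "MRI_f"))
  arr <- cohort_predictors(coh, visits = c("MRI_1", "MRI_f"))
  sw <- sweep_cox(arr, coh$clinical, default_grid(), "ftv_f", "full",
                  scale = cfg$scale)
  fit <- fit_cox(coh$truth$z, coh$clinical$rfs_months, coh$clinical$event,
                 scale = cfg$scale)
  opt <- sw$optimized_cell
  rows[[r]] <- data.frame(
    replicate = r, opt_pe_t = opt[["pe_t"]], opt_ser_t = opt[["ser_t"]],
    min_p = min(sw$p[sw$converged & !sw$degenerate], na.rm = TRUE),
    beta_true_cell = fit$beta, events = sum(coh$clinical$event))
  cat(sprintf("replicate %2d: optimum (%g%%, %g), beta at true cell %.3f\n",
              r, opt[["pe_t"]], opt[["ser_t"]], fit$beta))
}
res <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(res, file.path("results", "recovery.csv"), row.names = FALSE)

hit <- abs(res$opt_pe_t - 100) <= 10 & abs(res$opt_ser_t - 1.0) <= 0.2
cat(sprintf("\nwithin one grid step of (100%%, 1.0): %d/%d (%.0f%%)\n",
            sum(hit), n_rep, 100 * mean(hit)))
cat(sprintf("mean fitted log-hazard at the true cell: %.3f (truth 0.5)\n",
            mean(res$beta_true_cell)))
cat("-> results/recovery.csv\n")
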