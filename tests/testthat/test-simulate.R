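# a small, fast configuration used across the generator tests
quick_cfg <- function(seed = 123, ...) {
  # small field of view, with tumors scaled to fit inside it
  sim_config(n_patients = 6, shape = c(20, 20, 10),
             tumor_radius_mm_range = c(3, 5.5), seed = seed, ...)
}

test_that("zero-noise fixed kinetics round-trip exactly through the maps", {
  kin <- default_kinetics()
  kin$tumor$pe <- 150; kin$tumor$pe_sd <- 0; kin$tumor$pe_patient_sd <- 0
  kin$tumor$ser_by_subtype[] <- 1.5
  kin$tumor$ser_sd <- 0; kin$tumor$ser_patient_sd <- 0
  kin$tumor$s0_sd <- 0
  cfg <- quick_cfg(kinetics = kin, noise_sd = 0)
  set.seed(cfg$seed)
  p <- ftvsweep:::draw_patient(cfg, "P001")
  st <- simulate_study(cfg, p, "MRI_1")
  tum <- attr(st, "tumor_mask")
  expect_gt(sum(tum), 0)
  maps <- enhancement_maps(st, s0_floor = 10)
  expect_equal(unname(maps$pe_early[tum]), rep(150, sum(tum)))
  expect_equal(unname(maps$ser[tum]), rep(1.5, sum(tum)), tolerance = 1e-12)
})

test_that("zero-noise FTV at sub-threshold settings equals the tumor volume", {
  kin <- default_kinetics()
  kin$tumor$pe <- 150; kin$tumor$pe_sd <- 0; kin$tumor$pe_patient_sd <- 0
  kin$tumor$ser_by_subtype[] <- 1.5
  kin$tumor$ser_sd <- 0; kin$tumor$ser_patient_sd <- 0
  # keep surrounding tissue quiet so only the tumor enhances past 100%
  kin$parenchyma$pe <- 20; kin$parenchyma$pe_sd <- 0
  cfg <- quick_cfg(kinetics = kin, noise_sd = 0)
  set.seed(cfg$seed)
  p <- ftvsweep:::draw_patient(cfg, "P001")
  st <- simulate_study(cfg, p, "MRI_1")
  tum <- attr(st, "tumor_mask")
  voi <- array(TRUE, dim(st$s0))
  maps <- enhancement_maps(st, s0_floor = 10)
  ftv <- compute_ftv(st, maps, voi, pe_t = 100, ser_t = 1.0,
                     min_cluster_voxels = 1)
  expect_equal(ftv, sum(tum) * voxel_volume_cc(st))
})

test_that("full shrinkage empties the final-visit tumor", {
  cfg <- quick_cfg(shrink_mri2_range = c(0, 0), shrink_mrif_range = c(0, 0))
  set.seed(cfg$seed)
  p <- ftvsweep:::draw_patient(cfg, "P001")
  st <- simulate_study(cfg, p, "MRI_f")
  expect_equal(sum(attr(st, "tumor_mask")), 0)
})

test_that("tumor FTV approaches the Gaussian tail expectation", {
  kin <- default_kinetics()
  kin$tumor$pe <- 160; kin$tumor$pe_sd <- 20; kin$tumor$pe_patient_sd <- 0
  kin$tumor$ser_by_subtype[] <- 1.2
  kin$tumor$ser_sd <- 0.2; kin$tumor$ser_patient_sd <- 0
  kin$parenchyma$pe <- 0; kin$parenchyma$pe_sd <- 0
  cfg <- sim_config(n_patients = 1, shape = c(28, 28, 14),
                    tumor_radius_mm_range = c(8, 8),
                    kinetics = kin, noise_sd = 0, seed = 7)
  set.seed(7)
  p <- ftvsweep:::draw_patient(cfg, "P001")
  st <- simulate_study(cfg, p, "MRI_1")
  tum <- attr(st, "tumor_mask")
  maps <- enhancement_maps(st, s0_floor = 10)
  ftv <- compute_ftv(st, maps, array(TRUE, dim(st$s0)), 130, 1.0,
                     min_cluster_voxels = 1)
  # independent voxel draws: survivor fraction is the product of two
  # Gaussian tail probabilities (SER >= 1 given sd 0.2 about 1.2)
  p_pass <- pnorm((160 - 130) / 20) * pnorm((1.2 - 1.0) / 0.2)
  expected <- sum(tum) * p_pass * voxel_volume_cc(st)
  mc_sd <- sqrt(sum(tum) * p_pass * (1 - p_pass)) * voxel_volume_cc(st)
  expect_lt(abs(ftv - expected), 4 * mc_sd)
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  cfg <- quick_cfg()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$z, b$truth$z)
  expect_identical(a$studies$P001$MRI_1$s0, b$studies$P001$MRI_1$s0)
  c2 <- simulate_cohort(quick_cfg(seed = 456))
  expect_false(identical(a$clinical$rfs_months, c2$clinical$rfs_months))
})

test_that("null effect yields hazard ratios near 1 with nominal CI coverage", {
  set.seed(131)
  cover <- logical(40)
  for (r in seq_len(40)) {
    cfg <- sim_config(n_patients = 150, true_beta = 0, seed = 1000 + r)
    z <- rnorm(150, 0, 1)  # any predictor: hazard does not depend on it
    surv <- simulate_survival(z, cfg)
    f <- fit_cox(z, surv$rfs_months, surv$event, scale = cfg$scale)
    cover[r] <- f$ci_lo <= 1 && 1 <= f$ci_hi
  }
  expect_gt(mean(cover), 0.85)
})

test_that("survival generator recovers the configured log-hazard", {
  set.seed(132)
  betas <- numeric(60)
  for (r in seq_len(60)) {
    cfg <- sim_config(n_patients = 200, true_beta = 0.5, scale = 1,
                      baseline_hazard = 0.01, seed = 2000 + r)
    z <- rnorm(200)
    surv <- simulate_survival(z, cfg)
    betas[r] <- fit_cox(z, surv$rfs_months, surv$event, scale = 1)$beta
  }
  expect_lt(abs(mean(betas) - 0.5), 0.1)
})

test_that("constant predictors propagate to the non-identifiability error", {
  cfg <- quick_cfg()
  surv <- simulate_survival(rep(1, 10), cfg)
  expect_error(fit_cox(rep(1, 10), surv$rfs_months, surv$event),
               "non-identifiable")
  expect_error(simulate_survival(c(1, NA), cfg), "non-missing")
  expect_error(sim_config(baseline_hazard = 0), "positive")
})

test_that("a written cohort loads back through the disk pipeline formats", {
  td <- withr::local_tempdir()
  cfg <- quick_cfg()
  coh <- simulate_cohort(cfg, dir = td, keep_studies = TRUE)
  expect_true(file.exists(file.path(td, "clinical.csv")))
  expect_true(file.exists(file.path(td, "truth.json")))
  clin <- read_clinical(file.path(td, "clinical.csv"))
  expect_equal(nrow(clin), cfg$n_patients)
  # NIfTI round trip preserves the volumes and geometry
  st_mem <- coh$studies$P001$MRI_1
  st_disk <- read_dce_study(file.path(td, "images", "P001_MRI_1.nii.gz"),
                            patient_id = "P001", visit = "MRI_1")
  expect_equal(st_disk$s0, st_mem$s0, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(st_disk$voxel_size_mm, st_mem$voxel_size_mm,
               tolerance = 1e-5)
  # missing early exams are absent on disk
  missing2 <- vapply(coh$truth$patients, `[[`, logical(1), "missing_mri2")
  ids <- clin$patient_id
  for (i in seq_along(ids)) {
    f <- file.path(td, "images", sprintf("%s_MRI_2.nii.gz", ids[i]))
    expect_equal(file.exists(f), !missing2[i])
  }
})

test_that("tumors exceeding the volume bounds are clipped with a warning", {
  cfg <- sim_config(n_patients = 1, shape = c(12, 12, 6),
                    tumor_radius_mm_range = c(10, 10), seed = 99)
  set.seed(99)
  p <- ftvsweep:::draw_patient(cfg, "P001")
  expect_warning(st <- simulate_study(cfg, p, "MRI_1"), "clipped")
  expect_true(all(dim(attr(st, "tumor_mask")) == cfg$shape))
})
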