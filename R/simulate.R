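#' Configuration for the synthetic DCE-MRI cohort generator
#'
#' The generator emulates the structure of the study cohort: patients with
#' a breast-cancer subtype, three MRI visits (baseline `MRI_1`,
#' early-treatment `MRI_2`, pre-surgery `MRI_f`) each a three-timepoint
#' DCE series, tumors that shrink under treatment, and recurrence-free
#' survival whose hazard depends log-linearly on one FTV predictor
#' evaluated at a known "true" threshold pair. That construction makes
#' threshold recovery a falsifiable property: the sweep should locate the
#' true cell.
#'
#' Tissue model: a fat background with suppressed baseline signal, a
#' parenchyma ellipsoid with weak enhancement, and a tumor ellipsoid with
#' strong enhancement and subtype-dependent washout. Voxelwise `PE_early`
#' and `SER` are drawn per tissue class around per-patient means (patient
#' random effects make neighboring threshold cells correlated, as in real
#' data); `s_early`/`s_late` are reconstructed from them by inverting the
#' enhancement definitions. Visit-dependent shrinkage scales the tumor
#' radii.
#'
#' @param n_patients Cohort size (default 64, the study size).
#' @param subtype_mix Probabilities over subtypes; default reproduces the
#'   study mix of 21 HR+/HER2-, 15 HER2+, 11 TN and 17 unknown out of 64.
#' @param shape Volume dimensions in voxels.
#' @param voxel_size_mm Voxel geometry (default 0.7 x 0.94 x 2.0 mm).
#' @param tumor_radius_mm_range Baseline tumor semi-axis range (mm),
#'   sampled per axis.
#' @param kinetics Per-class kinetic distributions; see Details.
#' @param shrink_mri2_range,shrink_mrif_range Ranges of the per-patient
#'   radius scale factors at `MRI_2` and `MRI_f` (1 = no response,
#'   0 = complete response). `MRI_2` factors are drawn first, then `MRI_f`
#'   is drawn at or below the `MRI_2` factor.
#' @param noise_sd Multiplicative Gaussian intensity noise SD as a fraction
#'   of the class baseline (0 gives exactly invertible kinetics).
#' @param true_thresholds Named `c(pe = , ser = )` threshold pair at which
#'   the hazard-driving predictor is computed.
#' @param true_beta Log hazard ratio per `scale` units of the active
#'   predictor.
#' @param active_predictor Which FTV predictor drives the hazard.
#' @param scale Per-unit divisor of the active predictor (see
#'   [default_scale()]).
#' @param baseline_hazard Exponential event rate per month for a patient
#'   with predictor 0.
#' @param admin_horizon_months Administrative censoring horizon.
#' @param dropout_rate Exponential random-dropout rate per month.
#' @param missing_mri2_rate Probability a patient's early-treatment exam is
#'   missing (the study lost 14/64).
#' @param min_cluster_voxels,connectivity,s0_floor FTV settings used when
#'   computing the hazard-driving predictor.
#' @param seed Integer seed; identical configuration and seed give a
#'   bit-identical cohort.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 64,
                       subtype_mix = c(HRpos_HER2neg = 21, HER2pos = 15,
                                       TN = 11, unknown = 17) / 64,
                       shape = c(32, 32, 16),
                       voxel_size_mm = c(0.7, 0.94, 2.0),
                       tumor_radius_mm_range = c(5, 8),
                       kinetics = default_kinetics(),
                       shrink_mri2_range = c(0.55, 1.0),
                       shrink_mrif_range = c(0.3, 1.0),
                       noise_sd = 0.02,
                       true_thresholds = c(pe = 100, ser = 1.0),
                       true_beta = 0.5,
                       active_predictor = "ftv_f",
                       scale = NULL,
                       baseline_hazard = 0.005,
                       admin_horizon_months = 120,
                       dropout_rate = 0.002,
                       missing_mri2_rate = 0.2,
                       min_cluster_voxels = 8,
                       connectivity = 26,
                       s0_floor = NULL,
                       seed = 1L) {
  subtype_mix <- subtype_mix / sum(subtype_mix)
  if (any(subtype_mix < 0)) stop("subtype probabilities must be non-negative",
                                 call. = FALSE)
  if (baseline_hazard <= 0) stop("'baseline_hazard' must be positive",
                                 call. = FALSE)
  if (any(tumor_radius_mm_range <= 0)) stop("tumor radii must be positive",
                                            call. = FALSE)
  stopifnot(shrink_mri2_range[1] >= 0, shrink_mri2_range[2] <= 1,
            shrink_mrif_range[1] >= 0, shrink_mrif_range[2] <= 1)
  active_predictor <- match.arg(active_predictor,
                                c("delta_ftv2", "delta_ftvf", "ftv_f"))
  # hazard unit matched to the phantom's scaled-down geometry: simulated
  # tumors are tenths of a cc where clinical tumors are tens, so the
  # absolute-volume predictor acts per 0.1 cc; percent-change predictors
  # keep their per-10-percentage-point unit
  if (is.null(scale))
    scale <- if (active_predictor == "ftv_f") 0.1
             else default_scale(active_predictor)
  structure(list(n_patients = n_patients, subtype_mix = subtype_mix,
                 shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
                 tumor_radius_mm_range = tumor_radius_mm_range,
                 kinetics = kinetics,
                 shrink_mri2_range = shrink_mri2_range,
                 shrink_mrif_range = shrink_mrif_range,
                 noise_sd = noise_sd,
                 true_thresholds = true_thresholds, true_beta = true_beta,
                 active_predictor = active_predictor, scale = scale,
                 baseline_hazard = baseline_hazard,
                 admin_horizon_months = admin_horizon_months,
                 dropout_rate = dropout_rate,
                 missing_mri2_rate = missing_mri2_rate,
                 min_cluster_voxels = min_cluster_voxels,
                 connectivity = connectivity, s0_floor = s0_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default per-tissue kinetic distributions
#'
#' Means and SDs of the voxelwise early percent enhancement and SER, by
#' tissue class; tumor SER means differ by subtype (HER2+ tumors wash out
#' fastest, HR+/HER2- slowest, consistent with the washout-kinetics
#' gradient across subtypes). `patient_sd` terms are per-patient random
#' effects on the class mean.
#'
#' @return Nested list of kinetic parameters.
#' @export
default_kinetics <- function() {
  list(
    fat = list(s0 = 40, s0_sd = 8, pe = 0, pe_sd = 4),
    parenchyma = list(s0 = 300, s0_sd = 30, pe = 30, pe_sd = 15,
                      ser = 0.7, ser_sd = 0.2),
    tumor = list(s0 = 400, s0_sd = 40,
                 pe = 135, pe_patient_sd = 50, pe_sd = 12,
                 ser_by_subtype = c(HRpos_HER2neg = 0.95, HER2pos = 1.25,
                                    TN = 1.1, unknown = 1.05),
                 ser_patient_sd = 0.25, ser_sd = 0.15))
}

# ellipsoid membership mask on the voxel grid, in mm coordinates
ellipsoid_mask <- function(shape, voxel_size_mm, center_mm, radii_mm) {
  cx <- (seq_len(shape[1]) - 0.5) * voxel_size_mm[1]
  cy <- (seq_len(shape[2]) - 0.5) * voxel_size_mm[2]
  cz <- (seq_len(shape[3]) - 0.5) * voxel_size_mm[3]
  dx2 <- ((cx - center_mm[1]) / radii_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / radii_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / radii_mm[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# per-patient latent parameters drawn once; visits reuse them
draw_patient <- function(cfg, id) {
  subtype <- sample(names(cfg$subtype_mix), 1, prob = cfg$subtype_mix)
  fov <- cfg$shape * cfg$voxel_size_mm
  radii <- stats::runif(3, cfg$tumor_radius_mm_range[1],
                        cfg$tumor_radius_mm_range[2])
  center <- fov / 2 + stats::runif(3, -0.08, 0.08) * fov
  f2 <- stats::runif(1, cfg$shrink_mri2_range[1], cfg$shrink_mri2_range[2])
  ff <- min(f2, stats::runif(1, cfg$shrink_mrif_range[1],
                             cfg$shrink_mrif_range[2]))
  tk <- cfg$kinetics$tumor
  list(patient_id = id, subtype = subtype,
       radii_mm = radii, center_mm = center,
       shrink = c(MRI_1 = 1, MRI_2 = f2, MRI_f = ff),
       pe_mu = stats::rnorm(1, tk$pe, tk$pe_patient_sd),
       ser_mu = stats::rnorm(1, tk$ser_by_subtype[[subtype]],
                             tk$ser_patient_sd),
       missing_mri2 = stats::runif(1) < cfg$missing_mri2_rate)
}

#' Simulate one DCE-MRI study (one patient visit)
#'
#' Builds the pre-contrast volume from per-class baselines plus Gaussian
#' noise, draws voxelwise `PE_early` and `SER`, and reconstructs the two
#' post-contrast volumes by inverting the enhancement definitions:
#' `s_early = s0 (1 + PE/100)` and `s_late = s0 (1 + (PE/SER)/100)`.
#' Tumor radii are scaled by the visit's shrinkage factor. With
#' `noise_sd = 0` and degenerate (zero-SD) kinetics the enhancement module
#' recovers the configured PE and SER exactly.
#'
#' @param cfg A [sim_config()].
#' @param patient Internal per-patient parameter list (from the cohort
#'   generator); [simulate_cohort()] is the usual entry point.
#' @param visit `"MRI_1"`, `"MRI_2"` or `"MRI_f"`.
#' @return A [dce_study()] with attributes `tumor_mask` (ground-truth
#'   ellipsoid membership) and `truth` (the patient's latent parameters).
#' @export
simulate_study <- function(cfg, patient, visit = "MRI_1") {
  stopifnot(inherits(cfg, "sim_config"))
  shape <- cfg$shape
  kin <- cfg$kinetics
  fov <- shape * cfg$voxel_size_mm

  # tissue classes: fat background, central parenchyma, tumor ellipsoid
  parenchyma <- ellipsoid_mask(shape, cfg$voxel_size_mm, fov / 2, fov * 0.42)
  radii <- patient$radii_mm * patient$shrink[[visit]]
  tumor <- if (all(radii > 0))
    ellipsoid_mask(shape, cfg$voxel_size_mm, patient$center_mm, radii)
  else array(FALSE, shape)
  if (any(patient$center_mm - radii < 0) ||
      any(patient$center_mm + radii > fov))
    warning("tumor of patient ", patient$patient_id,
            " exceeds the volume bounds; clipped", call. = FALSE)
  if (any(tumor & !parenchyma)) {
    # keep the lesion inside the breast-tissue compartment
    tumor <- tumor & parenchyma
  }

  nvox <- prod(shape)
  s0 <- array(stats::rnorm(nvox, kin$fat$s0, kin$fat$s0_sd), shape)
  s0[parenchyma] <- stats::rnorm(sum(parenchyma), kin$parenchyma$s0,
                                 kin$parenchyma$s0_sd)
  s0[tumor] <- stats::rnorm(sum(tumor), kin$tumor$s0, kin$tumor$s0_sd)
  s0 <- pmax(s0, 1)

  pe <- array(stats::rnorm(nvox, kin$fat$pe, kin$fat$pe_sd), shape)
  ser <- array(1, shape)  # fat: no washout structure
  np <- sum(parenchyma)
  pe[parenchyma] <- stats::rnorm(np, kin$parenchyma$pe, kin$parenchyma$pe_sd)
  ser[parenchyma] <- stats::rnorm(np, kin$parenchyma$ser,
                                  kin$parenchyma$ser_sd)
  nt <- sum(tumor)
  pe[tumor] <- stats::rnorm(nt, patient$pe_mu, kin$tumor$pe_sd)
  ser[tumor] <- stats::rnorm(nt, patient$ser_mu, kin$tumor$ser_sd)
  ser <- pmax(ser, 0.2)  # washout ratios below 0.2 are not physiological

  s_early <- s0 * (1 + pe / 100)
  s_late <- s0 * (1 + (pe / ser) / 100)
  if (cfg$noise_sd > 0) {
    s_early <- s_early * (1 + stats::rnorm(nvox, 0, cfg$noise_sd))
    s_late <- s_late * (1 + stats::rnorm(nvox, 0, cfg$noise_sd))
  }
  study <- dce_study(pmax(s0, 0), pmax(s_early, 0), pmax(s_late, 0),
                     voxel_size_mm = cfg$voxel_size_mm,
                     patient_id = patient$patient_id, visit = visit)
  attr(study, "tumor_mask") <- tumor
  attr(study, "truth") <- patient
  study
}

#' VOI specification covering a patient's tumor
#'
#' Builds the two orthogonal rectangular projection ROIs from the
#' ground-truth tumor bounding box at baseline plus a margin, emulating
#' ROIs placed on maximum-intensity projections.
#'
#' @param cfg A [sim_config()].
#' @param patient Per-patient parameter list.
#' @param margin_mm Margin added around the tumor bounding box.
#' @return A [voi_spec()] (projections along axes 3 and 1).
#' @export
simulate_voi_spec <- function(cfg, patient, margin_mm = 4) {
  lo_mm <- patient$center_mm - patient$radii_mm - margin_mm
  hi_mm <- patient$center_mm + patient$radii_mm + margin_mm
  lo <- pmax(0L, as.integer(floor(lo_mm / cfg$voxel_size_mm)))
  hi <- pmin(cfg$shape, as.integer(ceiling(hi_mm / cfg$voxel_size_mm)))
  hi <- pmax(hi, lo + 1L)
  voi_spec(
    roi_a = list(axis = 3, rect = list(c(lo[1], hi[1]), c(lo[2], hi[2]))),
    roi_b = list(axis = 1, rect = list(c(lo[2], hi[2]), c(lo[3], hi[3]))))
}

#' Simulate survival outcomes from a predictor
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(true_beta * z / scale)`; censoring is the
#' earlier of an administrative horizon and exponential random dropout.
#'
#' @param z Per-patient values of the active predictor evaluated at the
#'   true thresholds (non-missing).
#' @param cfg A [sim_config()].
#' @return Data frame with `rfs_months` and `event`.
#' @export
simulate_survival <- function(z, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (anyNA(z)) stop("predictor 'z' must be non-missing for all patients",
                     call. = FALSE)
  n <- length(z)
  rate <- cfg$baseline_hazard * exp(cfg$true_beta * z / cfg$scale)
  t_event <- stats::rexp(n, rate)
  t_drop <- if (cfg$dropout_rate > 0) stats::rexp(n, cfg$dropout_rate)
            else rep(Inf, n)
  t_cens <- pmin(t_drop, cfg$admin_horizon_months)
  data.frame(rfs_months = pmax(pmin(t_event, t_cens), 1e-6),
             event = as.integer(t_event <= t_cens))
}

#' Simulate a full synthetic cohort
#'
#' Draws the patient table (subtype, geometry, response, kinetics), builds
#' every visit's DCE study, computes the hazard-driving predictor at the
#' true thresholds through the actual enhancement/FTV pipeline, simulates
#' survival from it, and finally applies early-exam missingness. With
#' `keep_studies = TRUE` the studies stay in memory; with `dir` set, the
#' cohort is written to disk in the formats the pipeline reads (4D NIfTI
#' per visit, VOI JSON per patient, clinical CSV, ground-truth JSON).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @param keep_studies Keep the simulated volumes in the returned object.
#' @param visits Visits to generate (all three by default); must include
#'   the visits the active predictor needs. Restricting visits changes the
#'   random stream, so it defines a different (smaller) cohort.
#' @return Object of class `sim_cohort`: list with `clinical` (a
#'   [survival_records()] table), `truth` (per-patient ground truth
#'   including `z`), `voi_specs`, and optionally `studies` (per patient, a
#'   named list of visits).
#' @export
simulate_cohort <- function(cfg, dir = NULL, keep_studies = is.null(dir),
                            visits = c("MRI_1", "MRI_2", "MRI_f")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ids <- sprintf("P%03d", seq_len(cfg$n_patients))
  patients <- lapply(ids, function(id) draw_patient(cfg, id))

  visits_needed <- switch(cfg$active_predictor,
                          delta_ftv2 = c("MRI_1", "MRI_2"),
                          delta_ftvf = c("MRI_1", "MRI_f"),
                          ftv_f = c("MRI_1", "MRI_f"))
  all_visits <- match.arg(visits, c("MRI_1", "MRI_2", "MRI_f"),
                          several.ok = TRUE)
  if (!all(visits_needed %in% all_visits))
    stop("'visits' must include those needed by the active predictor: ",
         paste(visits_needed, collapse = ", "), call. = FALSE)

  z <- numeric(cfg$n_patients)
  studies <- if (keep_studies || !is.null(dir)) vector("list", cfg$n_patients)
  voi_specs <- vector("list", cfg$n_patients)

  for (i in seq_along(patients)) {
    p <- patients[[i]]
    spec <- simulate_voi_spec(cfg, p)
    voi_specs[[i]] <- spec
    voi <- suppressWarnings(voi_mask(spec, cfg$shape))
    vis <- lapply(stats::setNames(all_visits, all_visits),
                  function(v) simulate_study(cfg, p, v))
    box <- mask_bbox(voi)
    ftv_true <- vapply(vis[visits_needed], function(st) {
      floor_i <- cfg$s0_floor %||% default_s0_floor(st$s0)
      if (!is.null(box)) {
        st_c <- crop_study(st, box)
        voi_c <- crop_mask(voi, box)
      } else {
        st_c <- st; voi_c <- voi
      }
      maps <- enhancement_maps(st_c, s0_floor = floor_i)
      compute_ftv(st_c, maps, voi_c, cfg$true_thresholds[["pe"]],
                  cfg$true_thresholds[["ser"]],
                  cfg$min_cluster_voxels, cfg$connectivity)
    }, numeric(1))
    z[i] <- switch(cfg$active_predictor,
                   delta_ftv2 = ,
                   delta_ftvf = {
                     if (ftv_true[["MRI_1"]] == 0) 0
                     else (ftv_true[[2]] - ftv_true[["MRI_1"]]) /
                       ftv_true[["MRI_1"]] * 100
                   },
                   ftv_f = ftv_true[["MRI_f"]])
    if (keep_studies || !is.null(dir)) studies[[i]] <- vis
  }

  surv <- simulate_survival(z, cfg)
  clinical <- survival_records(data.frame(
    patient_id = ids,
    subtype = vapply(patients, `[[`, character(1), "subtype"),
    rfs_months = surv$rfs_months, event = surv$event))

  # apply early-exam missingness after the ground-truth z is fixed
  for (i in seq_along(patients)) {
    if (patients[[i]]$missing_mri2 && !is.null(studies[[i]]))
      studies[[i]]$MRI_2 <- NULL
  }

  truth <- list(true_thresholds = cfg$true_thresholds,
                true_beta = cfg$true_beta,
                active_predictor = cfg$active_predictor,
                scale = cfg$scale, z = stats::setNames(z, ids),
                patients = patients)
  out <- structure(list(cfg = cfg, clinical = clinical, truth = truth,
                        voi_specs = stats::setNames(voi_specs, ids)),
                   class = "sim_cohort")
  if (keep_studies) out$studies <- stats::setNames(studies, ids)
  if (!is.null(dir)) write_cohort(out, studies, dir)
  out
}

# write NIfTI volumes, VOI JSONs, clinical CSV and ground-truth JSON
write_cohort <- function(cohort, studies, dir) {
  img_dir <- file.path(dir, "images")
  voi_dir <- file.path(dir, "voi")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(voi_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$clinical$patient_id
  for (i in seq_along(ids)) {
    for (v in names(studies[[i]])) {
      st <- studies[[i]][[v]]
      vol4d <- array(c(st$s0, st$s_early, st$s_late), c(dim(st$s0), 3L))
      img <- RNifti::asNifti(vol4d, reference = NULL)
      RNifti::pixdim(img) <- c(cohort$cfg$voxel_size_mm, 1)
      RNifti::writeNifti(img, file.path(img_dir,
                                        sprintf("%s_%s.nii.gz", ids[i], v)))
    }
    write_voi_spec(cohort$voi_specs[[i]],
                   file.path(voi_dir, paste0(ids[i], ".json")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(true_thresholds = as.list(cohort$truth$true_thresholds),
                            true_beta = cohort$truth$true_beta,
                            active_predictor = cohort$truth$active_predictor,
                            scale = cohort$truth$scale,
                            z = as.list(cohort$truth$z)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic DCE-MRI cohort: %d patients (seed %d)\n",
              nrow(x$clinical), x$cfg$seed))
  print(table(x$clinical$subtype))
  cat(sprintf("events %d/%d; hazard driven by %s at (PE %g%%, SER %g), beta %g per %g\n",
              sum(x$clinical$event), nrow(x$clinical),
              x$truth$active_predictor, x$truth$true_thresholds[["pe"]],
              x$truth$true_thresholds[["ser"]], x$truth$true_beta,
              x$truth$scale))
  if (!is.null(x$studies)) cat("volumes kept in memory ($studies)\n")
  invisible(x)
}
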