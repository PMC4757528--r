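#' Read one visit's DCE series from NIfTI
#'
#' Accepts either one 4D file with the timepoint axis last (order: pre,
#' early post, late post) or three 3D files. For three files, the affines
#' must agree to 1e-4.
#'
#' @param path Path to a 4D NIfTI file, or character vector of three 3D
#'   NIfTI paths in (t0, t1, t2) order.
#' @param patient_id,visit Identifiers for the resulting study.
#' @param voxel_size_mm Override voxel geometry; default taken from the
#'   NIfTI header (`pixdim`).
#' @return A [dce_study()].
#' @export
read_dce_study <- function(path, patient_id = "unknown", visit = "MRI_1",
                           voxel_size_mm = NULL) {
  if (length(path) == 1L) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L || d[4] != 3L)
      stop("'", path, "' must be 4D with 3 timepoints on the last axis",
           call. = FALSE)
    if (is.null(voxel_size_mm))
      voxel_size_mm <- RNifti::pixdim(img)[1:3]
    arr <- as.array(img)
    return(dce_study(arr[, , , 1], arr[, , , 2], arr[, , , 3],
                     voxel_size_mm = voxel_size_mm,
                     patient_id = patient_id, visit = visit))
  }
  if (length(path) != 3L)
    stop("'path' must be one 4D or three 3D NIfTI files", call. = FALSE)
  imgs <- lapply(path, RNifti::readNifti)
  affines <- lapply(imgs, function(i) RNifti::xform(i))
  for (k in 2:3)
    if (max(abs(affines[[k]] - affines[[1]])) > 1e-4)
      stop("affine mismatch between '", path[1], "' and '", path[k], "'",
           call. = FALSE)
  if (is.null(voxel_size_mm))
    voxel_size_mm <- RNifti::pixdim(imgs[[1]])[1:3]
  dce_study(as.array(imgs[[1]]), as.array(imgs[[2]]), as.array(imgs[[3]]),
            voxel_size_mm = voxel_size_mm,
            patient_id = patient_id, visit = visit)
}

# bounding box (list of index ranges) of a logical mask; NULL when empty
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  lapply(1:3, function(k) range(w[, k]))
}

# restrict a study and companion masks to a box; FTV counts only VOI
# voxels and connected components live inside the VOI, so computing on the
# VOI bounding box is exact (the s0 validity floor must be supplied, since
# its default would otherwise be estimated from the cropped volume)
crop_study <- function(study, box) {
  sub <- function(a) a[box[[1]][1]:box[[1]][2], box[[2]][1]:box[[2]][2],
                       box[[3]][1]:box[[3]][2], drop = FALSE]
  dce_study(sub(study$s0), sub(study$s_early), sub(study$s_late),
            voxel_size_mm = study$voxel_size_mm,
            patient_id = study$patient_id, visit = study$visit)
}

crop_mask <- function(mask, box) {
  mask[box[[1]][1]:box[[1]][2], box[[2]][1]:box[[2]][2],
       box[[3]][1]:box[[3]][2], drop = FALSE]
}

#' Per-patient FTV surfaces and predictors for a whole cohort
#'
#' Runs the imaging stages (enhancement maps, VOI mask, FTV surface per
#' visit, predictor record) for every patient of an in-memory simulated
#' cohort. Each patient is processed independently.
#'
#' @param cohort A [simulate_cohort()] result with `studies` kept.
#' @param grid A [threshold_grid()].
#' @param visits Visits to process (default all present); restricting to
#'   the visits a predictor needs skips unused surface computations.
#' @param s0_floor,min_cluster_voxels,connectivity FTV settings; defaults
#'   from the cohort configuration.
#' @return A [predictor_array()] list.
#' @export
cohort_predictors <- function(cohort, grid = default_grid(),
                              visits = c("MRI_1", "MRI_2", "MRI_f"),
                              s0_floor = cohort$cfg$s0_floor,
                              min_cluster_voxels = cohort$cfg$min_cluster_voxels,
                              connectivity = cohort$cfg$connectivity) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(cohort$studies))
    stop("cohort was simulated without keep_studies = TRUE", call. = FALSE)
  ids <- cohort$clinical$patient_id
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    vis <- cohort$studies[[i]]
    vis <- vis[intersect(names(vis), visits)]
    voi <- suppressWarnings(voi_mask(cohort$voi_specs[[i]],
                                     dim(vis[[1]]$s0)))
    box <- mask_bbox(voi)
    surfaces <- lapply(vis, function(st) {
      floor_i <- s0_floor %||% default_s0_floor(st$s0)
      if (!is.null(box)) {
        st_c <- crop_study(st, box)
        voi_c <- crop_mask(voi, box)
      } else {
        st_c <- st; voi_c <- voi
      }
      maps <- enhancement_maps(st_c, s0_floor = floor_i)
      ftv_surface(st_c, maps, voi_c, grid, min_cluster_voxels, connectivity)
    })
    records[[i]] <- build_predictors(surfaces, patient_id = ids[i],
                                     subtype = cohort$clinical$subtype[i])
  }
  predictor_array(records)
}

#' Run configuration for the end-to-end analysis
#'
#' @param clinical_csv Clinical table path.
#' @param image_dir Directory of `<patient>_<visit>.nii(.gz)` files.
#' @param voi_dir Directory of `<patient>.json` VOI specifications.
#' @param out_dir Output directory.
#' @param grid A [threshold_grid()].
#' @param s0_floor,min_cluster_voxels,connectivity FTV settings
#'   (`s0_floor = NULL` uses the per-study default).
#' @param predictors Predictors to sweep.
#' @param subsets Cohort subsets to analyze; `"full"` keeps every patient
#'   including unknown subtype, subtype subsets exclude the others.
#' @param scales Optional named per-predictor scales.
#' @param seed Seed echoed into the manifest (the analysis itself is
#'   deterministic given its inputs).
#' @return Object of class `run_config`.
#' @export
run_config <- function(clinical_csv, image_dir, voi_dir, out_dir,
                       grid = default_grid(),
                       s0_floor = NULL, min_cluster_voxels = 8,
                       connectivity = 26,
                       predictors = c("delta_ftv2", "delta_ftvf", "ftv_f"),
                       subsets = c("full", "HRpos_HER2neg", "HER2pos", "TN"),
                       scales = NULL, seed = 1L) {
  dc <- default_cell()
  if (!(dc[["pe_t"]] %in% grid$pe_thresholds &&
        dc[["ser_t"]] %in% grid$ser_thresholds))
    stop("the default cell (70%, 0.0) must lie on the grid", call. = FALSE)
  bad <- setdiff(subsets, c("full", "HRpos_HER2neg", "HER2pos", "TN",
                            "unknown"))
  if (length(bad)) stop("unknown subset label '", bad[1], "'", call. = FALSE)
  predictors <- match.arg(predictors,
                          c("delta_ftv2", "delta_ftvf", "ftv_f"),
                          several.ok = TRUE)
  structure(list(clinical_csv = clinical_csv, image_dir = image_dir,
                 voi_dir = voi_dir, out_dir = out_dir, grid = grid,
                 s0_floor = s0_floor,
                 min_cluster_voxels = min_cluster_voxels,
                 connectivity = connectivity, predictors = predictors,
                 subsets = subsets, scales = scales, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path Configuration file; keys as in [run_config()], with `grid`
#'   given as `pe_thresholds` / `ser_thresholds` vectors.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("clinical_csv", "image_dir", "voi_dir", "out_dir")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("config is missing required key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  grid <- if (!is.null(x$pe_thresholds) || !is.null(x$ser_thresholds))
    threshold_grid(x$pe_thresholds %||% seq(30, 200, 10),
                   x$ser_thresholds %||% seq(0, 2, 0.2))
  else default_grid()
  run_config(x$clinical_csv, x$image_dir, x$voi_dir, x$out_dir, grid = grid,
             s0_floor = x$s0_floor,
             min_cluster_voxels = x$min_cluster_voxels %||% 8,
             connectivity = x$connectivity %||% 26,
             predictors = x$predictors %||% c("delta_ftv2", "delta_ftvf",
                                              "ftv_f"),
             subsets = x$subsets %||% c("full", "HRpos_HER2neg", "HER2pos",
                                        "TN"),
             seed = x$seed %||% 1L)
}

#' Run the end-to-end FTV threshold analysis
#'
#' Loads the cohort from disk (clinical CSV, per-visit NIfTI images, VOI
#' JSONs), computes FTV surfaces and predictors for every patient, sweeps
#' Cox models per subset and predictor, selects the optimized cell, and
#' writes per-sweep CSV tables, optimized-vs-default comparison rows, heat
#' maps, a machine-readable report and a manifest with input hashes.
#' Patients without a baseline image are dropped with a warning; a subset
#' that is empty or yields no eligible cells is reported, not fatal.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the run report (also written as `report.json`).
#' @export
run_analysis <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  info <- function(...) if (!quiet) message(sprintf(...))
  clinical <- read_clinical(cfg$clinical_csv)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  records <- list()
  used_files <- character(0)
  dropped <- character(0)
  for (i in seq_len(nrow(clinical))) {
    pid <- clinical$patient_id[i]
    files <- vapply(c("MRI_1", "MRI_2", "MRI_f"), function(v) {
      f <- file.path(cfg$image_dir, sprintf("%s_%s.nii.gz", pid, v))
      if (!file.exists(f))
        f <- file.path(cfg$image_dir, sprintf("%s_%s.nii", pid, v))
      if (file.exists(f)) f else NA_character_
    }, character(1))
    if (is.na(files[["MRI_1"]])) {
      warning("patient ", pid, " has no baseline image; dropped",
              call. = FALSE)
      dropped <- c(dropped, pid)
      next
    }
    voi_file <- file.path(cfg$voi_dir, paste0(pid, ".json"))
    if (!file.exists(voi_file))
      stop("missing VOI specification for patient ", pid, call. = FALSE)
    spec <- read_voi_spec(voi_file)
    surfaces <- list()
    for (v in names(files)[!is.na(files)]) {
      st <- read_dce_study(files[[v]], patient_id = pid, visit = v)
      floor_v <- cfg$s0_floor %||% default_s0_floor(st$s0)
      voi <- suppressWarnings(voi_mask(spec, dim(st$s0)))
      box <- mask_bbox(voi)
      if (!is.null(box)) {
        st <- crop_study(st, box)
        voi <- crop_mask(voi, box)
      }
      maps <- enhancement_maps(st, s0_floor = floor_v)
      surfaces[[v]] <- ftv_surface(st, maps, voi, cfg$grid,
                                   cfg$min_cluster_voxels, cfg$connectivity)
    }
    records[[length(records) + 1L]] <-
      build_predictors(surfaces, patient_id = pid,
                       subtype = clinical$subtype[i])
    used_files <- c(used_files, files[!is.na(files)], voi_file)
    info("patient %s: %d visit(s)", pid, sum(!is.na(files)))
  }
  if (!length(records)) stop("no patients with baseline imaging",
                             call. = FALSE)
  predictors <- predictor_array(records)

  # long-format surface export reconstructed from the predictor arrays is
  # lossy (deltas); write surfaces per patient is covered by sweep CSVs.
  comparisons <- list()
  report_sweeps <- list()
  for (subset in cfg$subsets) for (pred in cfg$predictors) {
    sw <- tryCatch(
      sweep_cox(predictors, clinical, cfg$grid, pred, subset,
                scale = cfg$scales[[pred]]),
      error = function(e) e)
    key <- paste(subset, pred, sep = "_")
    if (inherits(sw, "error")) {
      info("sweep %s: skipped (%s)", key, conditionMessage(sw))
      report_sweeps[[key]] <- list(subset = subset, predictor = pred,
                                   skipped = conditionMessage(sw))
      next
    }
    utils::write.csv(sweep_table(sw),
                     file.path(cfg$out_dir, paste0("sweep_", key, ".csv")),
                     row.names = FALSE)
    render_heatmaps(sw, heatmap_style(), cfg$out_dir)
    comparisons[[key]] <- comparison_row(sw)
    report_sweeps[[key]] <- list(
      subset = subset, predictor = pred,
      n_patients = max(sw$n, na.rm = TRUE),
      n_events = max(sw$events, na.rm = TRUE),
      n_fits = sw$n_fits, n_significant = sw$n_significant,
      n_degenerate = sum(sw$degenerate),
      optimized_cell = if (is.null(sw$optimized_cell)) NULL
                       else as.list(sw$optimized_cell[1:2]))
    info("sweep %s: %d fits, %d significant, optimum %s", key, sw$n_fits,
         sw$n_significant,
         if (is.null(sw$optimized_cell)) "none"
         else sprintf("(%g%%, %g)", sw$optimized_cell[["pe_t"]],
                      sw$optimized_cell[["ser_t"]]))
  }
  comparison <- do.call(rbind, comparisons)
  if (!is.null(comparison))
    utils::write.csv(comparison, file.path(cfg$out_dir, "comparison.csv"),
                     row.names = FALSE)

  report <- list(n_clinical = nrow(clinical),
                 n_analyzed = length(records),
                 dropped_patients = dropped,
                 grid_cells = length(cfg$grid$pe_thresholds) *
                   length(cfg$grid$ser_thresholds),
                 sweeps = report_sweeps)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(config = cfg[setdiff(names(cfg), "grid")],
                   pe_thresholds = cfg$grid$pe_thresholds,
                   ser_thresholds = cfg$grid$ser_thresholds,
                   input_md5 = as.list(tools::md5sum(
                     c(cfg$clinical_csv, sort(unique(used_files))))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Collect run outputs into summary tables
#'
#' Reads a finished run directory and returns the optimized-vs-default
#' comparison rows, one table per subset, in the shape of the clinical
#' summary tables (hazard ratio, 95% CI and p at the optimized and default
#' cells, per predictor).
#'
#' @param run_dir A [run_analysis()] output directory.
#' @return Named list of data.frames, one per subset present.
#' @export
run_report <- function(run_dir) {
  f <- file.path(run_dir, "comparison.csv")
  if (!file.exists(f))
    stop("no comparison.csv under '", run_dir, "'; run the analysis first",
         call. = FALSE)
  comp <- utils::read.csv(f, stringsAsFactors = FALSE)
  split(comp, comp$subset)
}
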