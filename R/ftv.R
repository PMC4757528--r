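#' Threshold grid for the FTV sweep
#'
#' The default grid is the one swept in the analysis: PE thresholds from 30%
#' to 200% in steps of 10% (18 values) crossed with SER thresholds from 0.0
#' to 2.0 in steps of 0.2 (11 values), 198 cells. The default operating cell
#' is PE_t = 70%, SER_t = 0.
#'
#' @param pe_thresholds Strictly increasing percent values.
#' @param ser_thresholds Strictly increasing ratio values.
#' @return Object of class `threshold_grid`.
#' @export
threshold_grid <- function(pe_thresholds = seq(30, 200, by = 10),
                           ser_thresholds = seq(0, 2, by = 0.2)) {
  pe_thresholds <- as.numeric(pe_thresholds)
  ser_thresholds <- as.numeric(ser_thresholds)
  if (length(pe_thresholds) < 1L || any(diff(pe_thresholds) <= 0))
    stop("'pe_thresholds' must be strictly increasing", call. = FALSE)
  if (length(ser_thresholds) < 1L || any(diff(ser_thresholds) <= 0))
    stop("'ser_thresholds' must be strictly increasing", call. = FALSE)
  structure(list(pe_thresholds = pe_thresholds,
                 ser_thresholds = ser_thresholds),
            class = "threshold_grid")
}

#' @rdname threshold_grid
#' @export
default_grid <- function() threshold_grid()

#' Default FTV operating cell
#' @return Named numeric `c(pe_t = 70, ser_t = 0)`.
#' @export
default_cell <- function() c(pe_t = 70, ser_t = 0)

#' Label connected components of a 3D mask
#'
#' Union-find labeling with configurable 3D connectivity (6 face neighbors,
#' 18 face+edge, or 26 face+edge+corner).
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26, the most permissive).
#' @return Integer 3D array; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a logical 3D array", call. = FALSE)
  .label_components_3d(mask, dim(mask), as.integer(connectivity))
}

#' Remove small connected components from a mask
#'
#' @param mask Logical 3D array.
#' @param min_voxels Minimum component size (in voxels) to keep.
#' @param connectivity Neighborhood for component definition.
#' @return Logical 3D array with every component smaller than `min_voxels`
#'   removed.
#' @export
filter_small_components <- function(mask, min_voxels, connectivity = 26) {
  if (min_voxels < 1) stop("'min_voxels' must be >= 1", call. = FALSE)
  if (min_voxels == 1 || !any(mask)) return(mask)
  # label only the bounding box of the foreground; components cannot extend
  # beyond it, so the result is identical to labeling the full volume
  w <- which(mask, arr.ind = TRUE)
  rng <- lapply(1:3, function(k) range(w[, k]))
  sub <- mask[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
              rng[[3]][1]:rng[[3]][2], drop = FALSE]
  lab <- label_components(array(sub, dim = vapply(rng, diff, 0) + 1L),
                          connectivity)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < min_voxels)
  if (length(small)) sub[array(lab %in% small, dim(lab))] <- FALSE
  out <- array(FALSE, dim(mask))
  out[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
      rng[[3]][1]:rng[[3]][2]] <- sub
  out
}

#' Default minimum cluster size for the enhancing-tissue mask
#'
#' The connectivity test removes "very small regions" from the thresholded
#' PE map. The default is the voxel count closest to a 0.01 cc cluster at
#' the given voxel geometry (8 voxels at 0.7 x 0.94 x 2.0 mm).
#'
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @param min_volume_cc Smallest cluster volume retained, in cc.
#' @return Integer voxel count, at least 1.
#' @export
default_min_cluster_voxels <- function(voxel_size_mm = c(0.7, 0.94, 2.0),
                                       min_volume_cc = 0.01) {
  max(1L, as.integer(round(min_volume_cc / (prod(voxel_size_mm) / 1000))))
}

#' Enhancing-tissue mask at a PE threshold
#'
#' Applies the minimum early-enhancement threshold `pe_t` to the PE map
#' inside the VOI, then the connectivity test that removes components
#' smaller than `min_cluster_voxels`.
#'
#' @param maps `enhancement_maps` with `pe_early` and `valid` filled.
#' @param voi Logical 3D VOI mask (same shape).
#' @param pe_t Minimum early percent enhancement (closed comparison, `>=`).
#' @param min_cluster_voxels Minimum connected-component size retained.
#' @param connectivity 6, 18 or 26.
#' @return Logical 3D array.
#' @export
enhancing_mask <- function(maps, voi, pe_t, min_cluster_voxels = 8,
                           connectivity = 26) {
  stopifnot(inherits(maps, "enhancement_maps"))
  if (!identical(dim(voi), dim(maps$pe_early)))
    stop("VOI mask shape does not match the enhancement maps", call. = FALSE)
  raw <- maps$valid & voi & !is.na(maps$pe_early) & maps$pe_early >= pe_t
  filter_small_components(raw, min_cluster_voxels, connectivity)
}

#' Functional tumor volume at one threshold pair
#'
#' FTV is the volume of all VOI voxels that pass the PE threshold (with
#' small-region removal) and whose SER is at least `ser_t`. The order of
#' operations is fixed: PE threshold, then connectivity filter, then SER
#' threshold. Closed (`>=`) comparisons mean `ser_t = 0` gates nothing with
#' non-negative SER, reproducing the default-setting behavior.
#'
#' @param study A [dce_study()] (supplies voxel geometry).
#' @param maps `enhancement_maps` with `ser` filled.
#' @param voi Logical VOI mask.
#' @param pe_t,ser_t Thresholds.
#' @inheritParams enhancing_mask
#' @return Volume in cc (single non-negative number).
#' @export
compute_ftv <- function(study, maps, voi, pe_t, ser_t,
                        min_cluster_voxels = 8, connectivity = 26) {
  stopifnot(inherits(study, "dce_study"))
  if (is.null(maps$ser)) stop("SER map not computed; run compute_ser_map()",
                              call. = FALSE)
  m <- enhancing_mask(maps, voi, pe_t, min_cluster_voxels, connectivity)
  n_pass <- sum(maps$ser[m] >= ser_t, na.rm = TRUE)
  n_pass * voxel_volume_cc(study)
}

#' FTV over the full threshold grid
#'
#' Evaluates [compute_ftv()] at every grid cell, sharing the PE-thresholded,
#' connectivity-filtered mask across SER thresholds within each row.
#'
#' @inheritParams compute_ftv
#' @param grid A [threshold_grid()].
#' @return Object of class `ftv_surface`: a `|pe| x |ser|` matrix of volumes
#'   in cc with `dimnames` giving the thresholds, plus attributes
#'   `voxel_cc`, `patient_id` and `visit`.
#' @export
ftv_surface <- function(study, maps, voi, grid = default_grid(),
                        min_cluster_voxels = 8, connectivity = 26) {
  stopifnot(inherits(grid, "threshold_grid"))
  pe_ts <- grid$pe_thresholds
  ser_ts <- grid$ser_thresholds
  vx <- voxel_volume_cc(study)
  out <- matrix(0, length(pe_ts), length(ser_ts),
                dimnames = list(pe_t = pe_ts, ser_t = ser_ts))
  for (i in seq_along(pe_ts)) {
    m <- enhancing_mask(maps, voi, pe_ts[i], min_cluster_voxels, connectivity)
    ser_vals <- maps$ser[m]
    ser_vals <- ser_vals[!is.na(ser_vals)]
    if (length(ser_vals)) {
      # closed >= comparison: count of values >= t, vectorized over the row
      srt <- sort(ser_vals)
      counts <- length(srt) - findInterval(ser_ts, srt, left.open = TRUE)
      out[i, ] <- counts * vx
    }
  }
  structure(out, class = c("ftv_surface", "matrix"),
            voxel_cc = vx, patient_id = study$patient_id,
            visit = study$visit,
            pe_thresholds = pe_ts, ser_thresholds = ser_ts)
}

#' FTV-derived survival predictors for one patient
#'
#' From per-visit FTV surfaces, computes the three predictors per grid
#' cell: percent change from baseline to the early-treatment visit
#' (`delta_ftv2`), percent change from baseline to the pre-surgery visit
#' (`delta_ftvf`), and absolute final volume (`ftv_f`). Percent change is
#' `(later - baseline) / baseline * 100`, so negative values are shrinkage.
#' Cells with zero baseline FTV yield missing deltas; a patient without the
#' early-treatment exam yields an all-missing `delta_ftv2`.
#'
#' @param surfaces Named list of [ftv_surface()] matrices by visit; the
#'   `MRI_1` (baseline) entry is required.
#' @param patient_id,subtype Optional identifiers carried on the result.
#' @return Object of class `predictor_record`: list of matrices
#'   `delta_ftv2`, `delta_ftvf`, `ftv_f` (NA where undefined).
#' @export
build_predictors <- function(surfaces, patient_id = NULL, subtype = NULL) {
  if (is.null(surfaces$MRI_1))
    stop("baseline surface 'MRI_1' is required", call. = FALSE)
  base <- unclass(surfaces$MRI_1)
  pct_change <- function(later) {
    out <- (unclass(later) - base) / base * 100
    out[base == 0] <- NA_real_
    out
  }
  na_like <- array(NA_real_, dim(base), dimnames = dimnames(base))
  delta_ftv2 <- if (!is.null(surfaces$MRI_2)) pct_change(surfaces$MRI_2) else na_like
  delta_ftvf <- if (!is.null(surfaces$MRI_f)) pct_change(surfaces$MRI_f) else na_like
  ftv_f <- if (!is.null(surfaces$MRI_f)) unclass(surfaces$MRI_f) else na_like
  structure(list(patient_id = patient_id, subtype = subtype,
                 delta_ftv2 = delta_ftv2, delta_ftvf = delta_ftvf,
                 ftv_f = ftv_f),
            class = "predictor_record")
}

#' Export FTV surfaces in long format
#'
#' @param surfaces Named list (by visit) of [ftv_surface()] objects.
#' @param patient_id Patient identifier for the output rows.
#' @return A data.frame with columns patient_id, visit, pe_t, ser_t, ftv_cc.
#' @export
surface_long <- function(surfaces, patient_id) {
  do.call(rbind, lapply(names(surfaces), function(v) {
    s <- surfaces[[v]]
    pe <- attr(s, "pe_thresholds")
    ser <- attr(s, "ser_thresholds")
    data.frame(patient_id = patient_id, visit = v,
               pe_t = rep(pe, times = length(ser)),
               ser_t = rep(ser, each = length(pe)),
               ftv_cc = as.vector(unclass(s)))
  }))
}
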