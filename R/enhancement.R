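#' Construct a three-timepoint DCE-MRI study
#'
#' Bundles one visit's three co-registered volumes: pre-contrast baseline
#' `s0`, early post-contrast `s_early` and late post-contrast `s_late`,
#' together with the voxel geometry needed to convert voxel counts to
#' volumes in cc.
#'
#' @param s0,s_early,s_late 3D numeric arrays of identical shape, in scanner
#'   intensity units (non-negative).
#' @param voxel_size_mm Numeric length-3, voxel edge lengths in mm
#'   (default 0.7 x 0.94 x 2.0).
#' @param patient_id,visit Identifiers; `visit` is one of `"MRI_1"`,
#'   `"MRI_2"`, `"MRI_f"` (baseline, early-treatment, pre-surgery).
#' @return An object of class `dce_study`.
#' @export
dce_study <- function(s0, s_early, s_late,
                      voxel_size_mm = c(0.7, 0.94, 2.0),
                      patient_id = "unknown", visit = "MRI_1") {
  for (nm in c("s0", "s_early", "s_late")) {
    v <- get(nm)
    if (!is.array(v) || length(dim(v)) != 3L)
      stop(sprintf("'%s' must be a 3D array", nm), call. = FALSE)
  }
  if (!identical(dim(s0), dim(s_early)))
    stop("volume shape mismatch: 's_early' does not match 's0'", call. = FALSE)
  if (!identical(dim(s0), dim(s_late)))
    stop("volume shape mismatch: 's_late' does not match 's0'", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be 3 strictly positive values", call. = FALSE)
  visit <- match.arg(visit, c("MRI_1", "MRI_2", "MRI_f"))
  structure(list(patient_id = as.character(patient_id), visit = visit,
                 s0 = s0, s_early = s_early, s_late = s_late,
                 voxel_size_mm = voxel_size_mm),
            class = "dce_study")
}

#' Voxel volume of a study in cc
#' @param study A [dce_study()].
#' @return Volume of one voxel in cc (mm^3 / 1000).
#' @export
voxel_volume_cc <- function(study) prod(study$voxel_size_mm) / 1000

#' Default baseline-intensity validity floor
#'
#' Voxels whose pre-contrast signal sits at the noise level of the
#' fat-suppressed background produce unstable percent-enhancement values.
#' The default floor is 5% of the 98th percentile of `s0`, a scale-free
#' choice that tracks the scanner's intensity calibration.
#'
#' @param s0 3D baseline intensity array.
#' @return A single non-negative intensity value.
#' @export
default_s0_floor <- function(s0) {
  0.05 * stats::quantile(s0, 0.98, names = FALSE, type = 7)
}

#' Compute percent-enhancement maps
#'
#' Voxelwise early and late percent enhancement,
#' `PE = (S_t - S0) / S0 * 100`, for the two post-contrast timepoints.
#' Voxels with `s0 <= s0_floor` are marked invalid and are excluded from all
#' downstream masks.
#'
#' @param study A [dce_study()].
#' @param s0_floor Absolute intensity floor below which the baseline is
#'   considered noise; defaults to [default_s0_floor()] of the study's `s0`.
#' @return An object of class `enhancement_maps` with elements `pe_early`,
#'   `pe_late` (percent units), `valid` (logical array), and `ser` (`NULL`
#'   until [compute_ser_map()] is applied).
#' @export
compute_pe_maps <- function(study, s0_floor = NULL) {
  stopifnot(inherits(study, "dce_study"))
  if (is.null(s0_floor)) s0_floor <- default_s0_floor(study$s0)
  if (!is.numeric(s0_floor) || length(s0_floor) != 1L || s0_floor < 0)
    stop("'s0_floor' must be a single non-negative intensity", call. = FALSE)
  valid <- study$s0 > s0_floor
  s0 <- study$s0
  s0[!valid] <- 1  # avoid 0/0; these voxels are masked out anyway
  pe_early <- (study$s_early - study$s0) / s0 * 100
  pe_late <- (study$s_late - study$s0) / s0 * 100
  pe_early[!valid] <- NA_real_
  pe_late[!valid] <- NA_real_
  structure(list(pe_early = pe_early, pe_late = pe_late, ser = NULL,
                 valid = valid, s0_floor = s0_floor),
            class = "enhancement_maps")
}

#' Compute the signal-enhancement-ratio map
#'
#' `SER = PE_early / PE_late`, the early-to-late enhancement ratio; values
#' above 1 indicate contrast washout, the kinetic pattern associated with
#' malignancy. The ratio is undefined where the late signal has fallen to or
#' below baseline (`pe_late <= 0`); such complete-washout voxels are the
#' extreme of the behavior SER is designed to flag, so they are assigned the
#' cap value `washout_cap` (default `Inf`), which passes every SER
#' threshold. Non-enhancing voxels (`pe_early <= 0`) get `ser = 0`.
#'
#' @param maps An `enhancement_maps` object from [compute_pe_maps()].
#' @param washout_cap SER value assigned where `pe_late <= 0 < pe_early`.
#' @return The `enhancement_maps` object with `ser` filled in.
#' @export
compute_ser_map <- function(maps, washout_cap = Inf) {
  stopifnot(inherits(maps, "enhancement_maps"))
  pe_e <- maps$pe_early
  pe_l <- maps$pe_late
  ser <- array(NA_real_, dim(pe_e))
  v <- maps$valid
  nonenh <- v & pe_e <= 0
  ratio <- v & pe_e > 0 & pe_l > 0
  washout <- v & pe_e > 0 & pe_l <= 0
  ser[nonenh] <- 0
  ser[ratio] <- pe_e[ratio] / pe_l[ratio]
  ser[washout] <- washout_cap
  maps$ser <- ser
  maps
}

#' Compute PE and SER maps in one step
#' @inheritParams compute_pe_maps
#' @inheritParams compute_ser_map
#' @return An `enhancement_maps` object with all maps filled.
#' @export
enhancement_maps <- function(study, s0_floor = NULL, washout_cap = Inf) {
  compute_ser_map(compute_pe_maps(study, s0_floor), washout_cap)
}
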