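#' Default per-unit scaling of the FTV predictors
#'
#' Hazard ratios are reported "per unit change" of the predictor; the unit
#' is 10 percentage points for the percent-change predictors and 1 cc for
#' the absolute final volume. The scale in use is always carried on the
#' results.
#'
#' @param predictor One of `"delta_ftv2"`, `"delta_ftvf"`, `"ftv_f"`.
#' @return A single positive divisor.
#' @export
default_scale <- function(predictor) {
  switch(match.arg(predictor, c("delta_ftv2", "delta_ftvf", "ftv_f")),
         delta_ftv2 = 10, delta_ftvf = 10, ftv_f = 1)
}

#' Stack per-patient predictor records into 3D arrays
#'
#' @param records List of [build_predictors()] results, one per patient.
#' @return List with `patient_id`, `subtype`, and for each predictor a
#'   3D array `[patient, pe_t, ser_t]`.
#' @export
predictor_array <- function(records) {
  stopifnot(length(records) > 0)
  d <- dim(records[[1]]$ftv_f)
  dn <- dimnames(records[[1]]$ftv_f)
  stack <- function(name) {
    a <- array(NA_real_, c(length(records), d),
               dimnames = c(list(NULL), dn))
    for (i in seq_along(records)) a[i, , ] <- records[[i]][[name]]
    a
  }
  list(patient_id = vapply(records, function(r) r$patient_id %||% NA_character_,
                           character(1)),
       subtype = vapply(records, function(r) r$subtype %||% "unknown",
                        character(1)),
       delta_ftv2 = stack("delta_ftv2"),
       delta_ftvf = stack("delta_ftvf"),
       ftv_f = stack("ftv_f"))
}

# placeholder for cells whose fit could not be attempted / did not converge
placeholder_result <- function(n_used, n_events, reason) {
  structure(list(beta = NA_real_, se = NA_real_, hazard_ratio = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, lr_stat = NA_real_,
                 lr_pvalue = NA_real_, n_used = n_used, n_events = n_events,
                 converged = FALSE, degenerate = TRUE, scale = NA_real_,
                 reason = reason),
            class = "cox_result")
}

#' Cox threshold sweep over the grid
#'
#' Fits one univariate Cox model per grid cell: the predictor evaluated at
#' that cell's (PE_t, SER_t) against recurrence-free survival, within the
#' requested cohort subset. Patients with a missing predictor at a cell are
#' dropped from that cell's fit only. Cells whose fit cannot be attempted
#' (no events, constant covariate, too few subjects) or does not satisfy
#' the stability guards carry flagged placeholder results. No multiplicity
#' correction is applied across cells; the number of fits and the count of
#' cells with p < 0.05 are always reported.
#'
#' @param predictors Result of [predictor_array()].
#' @param surv A [survival_records()] table; matched to the predictor rows
#'   by `patient_id`.
#' @param grid The [threshold_grid()] the predictor arrays were computed on.
#' @param predictor Which predictor to sweep.
#' @param subset `"full"` (all patients, unknown subtype included) or one
#'   of the subtype labels.
#' @param scale Per-unit divisor; defaults to [default_scale()].
#' @return Object of class `sweep_result` with matrices `hr`, `p`, `ci_lo`,
#'   `ci_hi`, `beta`, `n`, `events`, `converged`, `degenerate`; the
#'   `default_cell`, the `optimized_cell` (or NULL), the per-cell results,
#'   and summary counts.
#' @export
sweep_cox <- function(predictors, surv, grid = default_grid(),
                      predictor = c("delta_ftv2", "delta_ftvf", "ftv_f"),
                      subset = "full", scale = NULL) {
  predictor <- match.arg(predictor)
  if (is.null(scale)) scale <- default_scale(predictor)
  stopifnot(inherits(grid, "threshold_grid"))
  arr <- predictors[[predictor]]

  idx <- match(predictors$patient_id, surv$patient_id)
  if (anyNA(idx))
    stop("patients without survival records: ",
         paste(predictors$patient_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  surv <- surv[idx, ]

  if (identical(subset, "full")) {
    sel <- rep(TRUE, nrow(surv))
  } else {
    if (!subset %in% c("HRpos_HER2neg", "HER2pos", "TN", "unknown"))
      stop("unknown subset label '", subset, "'", call. = FALSE)
    sel <- surv$subtype == subset
  }
  if (!any(sel))
    stop("empty subset after filtering on '", subset, "'", call. = FALSE)
  arr <- arr[sel, , , drop = FALSE]
  surv <- surv[sel, ]

  pe <- grid$pe_thresholds
  ser <- grid$ser_thresholds
  np <- length(pe); ns <- length(ser)
  mk <- function() matrix(NA_real_, np, ns, dimnames = list(pe_t = pe, ser_t = ser))
  hr <- p <- ci_lo <- ci_hi <- beta_m <- mk()
  n_m <- ev_m <- mk()
  conv <- deg <- matrix(FALSE, np, ns, dimnames = dimnames(mk()))
  cells <- vector("list", np * ns)
  dim(cells) <- c(np, ns)

  for (i in seq_len(np)) for (j in seq_len(ns)) {
    x <- arr[, i, j]
    ok <- is.finite(x)
    res <- tryCatch(
      fit_cox(x[ok], surv$rfs_months[ok], surv$event[ok], scale = scale),
      error = function(e) placeholder_result(sum(ok),
                                             sum(surv$event[ok]),
                                             conditionMessage(e)))
    cells[[i, j]] <- res
    hr[i, j] <- res$hazard_ratio; p[i, j] <- res$lr_pvalue
    ci_lo[i, j] <- res$ci_lo; ci_hi[i, j] <- res$ci_hi
    beta_m[i, j] <- res$beta
    n_m[i, j] <- res$n_used; ev_m[i, j] <- res$n_events
    conv[i, j] <- res$converged; deg[i, j] <- res$degenerate
  }

  out <- structure(list(predictor = predictor, subset = subset,
                        grid = grid, scale = scale,
                        hr = hr, p = p, ci_lo = ci_lo, ci_hi = ci_hi,
                        beta = beta_m, n = n_m, events = ev_m,
                        converged = conv, degenerate = deg,
                        cells = cells,
                        default_cell = default_cell(),
                        n_fits = np * ns,
                        n_significant = sum(p < 0.05 & conv & !deg,
                                            na.rm = TRUE)),
                   class = "sweep_result")
  out$optimized_cell <- tryCatch(select_optimized(out), error = function(e) NULL)
  out
}

#' Select the optimized threshold cell
#'
#' The optimized (PE_t, SER_t) combination is the cell with the lowest
#' likelihood-ratio p-value among converged, non-degenerate cells. Exact
#' ties are broken by higher hazard ratio, then lower PE_t, then lower
#' SER_t.
#'
#' @param sweep A [sweep_cox()] result.
#' @return Named numeric `c(pe_t =, ser_t =)` with attributes `index`
#'   (grid indices) and `tie_broken`.
#' @export
select_optimized <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  eligible <- sweep$converged & !sweep$degenerate & is.finite(sweep$p)
  if (!any(eligible))
    stop(sprintf(
      "no eligible cells for optimum selection (%d cells: %d unconverged, %d degenerate)",
      length(eligible), sum(!sweep$converged), sum(sweep$degenerate)),
      call. = FALSE)
  pmin_val <- min(sweep$p[eligible])
  cand <- which(eligible & sweep$p == pmin_val, arr.ind = TRUE)
  tie_broken <- nrow(cand) > 1L
  if (tie_broken) {
    hrs <- sweep$hr[cand]
    cand <- cand[hrs == max(hrs), , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  }
  i <- cand[1, 1]; j <- cand[1, 2]
  out <- c(pe_t = sweep$grid$pe_thresholds[i],
           ser_t = sweep$grid$ser_thresholds[j])
  attr(out, "index") <- c(i, j)
  attr(out, "tie_broken") <- tie_broken
  out
}

#' Flatten a sweep to a long table
#'
#' One row per grid cell with the columns used by the run outputs:
#' subset, predictor, pe_t, ser_t, n, events, beta, hr, ci_lo, ci_hi,
#' lr_p, converged, degenerate.
#'
#' @param sweep A [sweep_cox()] result.
#' @return A data.frame with one row per grid cell.
#' @export
sweep_table <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  pe <- sweep$grid$pe_thresholds
  ser <- sweep$grid$ser_thresholds
  data.frame(subset = sweep$subset, predictor = sweep$predictor,
             pe_t = rep(pe, times = length(ser)),
             ser_t = rep(ser, each = length(pe)),
             n = as.vector(sweep$n), events = as.vector(sweep$events),
             beta = as.vector(sweep$beta), hr = as.vector(sweep$hr),
             ci_lo = as.vector(sweep$ci_lo), ci_hi = as.vector(sweep$ci_hi),
             lr_p = as.vector(sweep$p),
             converged = as.vector(sweep$converged),
             degenerate = as.vector(sweep$degenerate))
}

#' Optimized-vs-default comparison row
#'
#' The per-predictor summary the clinical tables report: hazard ratio,
#' Wald 95% CI and p-value at the optimized cell and at the default cell
#' (PE_t = 70%, SER_t = 0).
#'
#' @param sweep A [sweep_cox()] result.
#' @return A one-row data.frame (optimized columns NA when no cell was
#'   eligible).
#' @export
comparison_row <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  at <- function(cell) {
    i <- match(cell[1], sweep$grid$pe_thresholds)
    j <- match(cell[2], sweep$grid$ser_thresholds)
    if (is.na(i) || is.na(j)) return(rep(NA_real_, 4))
    c(sweep$hr[i, j], sweep$ci_lo[i, j], sweep$ci_hi[i, j], sweep$p[i, j])
  }
  opt <- sweep$optimized_cell
  o <- if (is.null(opt)) rep(NA_real_, 4) else at(opt)
  d <- at(sweep$default_cell)
  data.frame(subset = sweep$subset, predictor = sweep$predictor,
             scale = sweep$scale,
             opt_pe_t = if (is.null(opt)) NA_real_ else opt[["pe_t"]],
             opt_ser_t = if (is.null(opt)) NA_real_ else opt[["ser_t"]],
             opt_hr = o[1], opt_ci_lo = o[2], opt_ci_hi = o[3], opt_p = o[4],
             def_pe_t = sweep$default_cell[["pe_t"]],
             def_ser_t = sweep$default_cell[["ser_t"]],
             def_hr = d[1], def_ci_lo = d[2], def_ci_hi = d[3], def_p = d[4],
             n_fits = sweep$n_fits, n_significant = sweep$n_significant)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Cox threshold sweep: %s, subset %s, %d cells (scale %g)\n",
              x$predictor, x$subset, x$n_fits, x$scale))
  cat(sprintf("  %d cells p < 0.05, %d degenerate\n", x$n_significant,
              sum(x$degenerate)))
  if (!is.null(x$optimized_cell))
    cat(sprintf("  optimized cell: PE_t = %g%%, SER_t = %g\n",
                x$optimized_cell[["pe_t"]], x$optimized_cell[["ser_t"]]))
  else cat("  no eligible optimized cell\n")
  invisible(x)
}
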