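#' Survival records for the cohort
#'
#' Recurrence-free survival (RFS): time from surgery to local or distant
#' recurrence; patients without recurrence are censored at their most
#' recent follow-up.
#'
#' @param df Data frame with columns `patient_id`, `subtype` (one of
#'   `"HRpos_HER2neg"`, `"HER2pos"`, `"TN"`, `"unknown"`), `rfs_months`
#'   (positive), `event` (0/1 or logical).
#' @return The validated data frame with class `survival_records`.
#' @export
survival_records <- function(df) {
  need <- c("patient_id", "subtype", "rfs_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!(df$subtype %in% c("HRpos_HER2neg", "HER2pos", "TN", "unknown")))
  if (length(bad))
    stop(sprintf("unknown subtype label '%s' at row %d", df$subtype[bad[1]],
                 bad[1]), call. = FALSE)
  bad <- which(!is.finite(df$rfs_months) | df$rfs_months <= 0)
  if (length(bad))
    stop(sprintf("non-positive rfs_months at row %d", bad[1]), call. = FALSE)
  if (!all(df$event %in% c(0, 1, TRUE, FALSE)))
    stop("'event' must be coded 0/1", call. = FALSE)
  df$event <- as.integer(df$event)
  df$patient_id <- as.character(df$patient_id)
  class(df) <- c("survival_records", "data.frame")
  df
}

#' Read the clinical table
#' @param path CSV with columns patient_id, subtype, rfs_months, event.
#' @return A [survival_records()] data frame.
#' @export
read_clinical <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed clinical CSV '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  survival_records(df)
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with the Efron correction for tied
#' event times by Newton iteration, for a single covariate `x / scale`. The
#' hazard ratio is `exp(beta)` per `scale` units of `x`; the Wald 95% CI is
#' `exp(beta +/- 1.96 se)`; the p-value is the likelihood-ratio test of
#' `beta = 0` against chi-square(1).
#'
#' Monotone partial likelihood (perfect separation of events along the
#' covariate, common in small subsets) makes `|beta|` diverge; fits with
#' `|beta| > 15` or `se > 10` are flagged `degenerate` and excluded from
#' optimum selection downstream, but still reported.
#'
#' @param x Numeric covariate, one value per subject (NAs dropped together
#'   with their subjects).
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = recurrence, 0 = censored).
#' @param scale Covariate divisor defining the "unit" of the hazard ratio
#'   (e.g. 10 for per-10-percentage-point on a percent-change predictor).
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `cox_result`: list with `beta`, `se`,
#'   `hazard_ratio`, `ci_lo`, `ci_hi`, `lr_stat`, `lr_pvalue`, `n_used`,
#'   `n_events`, `converged`, `degenerate`, `scale`.
#' @export
fit_cox <- function(x, time, event, scale = 1, max_iter = 50, tol = 1e-10) {
  keep <- is.finite(x) & is.finite(time) & !is.na(event)
  x <- x[keep]; time <- time[keep]; event <- as.integer(event[keep])
  n <- length(x)
  if (n < 2L) stop("fewer than 2 subjects with non-missing predictor",
                   call. = FALSE)
  if (sum(event) == 0L) stop("no events", call. = FALSE)
  if (stats::sd(x) == 0) stop("non-identifiable: constant covariate",
                              call. = FALSE)
  z <- x / scale

  ord <- order(time, -event)  # events before censoring at tied times
  z <- z[ord]; time <- time[ord]; event <- event[ord]

  # pre-group: for each unique event time, indices of deaths and risk set
  ev_times <- unique(time[event == 1L])
  groups <- lapply(ev_times, function(t) {
    list(deaths = which(time == t & event == 1L),
         risk_from = match(TRUE, time >= t))  # risk set = risk_from..n
  })

  efron_quants <- function(beta) {
    w <- exp(beta * z)
    zw <- z * w
    z2w <- z * zw
    # reverse cumulative sums over the time-ordered subjects
    cw <- rev(cumsum(rev(w)))
    czw <- rev(cumsum(rev(zw)))
    cz2w <- rev(cumsum(rev(z2w)))
    ll <- 0; grad <- 0; info <- 0
    for (g in groups) {
      d <- length(g$deaths)
      s0r <- cw[g$risk_from]; s1r <- czw[g$risk_from]; s2r <- cz2w[g$risk_from]
      s0d <- sum(w[g$deaths]); s1d <- sum(zw[g$deaths]); s2d <- sum(z2w[g$deaths])
      zsum <- sum(z[g$deaths])
      ll <- ll + beta * zsum
      phis <- (seq_len(d) - 1) / d
      a0 <- s0r - phis * s0d
      a1 <- s1r - phis * s1d
      a2 <- s2r - phis * s2d
      ll <- ll - sum(log(a0))
      grad <- grad + zsum - sum(a1 / a0)
      info <- info + sum(a2 / a0 - (a1 / a0)^2)
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- 0
  q <- efron_quants(beta)
  ll0 <- q$ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (!is.finite(q$info) || q$info <= 0) break
    step <- q$grad / q$info
    # step-halving to guarantee likelihood ascent
    new_beta <- beta + step
    q_new <- efron_quants(new_beta)
    halvings <- 0
    while ((!is.finite(q_new$ll) || q_new$ll < q$ll) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      q_new <- efron_quants(new_beta)
      halvings <- halvings + 1
    }
    beta <- new_beta
    q <- q_new
    if (abs(q$grad) < tol || abs(step) < 1e-12) { converged <- TRUE; break }
  }

  se <- if (is.finite(q$info) && q$info > 0) sqrt(1 / q$info) else NA_real_
  lr_stat <- max(0, 2 * (q$ll - ll0))
  lr_p <- stats::pchisq(lr_stat, df = 1, lower.tail = FALSE)
  degenerate <- !is.finite(beta) || abs(beta) > 15 ||
    !is.finite(se) || se > 10
  structure(list(beta = beta, se = se, hazard_ratio = exp(beta),
                 ci_lo = exp(beta - 1.96 * se),
                 ci_hi = exp(beta + 1.96 * se),
                 lr_stat = lr_stat, lr_pvalue = lr_p,
                 n_used = n, n_events = sum(event),
                 converged = converged, degenerate = degenerate,
                 scale = scale),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf(
    "Cox PH fit: HR = %.3f (95%% CI %.3f-%.3f) per %g unit(s), LR p = %.3g\n",
    x$hazard_ratio, x$ci_lo, x$ci_hi, x$scale, x$lr_pvalue))
  cat(sprintf("  n = %d, events = %d, converged = %s%s\n", x$n_used,
              x$n_events, x$converged,
              if (x$degenerate) ", DEGENERATE (monotone likelihood)" else ""))
  invisible(x)
}
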