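#' Heat-map styling for sweep results
#'
#' Matches the figure conventions of the analysis: hazard ratios
#' color-coded blue-to-red over 0.9-1.2, p-values red-to-blue over
#' 0.001-0.1 (on a log10 scale, since three decades of p are displayed);
#' values outside a range clamp to its endpoints. PE_t runs on the y axis,
#' SER_t on the x axis; the default cell is marked with a circle and the
#' optimized cell with a star.
#'
#' @param hr_range,p_range Length-2 numeric color ranges.
#' @param p_log10 Color p-values on a log10 scale.
#' @return Object of class `heatmap_style`.
#' @export
heatmap_style <- function(hr_range = c(0.9, 1.2), p_range = c(0.001, 0.1),
                          p_log10 = TRUE) {
  stopifnot(length(hr_range) == 2, hr_range[1] < hr_range[2],
            length(p_range) == 2, 0 < p_range[1], p_range[1] < p_range[2])
  structure(list(hr_range = hr_range, p_range = p_range, p_log10 = p_log10),
            class = "heatmap_style")
}

#' Clamp values to a range
#' @param x Numeric vector or matrix.
#' @param range Length-2 numeric `c(lo, hi)`.
#' @return `x` with values below/above the range set to its endpoints
#'   (NAs preserved).
#' @export
clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Render hazard-ratio and p-value heat maps for a sweep
#'
#' Writes one HR map and one p map (per-cell raster for determinism) for
#' the sweep's subset and predictor, plus a JSON sidecar recording the
#' style, clamp ranges and marker positions. Degenerate cells are
#' annotated with a cross. Returns the exact clamped matrices that were
#' plotted so tests can assert on numbers rather than pixels.
#'
#' @param sweep A [sweep_cox()] result.
#' @param style A [heatmap_style()].
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output and only returns the plotted matrices.
#' @param formats Image formats to write (`"png"`, optionally `"svg"`).
#' @return Invisibly, list with `hr` and `p` clamped matrices and the
#'   paths written.
#' @export
render_heatmaps <- function(sweep, style = heatmap_style(), out_dir = NULL,
                            formats = "png") {
  stopifnot(inherits(sweep, "sweep_result"), inherits(style, "heatmap_style"))
  hr_c <- clamp(sweep$hr, style$hr_range)
  p_c <- clamp(sweep$p, style$p_range)
  if (is.null(sweep$optimized_cell))
    warning("no eligible optimized cell; rendering without the star marker",
            call. = FALSE)
  paths <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory '", out_dir, "'", call. = FALSE)
    stem <- file.path(out_dir, paste0(sweep$subset, "_", sweep$predictor))
    paths <- c(
      write_heatmap_figure(sweep, hr_c, style$hr_range, FALSE,
                           "Hazard ratio", paste0(stem, "_hr"), formats),
      write_heatmap_figure(sweep, p_c, style$p_range, style$p_log10,
                           "LR p-value", paste0(stem, "_p"), formats))
    sidecar <- paste0(stem, "_style.json")
    jsonlite::write_json(list(
      subset = sweep$subset, predictor = sweep$predictor,
      hr_range = style$hr_range, p_range = style$p_range,
      p_log10 = style$p_log10,
      default_cell = as.list(sweep$default_cell),
      optimized_cell = if (is.null(sweep$optimized_cell)) NULL
                       else as.list(sweep$optimized_cell[1:2]),
      degenerate_cells = sum(sweep$degenerate)),
      sidecar, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, sidecar)
  }
  invisible(list(hr = hr_c, p = p_c, paths = paths))
}

write_heatmap_figure <- function(sweep, mat, range, log10_scale, label,
                                 stem, formats) {
  pe <- sweep$grid$pe_thresholds
  ser <- sweep$grid$ser_thresholds
  df <- data.frame(pe_t = rep(pe, times = length(ser)),
                   ser_t = rep(ser, each = length(pe)),
                   value = as.vector(mat),
                   degenerate = as.vector(sweep$degenerate))
  colors <- if (log10_scale) c("red", "blue") else c("blue", "red")
  trans_val <- if (log10_scale) log10(df$value) else df$value
  trans_rng <- if (log10_scale) log10(range) else range
  df$fill <- trans_val
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = ser_t, y = pe_t)) +
    ggplot2::geom_raster(ggplot2::aes(fill = fill)) +
    ggplot2::scale_fill_gradient(low = colors[1], high = colors[2],
                                 limits = trans_rng, na.value = "grey80",
                                 name = label) +
    ggplot2::labs(x = expression(SER[t]), y = expression(PE[t] * " (%)"),
                  title = sprintf("%s — %s (%s)", label, sweep$predictor,
                                  sweep$subset)) +
    ggplot2::theme_minimal()
  if (any(df$degenerate))
    gp <- gp + ggplot2::geom_point(data = df[df$degenerate, ],
                                   shape = 4, size = 2, color = "grey30")
  dc <- sweep$default_cell
  gp <- gp + ggplot2::annotate("point", x = dc[["ser_t"]], y = dc[["pe_t"]],
                               shape = 1, size = 4, stroke = 1.2)
  if (!is.null(sweep$optimized_cell)) {
    oc <- sweep$optimized_cell
    gp <- gp + ggplot2::annotate("point", x = oc[["ser_t"]], y = oc[["pe_t"]],
                                 shape = 8, size = 4, stroke = 1.2)
  }
  out <- character(0)
  for (fmt in formats) {
    f <- paste0(stem, ".", fmt)
    ggplot2::ggsave(f, gp, width = 5, height = 5, dpi = 120)
    out <- c(out, f)
  }
  out
}
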