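#' Maximum intensity projection of a volume
#'
#' Collapses one axis of a 3D volume by taking the per-line maximum, the
#' projection used to place rectangular ROIs when defining the volume of
#' interest.
#'
#' @param volume 3D numeric array.
#' @param axis Axis to collapse (1, 2 or 3).
#' @return 2D array with the collapsed axis removed.
#' @export
project_mip <- function(volume, axis) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("'volume' must be a 3D array", call. = FALSE)
  if (!(axis %in% 1:3))
    stop("'axis' must be 1, 2 or 3 for a 3D volume", call. = FALSE)
  apply(volume, setdiff(1:3, axis), max)
}

#' Declarative volume-of-interest specification
#'
#' The VOI is defined the way the original semi-automated workflow defines
#' it: two rectangular ROIs drawn on orthogonal maximum-intensity
#' projections, back-projected along their projection axes and intersected;
#' enhancing non-tumor structures (vessels, heart) are then removed with
#' exclusion regions. Here the ROIs are supplied declaratively instead of
#' drawn interactively.
#'
#' All indices are 0-based, half-open `[lo, hi)` in array order: an ROI on
#' projection axis `a` has `rect` rows for the two remaining axes in
#' ascending order. Exclusions are axis-aligned 3D boxes (`list(box =
#' list(c(lo, hi), c(lo, hi), c(lo, hi)))`) or 2D polygons swept along an
#' axis (`list(axis =, poly = matrix, range =)` where `poly` has columns for
#' the two remaining axes in 0-based voxel-center coordinates and `range` is
#' an optional `[lo, hi)` interval on the swept axis).
#'
#' @param roi_a,roi_b Lists with elements `axis` (projection axis 1-3) and
#'   `rect` (a list of two `c(lo, hi)` integer pairs).
#' @param exclusions List of exclusion regions (possibly empty).
#' @return Object of class `voi_spec`.
#' @export
voi_spec <- function(roi_a, roi_b, exclusions = list()) {
  check_roi <- function(roi, nm) {
    if (!is.list(roi) || is.null(roi$axis) || is.null(roi$rect))
      stop(sprintf("'%s' must have elements 'axis' and 'rect'", nm),
           call. = FALSE)
    if (!(roi$axis %in% 1:3))
      stop(sprintf("'%s$axis' must be 1, 2 or 3", nm), call. = FALSE)
    if (length(roi$rect) != 2L)
      stop(sprintf("'%s$rect' must give [lo, hi) for both in-plane axes", nm),
           call. = FALSE)
    for (iv in roi$rect) {
      if (length(iv) != 2L || any(!is.finite(iv)))
        stop(sprintf("'%s' intervals must be finite [lo, hi) pairs", nm),
             call. = FALSE)
      if (iv[2] <= iv[1])
        stop(sprintf("degenerate (empty) rectangle in '%s'", nm),
             call. = FALSE)
    }
    roi
  }
  roi_a <- check_roi(roi_a, "roi_a")
  roi_b <- check_roi(roi_b, "roi_b")
  if (roi_a$axis == roi_b$axis)
    stop("the two ROIs must project along different axes", call. = FALSE)
  structure(list(roi_a = roi_a, roi_b = roi_b, exclusions = exclusions),
            class = "voi_spec")
}

# Back-project a rectangular projection ROI into a 3D slab mask.
# rect rows refer to the remaining axes (ascending) of the projection plane.
roi_slab_mask <- function(shape, axis, rect) {
  in_axes <- setdiff(1:3, axis)
  idx <- vector("list", 3)
  idx[[axis]] <- rep(TRUE, shape[axis])
  for (k in 1:2) {
    ax <- in_axes[k]
    lo <- max(0L, as.integer(ceiling(rect[[k]][1])))
    hi <- min(shape[ax], as.integer(floor(rect[[k]][2])))
    sel <- rep(FALSE, shape[ax])
    if (hi > lo) sel[(lo + 1L):hi] <- TRUE  # 0-based [lo,hi) -> 1-based
    idx[[ax]] <- sel
  }
  outer3 <- outer(outer(idx[[1]], idx[[2]], "&"), idx[[3]], "&")
  array(outer3, shape)
}

exclusion_mask <- function(excl, shape) {
  if (!is.null(excl$box)) {
    b <- excl$box
    if (length(b) != 3L) stop("exclusion box needs 3 intervals", call. = FALSE)
    idx <- lapply(1:3, function(ax) {
      lo <- max(0L, as.integer(ceiling(b[[ax]][1])))
      hi <- min(shape[ax], as.integer(floor(b[[ax]][2])))
      sel <- rep(FALSE, shape[ax])
      if (hi > lo) sel[(lo + 1L):hi] <- TRUE
      sel
    })
    return(array(outer(outer(idx[[1]], idx[[2]], "&"), idx[[3]], "&"), shape))
  }
  if (!is.null(excl$poly)) {
    ax <- excl$axis
    if (!(ax %in% 1:3)) stop("exclusion polygon needs an axis", call. = FALSE)
    in_axes <- setdiff(1:3, ax)
    poly <- as.matrix(excl$poly)
    plane_dim <- shape[in_axes]
    centers <- as.matrix(expand.grid(seq_len(plane_dim[1]) - 1L,
                                     seq_len(plane_dim[2]) - 1L))
    inside <- points_in_polygon(centers, poly)
    plane <- array(inside, plane_dim)
    sel_ax <- rep(TRUE, shape[ax])
    if (!is.null(excl$range)) {
      lo <- max(0L, as.integer(ceiling(excl$range[1])))
      hi <- min(shape[ax], as.integer(floor(excl$range[2])))
      sel_ax <- rep(FALSE, shape[ax])
      if (hi > lo) sel_ax[(lo + 1L):hi] <- TRUE
    }
    m <- array(FALSE, shape)
    # sweep the rasterized polygon along the exclusion axis
    perm <- order(c(ax, in_axes))
    swept <- outer(sel_ax, plane, "&")  # dims: shape[ax] x plane_dim
    dim(swept) <- c(shape[ax], plane_dim)
    return(aperm(swept, perm))
  }
  stop("exclusion must have a 'box' or a 'poly' element", call. = FALSE)
}

# even-odd rule point-in-polygon test; pts: n x 2, poly: k x 2 (open ring)
points_in_polygon <- function(pts, poly) {
  n <- nrow(pts)
  k <- nrow(poly)
  inside <- rep(FALSE, n)
  j <- k
  for (i in seq_len(k)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Build the 3D VOI mask from a specification
#'
#' A voxel belongs to the VOI iff it lies in the back-projected slab of both
#' rectangular ROIs and in no exclusion region; exclusions are subtracted
#' after the intersection.
#'
#' @param spec A [voi_spec()].
#' @param shape Integer length-3 volume shape.
#' @return Logical 3D array. If the resulting VOI is empty, the attribute
#'   `empty_voi` is set to `TRUE` and a warning is issued.
#' @export
voi_mask <- function(spec, shape) {
  stopifnot(inherits(spec, "voi_spec"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be 3 positive integers", call. = FALSE)
  m <- roi_slab_mask(shape, spec$roi_a$axis, spec$roi_a$rect) &
    roi_slab_mask(shape, spec$roi_b$axis, spec$roi_b$rect)
  for (excl in spec$exclusions) m <- m & !exclusion_mask(excl, shape)
  if (!any(m)) {
    warning("VOI mask is empty for this specification", call. = FALSE)
    attr(m, "empty_voi") <- TRUE
  }
  m
}

#' Read / write a VOI specification as JSON
#'
#' Serialization uses 0-based half-open intervals, matching [voi_spec()]:
#' `{"roi_a": {"axis": 0, "rect": [[r0,r1],[c0,c1]]}, "roi_b": ...,
#' "exclusions": [...]}`. Axes are 0-based in the file and 1-based in R.
#'
#' @param path File path.
#' @param spec A [voi_spec()] (for writing).
#' @return For `read_voi_spec`, a [voi_spec()].
#' @export
read_voi_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  conv_roi <- function(r) {
    rect <- r$rect
    if (is.matrix(rect)) rect <- lapply(seq_len(nrow(rect)), function(i) rect[i, ])
    list(axis = r$axis + 1L, rect = rect)
  }
  excl <- lapply(x$exclusions, function(e) {
    if (!is.null(e$box)) {
      b <- e$box
      if (is.matrix(b)) b <- lapply(seq_len(nrow(b)), function(i) b[i, ])
      list(box = b)
    } else {
      list(axis = e$axis + 1L, poly = matrix(unlist(e$poly), ncol = 2,
                                             byrow = TRUE),
           range = if (!is.null(e$range)) unlist(e$range))
    }
  })
  voi_spec(conv_roi(x$roi_a), conv_roi(x$roi_b), excl %||% list())
}

#' @rdname read_voi_spec
#' @export
write_voi_spec <- function(spec, path) {
  stopifnot(inherits(spec, "voi_spec"))
  conv_roi <- function(r) list(axis = r$axis - 1L, rect = r$rect)
  excl <- lapply(spec$exclusions, function(e) {
    if (!is.null(e$box)) list(box = e$box)
    else {
      out <- list(axis = e$axis - 1L,
                  poly = lapply(seq_len(nrow(e$poly)), function(i) e$poly[i, ]))
      if (!is.null(e$range)) out$range <- e$range
      out
    }
  })
  jsonlite::write_json(list(roi_a = conv_roi(spec$roi_a),
                            roi_b = conv_roi(spec$roi_b),
                            exclusions = excl),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
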