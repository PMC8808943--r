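## Geometry core: calibrated two-border cartilage contours, region partition,
## per-region CSA / bone-interface length / mean thickness.
##
## Conventions: pixel coordinates are 0-based pixel centers with y increasing
## downward (image convention). Borders are x-monotone polylines; the superior
## (synovial-cartilage) border lies above the inferior (cartilage-bone) border
## on screen, i.e. has strictly smaller y over the interior of the shared
## x-extent. All conversion to millimetres happens before any area or norm is
## taken, so anisotropic pixel spacing is honored.

#' Pixel-to-millimetre calibration
#'
#' @param mm_per_px_x,mm_per_px_y millimetres per pixel along x (medio-lateral)
#'   and y (depth). Ultrasound pixels need not be square; isotropy is not
#'   assumed.
#' @return an `image_calibration` object
#' @export
image_calibration <- function(mm_per_px_x, mm_per_px_y = mm_per_px_x) {
  if (!is.numeric(mm_per_px_x) || !is.numeric(mm_per_px_y) ||
      length(mm_per_px_x) != 1L || length(mm_per_px_y) != 1L ||
      !is.finite(mm_per_px_x) || !is.finite(mm_per_px_y) ||
      mm_per_px_x <= 0 || mm_per_px_y <= 0) {
    uc_stop("calibration factors must be single finite positive numbers",
            "calibration_error")
  }
  structure(list(mm_per_px_x = mm_per_px_x, mm_per_px_y = mm_per_px_y),
            class = "image_calibration")
}

#' An x-monotone border polyline
#'
#' Vertices in pixel coordinates. Orientation is normalized so x is
#' non-decreasing (a polyline supplied right-to-left is reversed); vertical
#' steps (repeated x with different y) are allowed, but x may never decrease.
#'
#' @param x,y numeric vertex coordinates (pixels), equal length, >= 2 vertices
#' @return a `polyline`: a 2-column matrix (columns `x`, `y`)
#' @export
polyline <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    uc_stop("a polyline needs >= 2 (x, y) vertex pairs", "polyline_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    uc_stop("polyline coordinates must be finite", "polyline_error")
  }
  dx <- diff(x)
  if (all(dx <= 0)) { x <- rev(x); y <- rev(y); dx <- diff(x) }
  if (any(dx < 0)) {
    uc_stop("polyline is not x-monotone after orientation normalization",
            "polyline_error")
  }
  if (x[1L] == x[length(x)]) {
    uc_stop("polyline has zero x-extent", "polyline_error")
  }
  structure(cbind(x = as.numeric(x), y = as.numeric(y)), class = "polyline")
}

as_polyline <- function(p) {
  if (inherits(p, "polyline")) return(p)
  if (is.matrix(p) && ncol(p) == 2L) return(polyline(p[, 1L], p[, 2L]))
  if (is.data.frame(p)) return(polyline(p[[1L]], p[[2L]]))
  uc_stop("cannot interpret object as a polyline", "polyline_error")
}

## Evaluate an x-monotone polyline at arbitrary x. At a vertical step the
## right-limit is returned (findInterval picks the last vertex with x <= x0).
eval_border <- function(pl, xout) {
  x <- pl[, 1L]; y <- pl[, 2L]
  i <- findInterval(xout, x, rightmost.closed = TRUE, all.inside = TRUE)
  x1 <- x[i]; x2 <- x[i + 1L]
  w <- ifelse(x2 == x1, 0, (xout - x1) / (x2 - x1))
  y[i] + w * (y[i + 1L] - y[i])
}

## All y values a border takes at exactly x = x0 (several at a vertical step).
border_values_at <- function(pl, x0) {
  hit <- pl[, 1L] == x0
  ys <- pl[hit, 2L]
  if (!any(hit)) ys <- eval_border(pl, x0)
  ys
}

## Clip an x-monotone polyline to [x_lo, x_hi], inserting interpolated
## vertices at the cut positions. Interpolated cut vertices are computed the
## same way from either side of a cut, so strip areas/lengths add exactly.
clip_polyline <- function(pl, x_lo, x_hi) {
  x <- pl[, 1L]; y <- pl[, 2L]
  n <- length(x)
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n - 1L)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
    if (x2 < x_lo || x1 > x_hi) next
    if (x1 == x2) {                       # vertical step inside the strip
      ox <- c(ox, x1, x1); oy <- c(oy, y1, y2)
      next
    }
    a <- max(x1, x_lo); b <- min(x2, x_hi)
    if (a > b) next
    ya <- y1 + (y2 - y1) * (a - x1) / (x2 - x1)
    yb <- y1 + (y2 - y1) * (b - x1) / (x2 - x1)
    ox <- c(ox, a, b); oy <- c(oy, ya, yb)
  }
  if (length(ox) == 0L) {
    uc_stop("strip does not intersect the polyline", "empty_strip_error")
  }
  keep <- c(TRUE, diff(ox) != 0 | diff(oy) != 0)
  structure(cbind(x = ox[keep], y = oy[keep]), class = "polyline")
}

#' A calibrated two-border cartilage segmentation
#'
#' The unit of geometric measurement: the superior synovial-cartilage border,
#' the inferior cartilage-bone border, the manually identified central point
#' (the middle of the synovial-cartilage border between the medial and lateral
#' condylar upslopes), the pixel calibration, and which x direction is medial.
#'
#' Invariants enforced: both borders span the identical x-extent; the superior
#' border lies strictly above (smaller y than) the inferior border at every
#' interior x; the central point's x falls strictly inside the extent. Only
#' the central point's x-coordinate is used geometrically (the partition is a
#' medio-lateral split); its y is retained for provenance.
#'
#' @param superior,inferior [polyline()]s or 2-column matrices (pixels)
#' @param central_point numeric `c(x, y)` in pixels
#' @param calibration an [image_calibration()]
#' @param medial_direction `"+x"` if the medial side is toward increasing x,
#'   `"-x"` otherwise (depends on probe orientation / limb side)
#' @param meta optional named list of provenance (subject, limb, session, ...)
#' @return a `cartilage_segmentation` object
#' @export
cartilage_segmentation <- function(superior, inferior, central_point,
                                   calibration,
                                   medial_direction = c("+x", "-x"),
                                   meta = list()) {
  superior <- as_polyline(superior)
  inferior <- as_polyline(inferior)
  medial_direction <- match.arg(medial_direction)
  if (!inherits(calibration, "image_calibration")) {
    uc_stop("calibration must be an image_calibration object",
            "calibration_error")
  }
  if (!is.numeric(central_point) || length(central_point) != 2L ||
      !all(is.finite(central_point))) {
    uc_stop("central_point must be finite c(x, y)", "segmentation_error")
  }
  ns <- nrow(superior); ni <- nrow(inferior)
  if (superior[1L, 1L] != inferior[1L, 1L] ||
      superior[ns, 1L] != inferior[ni, 1L]) {
    uc_stop("superior and inferior borders must share first and last x",
            "segmentation_error")
  }
  xmin <- superior[1L, 1L]; xmax <- superior[ns, 1L]
  cx <- central_point[1L]
  if (cx <= xmin || cx >= xmax) {
    uc_stop("central point x must lie strictly inside the shared x-extent",
            "segmentation_error")
  }
  # both borders are linear between adjacent knots of the union grid, so the
  # vertical gap is linear there: gap > 0 at every interior knot and >= 0 at
  # the shared endpoints guarantees no interior touch or crossing
  knots <- sort(unique(c(superior[, 1L], inferior[, 1L])))
  for (x0 in knots) {
    gap_lo <- min(border_values_at(inferior, x0)) -
      max(border_values_at(superior, x0))
    limit <- if (x0 > xmin && x0 < xmax) 0 else -1e-12
    if (gap_lo <= limit) {
      uc_stop(sprintf(
        "borders touch or cross at x = %g (superior must be above inferior)",
        x0), "segmentation_error")
    }
  }
  structure(list(superior = superior, inferior = inferior,
                 central_point = as.numeric(central_point),
                 calibration = calibration,
                 medial_direction = medial_direction,
                 meta = meta),
            class = "cartilage_segmentation")
}

#' @export
print.cartilage_segmentation <- function(x, ...) {
  ext <- segmentation_extent(x)
  cat(sprintf(
    "cartilage_segmentation: x-extent [%g, %g] px, central x = %g px, medial %s\n",
    ext[1L], ext[2L], x$central_point[1L], x$medial_direction))
  cat(sprintf("  calibration: %g x %g mm/px; %d + %d border vertices\n",
              x$calibration$mm_per_px_x, x$calibration$mm_per_px_y,
              nrow(x$superior), nrow(x$inferior)))
  invisible(x)
}

segmentation_extent <- function(seg) {
  unname(c(seg$superior[1L, 1L], seg$superior[nrow(seg$superior), 1L]))
}

#' Partition a segmentation into medial / intercondylar / lateral regions
#'
#' The intercondylar region is the middle fraction (default 25%) of the
#' cartilage's medio-lateral x-extent, centered on the central point's x; the
#' medial and lateral regions run from the intercondylar cuts to the
#' respective ends of the extent. Cuts are vertical lines at
#' `central_x +/- fraction/2 * extent_width`. A central point so eccentric
#' that a cut would leave the extent is an error, never a clamp.
#'
#' @param seg a [cartilage_segmentation()]
#' @param fraction width of the central region as a fraction of the x-extent
#' @return a `region_partition`: list with `cut_lo`, `cut_hi`, `extent`
#' @export
partition_regions <- function(seg, fraction = 0.25) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    uc_stop("fraction must be in (0, 1)", "partition_error")
  }
  ext <- segmentation_extent(seg)
  width <- ext[2L] - ext[1L]
  cx <- seg$central_point[1L]
  cut_lo <- cx - fraction / 2 * width
  cut_hi <- cx + fraction / 2 * width
  if (cut_lo <= ext[1L] || cut_hi >= ext[2L]) {
    uc_stop(sprintf(
      "degenerate partition: cuts (%g, %g) fall outside extent [%g, %g]",
      cut_lo, cut_hi, ext[1L], ext[2L]), "degenerate_partition_error")
  }
  structure(list(cut_lo = cut_lo, cut_hi = cut_hi, extent = ext),
            class = "region_partition")
}

#' Cross-sectional area of the cartilage band within an x-strip
#'
#' Both borders are clipped to `[x_lo, x_hi]` (interpolated vertices inserted
#' at the cuts), the clipped chains are joined into a closed polygon, and the
#' signed shoelace area is taken on millimetre coordinates
#' (`x * mm_per_px_x`, `y * mm_per_px_y`).
#'
#' @param seg a [cartilage_segmentation()]
#' @param x_lo,x_hi strip bounds in pixels, `x_lo < x_hi`, within the extent
#' @return area in mm^2
#' @export
region_csa <- function(seg, x_lo, x_hi) {
  check_strip(seg, x_lo, x_hi)
  sup <- clip_polyline(seg$superior, x_lo, x_hi)
  inf <- clip_polyline(seg$inferior, x_lo, x_hi)
  mmx <- seg$calibration$mm_per_px_x
  mmy <- seg$calibration$mm_per_px_y
  # closed polygon: superior left->right, inferior right->left
  px <- c(sup[, 1L], rev(inf[, 1L])) * mmx
  py <- c(sup[, 2L], rev(inf[, 2L])) * mmy
  abs(shoelace(px, py))
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))             # previous index, wrapping
  sum(x[j] * y - x * y[j]) / 2
}

check_strip <- function(seg, x_lo, x_hi) {
  ext <- segmentation_extent(seg)
  if (!is.finite(x_lo) || !is.finite(x_hi) || x_lo >= x_hi) {
    uc_stop("need x_lo < x_hi", "empty_strip_error")
  }
  if (x_lo < ext[1L] - 1e-9 || x_hi > ext[2L] + 1e-9) {
    uc_stop(sprintf("strip [%g, %g] outside extent [%g, %g]",
                    x_lo, x_hi, ext[1L], ext[2L]), "empty_strip_error")
  }
  invisible(TRUE)
}

#' Arc length of the cartilage-bone interface within an x-strip
#'
#' The inferior border is clipped to `[x_lo, x_hi]` and the Euclidean lengths
#' of its segments are summed, each segment converted to millimetres
#' component-wise before the norm, so anisotropic calibration is honored.
#'
#' @inheritParams region_csa
#' @return length in mm
#' @export
bone_interface_length <- function(seg, x_lo, x_hi) {
  check_strip(seg, x_lo, x_hi)
  inf <- clip_polyline(seg$inferior, x_lo, x_hi)
  dx <- diff(inf[, 1L]) * seg$calibration$mm_per_px_x
  dy <- diff(inf[, 2L]) * seg$calibration$mm_per_px_y
  sum(sqrt(dx^2 + dy^2))
}

#' Regional mean cartilage thickness
#'
#' Partitions the segmentation (see [partition_regions()]) and, for each of
#' the medial, intercondylar, and lateral regions, computes the CSA, the
#' cartilage-bone interface length, and their ratio -- the mean thickness.
#' Region labels follow `medial_direction`: the medial region is the outer
#' strip on the medial side.
#'
#' @inheritParams partition_regions
#' @return a data.frame (class `region_metrics`) with columns `region`,
#'   `csa_mm2`, `bone_length_mm`, `thickness_mm`
#' @export
#' @examples
#' seg <- make_phantom(phantom_spec())$segmentation
#' compute_thickness(seg)
compute_thickness <- function(seg, fraction = 0.25) {
  part <- partition_regions(seg, fraction)
  ext <- part$extent
  strips <- list(left  = c(ext[1L], part$cut_lo),
                 mid   = c(part$cut_lo, part$cut_hi),
                 right = c(part$cut_hi, ext[2L]))
  labels <- if (seg$medial_direction == "+x") {
    c(left = "lateral", mid = "intercondylar", right = "medial")
  } else {
    c(left = "medial", mid = "intercondylar", right = "lateral")
  }
  rows <- lapply(names(strips), function(nm) {
    s <- strips[[nm]]
    csa <- region_csa(seg, s[1L], s[2L])
    len <- bone_interface_length(seg, s[1L], s[2L])
    data.frame(region = labels[[nm]], csa_mm2 = csa, bone_length_mm = len,
               thickness_mm = csa / len, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[match(REGIONS, out$region), ]
  rownames(out) <- NULL
  class(out) <- c("region_metrics", "data.frame")
  out
}

## ---- independent geometric oracles -------------------------------------
## Different algorithms from the production path (column sampling and dense
## resampling instead of polygon clipping + shoelace); used by tests and to
## stamp ground truth on non-flat phantoms.

#' Rasterization-style CSA oracle (sub-pixel column sampling)
#'
#' Midpoint-rule integral of the vertical gap `inferior(x) - superior(x)`
#' over the strip, sampled every `dx` pixels. Independent of the polygon
#' clipping / shoelace path; agreement to <0.1% is a core correctness check.
#'
#' @inheritParams region_csa
#' @param dx sampling step in pixels (default 0.01 px)
#' @return area in mm^2
#' @export
oracle_region_csa <- function(seg, x_lo, x_hi, dx = 0.01) {
  check_strip(seg, x_lo, x_hi)
  xs <- seq(x_lo + dx / 2, x_hi, by = dx)
  xs <- xs[xs < x_hi]
  gap <- eval_border(seg$inferior, xs) - eval_border(seg$superior, xs)
  sum(gap) * dx * seg$calibration$mm_per_px_x * seg$calibration$mm_per_px_y
}

#' Dense-resampling oracle for the bone-interface length
#'
#' Resamples the clipped inferior border on a fine x-grid that includes the
#' original vertices (adding collinear points leaves a polyline's length
#' unchanged, so for piecewise-linear borders this is exact up to rounding).
#'
#' @inheritParams region_csa
#' @param n number of extra uniformly spaced sample points
#' @return length in mm
#' @export
oracle_bone_length <- function(seg, x_lo, x_hi, n = 20000L) {
  check_strip(seg, x_lo, x_hi)
  vx <- seg$inferior[, 1L]
  xs <- sort(unique(c(x_lo, x_hi, vx[vx > x_lo & vx < x_hi],
                      seq(x_lo, x_hi, length.out = n))))
  ys <- eval_border(seg$inferior, xs)
  dx <- diff(xs) * seg$calibration$mm_per_px_x
  dy <- diff(ys) * seg$calibration$mm_per_px_y
  sum(sqrt(dx^2 + dy^2))
}
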