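## Segmentation-level phantoms: two-border cartilage bands with known
## regional thickness, over flat / sloped / bicondylar bone profiles.
##
## Phantom convention: the superior border sits a *vertical* thickness above
## the inferior (bone) border. This makes flat-bone regional truth exact and
## sloped-bone truth analytically derivable (mean thickness = vertical-gap
## area / arc length, strictly below the vertical gap whenever the bone is
## not horizontal, because arc >= chord). It is a phantom convention, not an
## anatomical claim about normal-direction thickness.

#' Specification of a cartilage phantom
#'
#' Defaults describe a band resembling a transverse suprapatellar view at
#' 0.1 mm/px: a 400-px (40 mm) medio-lateral extent, regional thickness
#' 2.0 / 2.5 / 2.0 mm (medial / intercondylar / lateral -- the intercondylar
#' cartilage of this view is the thickest), and a bicondylar bone profile
#' with gentle condyle upslopes and a central notch.
#'
#' @param x_extent_px medio-lateral extent in pixels
#' @param bone_profile `"flat"`, `"sloped"`, or `"bicondylar"`
#' @param bone_y_px baseline bone depth (pixels, y-down)
#' @param slope bone slope in px/px (sloped profile)
#' @param condyle_amplitude_px height of the two condyle crests (bicondylar)
#' @param notch_depth_px extra depth of the intercondylar notch (bicondylar)
#' @param thickness_mm length-3 numeric `c(medial, intercondylar, lateral)`
#'   regional thickness in mm (piecewise constant with steps exactly at the
#'   region cuts), or a `function(x_px)` returning mm
#' @param central_x_px x of the central point; default mid-extent
#' @param region_fraction width of the intercondylar region (default 0.25)
#' @param calibration an [image_calibration()]; default 0.1 mm/px isotropic
#' @param medial_direction which x direction is medial
#' @param vertex_spacing_px border vertex spacing in px
#' @param noise_sd_px SD of Gaussian y-jitter added to interior border
#'   vertices (0 = exact phantom)
#' @param seed RNG seed for the jitter (determinism contract)
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(x_extent_px = 400,
                         bone_profile = c("flat", "sloped", "bicondylar"),
                         bone_y_px = 150,
                         slope = 0.1,
                         condyle_amplitude_px = 25,
                         notch_depth_px = 12,
                         thickness_mm = c(2.0, 2.5, 2.0),
                         central_x_px = x_extent_px / 2,
                         region_fraction = 0.25,
                         calibration = image_calibration(0.1, 0.1),
                         medial_direction = c("-x", "+x"),
                         vertex_spacing_px = 2,
                         noise_sd_px = 0,
                         seed = NULL) {
  bone_profile <- match.arg(bone_profile)
  medial_direction <- match.arg(medial_direction)
  if (is.numeric(thickness_mm)) {
    if (length(thickness_mm) != 3L || any(thickness_mm <= 0)) {
      uc_stop("regional thickness must be 3 positive values (mm)",
              "invalid_spec_error")
    }
  } else if (!is.function(thickness_mm)) {
    uc_stop("thickness_mm must be numeric[3] or a function of x (px)",
            "invalid_spec_error")
  }
  if (noise_sd_px < 0) uc_stop("noise SD must be >= 0", "invalid_spec_error")
  if (x_extent_px <= 4 * vertex_spacing_px) {
    uc_stop("extent too small for the vertex spacing", "invalid_spec_error")
  }
  structure(list(x_extent_px = x_extent_px, bone_profile = bone_profile,
                 bone_y_px = bone_y_px, slope = slope,
                 condyle_amplitude_px = condyle_amplitude_px,
                 notch_depth_px = notch_depth_px,
                 thickness_mm = thickness_mm, central_x_px = central_x_px,
                 region_fraction = region_fraction,
                 calibration = calibration,
                 medial_direction = medial_direction,
                 vertex_spacing_px = vertex_spacing_px,
                 noise_sd_px = noise_sd_px, seed = seed),
            class = "phantom_spec")
}

bone_profile_fun <- function(spec) {
  L <- spec$x_extent_px
  switch(spec$bone_profile,
    flat = function(x) rep(spec$bone_y_px, length(x)),
    sloped = function(x) spec$bone_y_px + spec$slope * x,
    bicondylar = function(x) {
      t <- x / L
      spec$bone_y_px +
        spec$notch_depth_px * exp(-((t - 0.5) / 0.08)^2) -
        spec$condyle_amplitude_px * (exp(-((t - 0.25) / 0.12)^2) +
                                     exp(-((t - 0.75) / 0.12)^2))
    })
}

## thickness in px at x, honoring the medial/intercondylar/lateral layout
thickness_px_fun <- function(spec) {
  mmy <- spec$calibration$mm_per_px_y
  if (is.function(spec$thickness_mm)) {
    f <- spec$thickness_mm
    return(function(x) f(x) / mmy)
  }
  L <- spec$x_extent_px
  cut_lo <- spec$central_x_px - spec$region_fraction / 2 * L
  cut_hi <- spec$central_x_px + spec$region_fraction / 2 * L
  t <- spec$thickness_mm                     # (medial, intercondylar, lateral)
  left_right <- if (spec$medial_direction == "-x") t[c(1L, 3L)] else t[c(3L, 1L)]
  function(x) {
    ifelse(x < cut_lo, left_right[1L],
           ifelse(x > cut_hi, left_right[2L], t[2L])) / mmy
  }
}

#' Generate a phantom segmentation with ground truth
#'
#' Builds the inferior border from the bone profile and the superior border
#' by a vertical thickness offset, optionally jitters interior vertices, and
#' returns the segmentation together with a `synthetic_truth` record. Truth
#' carries the exact regional thickness for noise-free flat-bone piecewise
#' phantoms, and oracle-computed values (sub-pixel column sampling and dense
#' resampling, see [oracle_region_csa()]) otherwise. Deterministic given
#' `seed`.
#'
#' @param spec a [phantom_spec()]
#' @return list with elements `segmentation` (a [cartilage_segmentation()])
#'   and `truth` (regional thickness, CSA, bone length, and the spec)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- spec$x_extent_px
  cut_lo <- spec$central_x_px - spec$region_fraction / 2 * L
  cut_hi <- spec$central_x_px + spec$region_fraction / 2 * L
  xs <- sort(unique(c(seq(0, L, by = spec$vertex_spacing_px), L,
                      cut_lo, cut_hi)))
  bone <- bone_profile_fun(spec)
  tpx <- thickness_px_fun(spec)
  inf_y <- bone(xs)
  sup_x <- xs; sup_y <- inf_y - tpx(xs)
  if (is.numeric(spec$thickness_mm)) {
    # piecewise-constant profile: duplicate the cut vertices so the superior
    # border steps exactly at the region boundaries
    for (cx in c(cut_lo, cut_hi)) {
      i <- which(sup_x == cx)
      yl <- bone(cx) - tpx(cx - 1e-9)
      yr <- bone(cx) - tpx(cx + 1e-9)
      if (yl != yr) {
        sup_x <- append(sup_x, cx, after = i)
        sup_y[i] <- yl
        sup_y <- append(sup_y, yr, after = i)
      }
    }
  }
  if (spec$noise_sd_px > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    ns <- length(sup_y); ni <- length(inf_y)
    sup_y[2:(ns - 1L)] <- sup_y[2:(ns - 1L)] +
      rnorm(ns - 2L, 0, spec$noise_sd_px)
    inf_y[2:(ni - 1L)] <- inf_y[2:(ni - 1L)] +
      rnorm(ni - 2L, 0, spec$noise_sd_px)
  }
  seg <- tryCatch(
    cartilage_segmentation(polyline(sup_x, sup_y), polyline(xs, inf_y),
                           central_point = c(spec$central_x_px,
                                             bone(spec$central_x_px) -
                                               tpx(spec$central_x_px)),
                           calibration = spec$calibration,
                           medial_direction = spec$medial_direction),
    ultracart_error = function(e) {
      uc_stop(paste0("phantom spec produces an invalid band: ",
                     conditionMessage(e)), "invalid_spec_error")
    })
  list(segmentation = seg, truth = phantom_truth(spec, seg))
}

phantom_truth <- function(spec, seg) {
  exact <- is.numeric(spec$thickness_mm) &&
    spec$bone_profile == "flat" && spec$noise_sd_px == 0
  if (exact) {
    thick <- setNames(spec$thickness_mm, REGIONS)
  } else {
    part <- partition_regions(seg, spec$region_fraction)
    strips <- list(c(part$extent[1L], part$cut_lo),
                   c(part$cut_lo, part$cut_hi),
                   c(part$cut_hi, part$extent[2L]))
    vals <- vapply(strips, function(s) {
      oracle_region_csa(seg, s[1L], s[2L], dx = 0.02) /
        oracle_bone_length(seg, s[1L], s[2L])
    }, numeric(1))
    nm <- if (spec$medial_direction == "+x") {
      c("lateral", "intercondylar", "medial")
    } else c("medial", "intercondylar", "lateral")
    thick <- setNames(vals, nm)[REGIONS]
  }
  structure(list(regional_thickness_mm = thick, exact = exact, spec = spec),
            class = "synthetic_truth")
}

#' Rasterize a phantom segmentation to a binary mask
#'
#' Pixel (row r, column c) has center (x, y) = (c-1, r-1), 0-based, y-down;
#' a pixel is cartilage when its center satisfies
#' `superior(x) <= y < inferior(x)` (half-open toward the bone, so a band of
#' integer thickness t px covers exactly t pixel rows). The frame must
#' contain the whole band.
#'
#' @param seg a [cartilage_segmentation()]
#' @param width,height frame size in pixels; defaults fit the band with a
#'   margin
#' @return integer matrix `height x width` of 0/1
#' @export
rasterize_phantom <- function(seg, width = NULL, height = NULL) {
  ext <- segmentation_extent(seg)
  ymax <- max(seg$inferior[, 2L])
  ymin <- min(seg$superior[, 2L])
  if (is.null(width)) width <- ceiling(ext[2L]) + 2L
  if (is.null(height)) height <- ceiling(ymax) + 3L
  if (ext[1L] < 0 || ext[2L] > width - 1 || ymin < 0 || ymax > height - 1) {
    uc_stop("segmentation does not fit in the frame", "out_of_frame_error")
  }
  mask <- matrix(0L, nrow = height, ncol = width)
  cols <- 0:(width - 1L)
  inside <- cols >= ext[1L] & cols <= ext[2L]
  for (x in cols[inside]) {
    top <- ceiling(eval_border(seg$superior, x))
    bot <- ceiling(eval_border(seg$inferior, x)) - 1L
    if (bot >= top) mask[(top:bot) + 1L, x + 1L] <- 1L
  }
  mask
}

#' Extract border polylines from a binary cartilage mask
#'
#' Per-column top/bottom nonzero pixel extraction: for every column with any
#' cartilage pixel, the superior border vertex is the topmost nonzero pixel
#' center and the inferior border the *lower edge* of the bottommost nonzero
#' pixel (bottom center + 1), matching the half-open rasterization of
#' [rasterize_phantom()]; the pair round-trips a band of integer thickness
#' exactly and any band to within 1 px. Columns with cartilage must be
#' contiguous.
#'
#' @param mask numeric/integer matrix (rows = y), cartilage = nonzero
#' @return list with `superior` and `inferior` [polyline()]s (pixel coords)
#' @export
mask_to_borders <- function(mask) {
  nz <- which(colSums(mask != 0) > 0)
  if (length(nz) < 2L) {
    uc_stop("mask has fewer than 2 cartilage columns", "mask_error")
  }
  if (any(diff(nz) != 1L)) {
    uc_stop("cartilage columns are not contiguous", "mask_error")
  }
  top <- vapply(nz, function(j) min(which(mask[, j] != 0)), integer(1))
  bot <- vapply(nz, function(j) max(which(mask[, j] != 0)), integer(1))
  list(superior = polyline(nz - 1, top - 1),
       inferior = polyline(nz - 1, bot))
}
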