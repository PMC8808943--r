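## Format readers/writers. One interchange schema between pipeline stages:
## long-format measurement CSV (subject, limb, region, session, image_index,
## thickness_mm). Contours travel as a per-image CSV (border, x_px, y_px)
## with a JSON sidecar holding the central point, calibration, medial
## direction, and provenance. Readers reject malformed input rather than
## silently coercing.

#' Write a segmentation as contour CSV + JSON sidecar
#'
#' @param seg a [cartilage_segmentation()]
#' @param csv_path output CSV path; the sidecar is written next to it with
#'   extension `.json`
#' @return invisibly, the sidecar path
#' @export
write_contour_csv <- function(seg, csv_path) {
  df <- rbind(
    data.frame(border = "superior", x_px = seg$superior[, 1L],
               y_px = seg$superior[, 2L]),
    data.frame(border = "inferior", x_px = seg$inferior[, 1L],
               y_px = seg$inferior[, 2L]))
  write.csv(df, csv_path, row.names = FALSE)
  sidecar <- contour_sidecar_path(csv_path)
  meta <- c(list(central_point = seg$central_point,
                 mm_per_px_x = seg$calibration$mm_per_px_x,
                 mm_per_px_y = seg$calibration$mm_per_px_y,
                 medial_direction = seg$medial_direction),
            seg$meta)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

contour_sidecar_path <- function(csv_path) {
  sub("\\.[Cc][Ss][Vv]$", ".json", csv_path)
}

#' Read a contour CSV (+ sidecar) into a segmentation
#'
#' @param csv_path CSV with columns `border` (superior|inferior), `x_px`,
#'   `y_px`
#' @param sidecar_path JSON sidecar; default: the CSV path with `.json`
#' @return a [cartilage_segmentation()]; sidecar provenance in `$meta`
#' @export
read_contour_csv <- function(csv_path, sidecar_path = NULL) {
  if (!file.exists(csv_path)) {
    uc_stop(paste0("no such contour file: ", csv_path), "io_error")
  }
  if (is.null(sidecar_path)) sidecar_path <- contour_sidecar_path(csv_path)
  if (!file.exists(sidecar_path)) {
    uc_stop(paste0("missing sidecar JSON: ", sidecar_path), "io_error")
  }
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("border", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    uc_stop("contour CSV needs columns border, x_px, y_px", "schema_error")
  }
  if (!all(df$border %in% c("superior", "inferior"))) {
    uc_stop("border column must be 'superior' or 'inferior'", "schema_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need_meta <- c("central_point", "mm_per_px_x", "mm_per_px_y",
                 "medial_direction")
  if (!all(need_meta %in% names(meta))) {
    uc_stop(paste0("sidecar lacks fields: ",
                   paste(setdiff(need_meta, names(meta)), collapse = ", ")),
            "schema_error")
  }
  sup <- df[df$border == "superior", ]
  inf <- df[df$border == "inferior", ]
  cartilage_segmentation(
    polyline(sup$x_px, sup$y_px), polyline(inf$x_px, inf$y_px),
    central_point = as.numeric(meta$central_point),
    calibration = image_calibration(meta$mm_per_px_x, meta$mm_per_px_y),
    medial_direction = meta$medial_direction,
    meta = meta[setdiff(names(meta), need_meta)])
}

#' Read an ImageJ .roi file (polygon / freehand / traced outline)
#'
#' Minimal reader for the binary ImageJ ROI format: magic `"Iout"`,
#' big-endian header, 16-bit vertex coordinates relative to the bounding
#' box. Only closed-outline subtypes (polygon = 0, freehand = 7,
#' traced = 8) are supported.
#'
#' @param path file path, or a raw vector of the file bytes
#' @return numeric matrix of vertex `(x, y)` in pixel coordinates
#' @export
read_imagej_roi <- function(path) {
  bytes <- if (is.raw(path)) path else {
    if (!file.exists(path)) {
      uc_stop(paste0("no such .roi file: ", path), "io_error")
    }
    readBin(path, "raw", n = file.size(path))
  }
  if (length(bytes) < 64L) {
    uc_stop("truncated .roi file (shorter than the 64-byte header)",
            "roi_format_error")
  }
  if (!identical(bytes[1:4], charToRaw("Iout"))) {
    uc_stop("bad magic: not an ImageJ .roi file", "roi_format_error")
  }
  be_i16 <- function(off) {                      # signed, big-endian, 0-based
    readBin(bytes[(off + 1L):(off + 2L)], "integer", size = 2L,
            endian = "big", signed = TRUE)
  }
  version <- be_i16(4L)
  type <- as.integer(bytes[7L])
  if (!type %in% c(0L, 7L, 8L)) {
    uc_stop(sprintf("unsupported ROI type %d (need polygon=0, freehand=7, traced=8)",
                    type), "roi_format_error")
  }
  top <- be_i16(8L); left <- be_i16(10L)
  n <- be_i16(16L)
  if (n < 3L) uc_stop("ROI outline has fewer than 3 vertices",
                      "roi_format_error")
  if (length(bytes) < 64L + 4L * n) {
    uc_stop("truncated .roi file (vertex data missing)", "roi_format_error")
  }
  coord <- readBin(bytes[65:(64L + 4L * n)], "integer", n = 2L * n,
                   size = 2L, endian = "big", signed = TRUE)
  cbind(x = coord[seq_len(n)] + left, y = coord[n + seq_len(n)] + top)
}

#' Split a closed cartilage outline into superior and inferior borders
#'
#' The closed polygon is cut at its minimum-x and maximum-x vertices (first
#' occurrence, in vertex order) into two chains; the chain with the lower
#' mean y (higher on screen) becomes the superior border. Both chains must
#' be x-monotone once oriented left-to-right.
#'
#' @param outline vertex matrix as from [read_imagej_roi()]
#' @return list with `superior` and `inferior` [polyline()]s
#' @export
split_outline <- function(outline) {
  outline <- as.matrix(outline)
  n <- nrow(outline)
  if (n < 4L) uc_stop("outline needs >= 4 vertices", "roi_format_error")
  i_min <- which.min(outline[, 1L])
  rot <- rbind(outline[i_min:n, , drop = FALSE],
               outline[seq_len(i_min - 1L), , drop = FALSE])
  i_max <- which.max(rot[, 1L])
  chain1 <- rot[1:i_max, , drop = FALSE]
  chain2 <- rbind(rot[i_max:nrow(rot), , drop = FALSE], rot[1L, , drop = FALSE])
  # drop the short vertical end edges of the outline (the band's left/right
  # closing edges): keep, at each end, only the vertex adjacent to the
  # interior of the chain
  trim_ends <- function(m) {
    xs <- m[, 1L]
    i0 <- max(which(xs == xs[1L]))
    i1 <- min(which(xs == xs[length(xs)]))
    if (i0 >= i1) uc_stop("outline chain is degenerate", "roi_format_error")
    m[i0:i1, , drop = FALSE]
  }
  mk <- function(ch) {
    p <- polyline(ch[, 1L], ch[, 2L])
    p <- trim_ends(unclass(p))
    polyline(p[, 1L], p[, 2L])
  }
  p1 <- mk(chain1)
  p2 <- mk(chain2)
  if (mean(p1[, 2L]) <= mean(p2[, 2L])) {
    list(superior = p1, inferior = p2)
  } else {
    list(superior = p2, inferior = p1)
  }
}

#' Read / write a binary cartilage mask as grayscale PNG
#'
#' Cartilage pixels are nonzero. Writing stores 0/255 8-bit grayscale.
#'
#' @param path PNG file path
#' @return [read_mask_png()]: integer 0/1 matrix (rows = y)
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) {
    uc_stop(paste0("no such PNG: ", path), "io_error")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  (img > 0) * 1L
}

#' @rdname read_mask_png
#' @param mask integer/numeric matrix, cartilage = nonzero
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

#' Read / write long-format measurement tables
#'
#' The interchange schema between pipeline stages: columns `subject`,
#' `limb`, `region`, `session`, `image_index`, `thickness_mm` (`limb` and
#' `image_index` optional on read).
#'
#' @param path CSV path
#' @return data.frame of measurements
#' @export
read_measurements_csv <- function(path) {
  if (!file.exists(path)) {
    uc_stop(paste0("no such measurements file: ", path), "io_error")
  }
  check_measurements(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_measurements_csv
#' @param measurements data.frame to write
#' @export
write_measurements_csv <- function(measurements, path) {
  write.csv(check_measurements(measurements), path, row.names = FALSE)
  invisible(path)
}
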