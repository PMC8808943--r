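# Fixtures are built in code; no binary files on disk.

# flat horizontal band: superior y = sup_y, inferior y = inf_y
flat_seg <- function(sup_y = 80, inf_y = 100, xmax = 400, mm = 0.1,
                     cx = xmax / 2, dir = "-x") {
  cartilage_segmentation(
    superior = polyline(c(0, xmax), c(sup_y, sup_y)),
    inferior = polyline(c(0, xmax), c(inf_y, inf_y)),
    central_point = c(cx, sup_y),
    calibration = image_calibration(mm, mm),
    medial_direction = dir)
}

# uniform-vertical-gap sloped band: superior (0,80)->(400,120),
# inferior (0,100)->(400,140)
sloped_seg <- function(mm = 0.1) {
  cartilage_segmentation(
    superior = polyline(c(0, 400), c(80, 120)),
    inferior = polyline(c(0, 400), c(100, 140)),
    central_point = c(200, 100),
    calibration = image_calibration(mm, mm),
    medial_direction = "-x")
}

# randomized smooth phantom for property checks (deterministic per seed)
random_phantom <- function(seed) {
  set.seed(seed)
  ext <- sample(250:450, 1)
  spec <- phantom_spec(
    x_extent_px = ext,
    bone_profile = sample(c("flat", "sloped", "bicondylar"), 1),
    slope = stats::runif(1, -0.15, 0.15),
    condyle_amplitude_px = stats::runif(1, 10, 30),
    notch_depth_px = stats::runif(1, 5, 15),
    thickness_mm = stats::runif(3, 1.5, 3.0),
    central_x_px = ext * stats::runif(1, 0.4, 0.6),
    noise_sd_px = stats::runif(1, 0, 0.5),
    seed = seed + 1000L)
  make_phantom(spec)
}

# mirror a segmentation in x and flip the medial direction
mirror_seg <- function(seg) {
  xmax <- seg$superior[nrow(seg$superior), 1]
  flip <- function(pl) polyline(rev(xmax - pl[, 1]), rev(pl[, 2]))
  cartilage_segmentation(
    flip(seg$superior), flip(seg$inferior),
    central_point = c(xmax - seg$central_point[1], seg$central_point[2]),
    calibration = seg$calibration,
    medial_direction = if (seg$medial_direction == "+x") "-x" else "+x")
}

# rescale the calibration of a segmentation by factor c (isotropic)
rescale_seg <- function(seg, c) {
  cal <- seg$calibration
  cartilage_segmentation(
    seg$superior, seg$inferior, seg$central_point,
    image_calibration(cal$mm_per_px_x * c, cal$mm_per_px_y * c),
    seg$medial_direction)
}

# evaluate a border polyline at given x (right-limit at vertical steps)
eval_border_for_test <- function(pl, xout) {
  ultracart:::eval_border(pl, xout)
}

# hand-assembled ImageJ .roi bytes (big-endian, 64-byte header, short coords)
roi_bytes <- function(x, y, type = 0L, version = 226L) {
  n <- length(x)
  left <- min(x); top <- min(y)
  w16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "big")
  h <- raw(64)
  h[1:4] <- charToRaw("Iout")
  h[5:6] <- w16(version)
  h[7] <- as.raw(type)
  h[9:10] <- w16(top)
  h[11:12] <- w16(left)
  h[13:14] <- w16(max(y) + 1L)
  h[15:16] <- w16(max(x) + 1L)
  h[17:18] <- w16(n)
  c(h, w16(x - left), w16(y - top))
}
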