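#' Cine-like edge phantom configuration
#'
#' Describes a grayscale frame containing a tilted ellipse of blood-pool
#' intensity on a myocardium-intensity background, separated by a
#' linear-ramp edge of known width measured normal to the boundary — a
#' controlled stand-in for the myocardium/blood-pool boundary of a bright
#' blood cine frame, used to validate the sharpness pipeline.
#'
#' @param image_size image size in pixels, scalar or `c(nx, ny)`.
#' @param pixel_spacing_mm isotropic pixel spacing (mm), default 1.5 (the
#'   in-plane cine voxel size).
#' @param blood_intensity,myocardium_intensity plateau intensities
#'   (arbitrary units, unequal).
#' @param edge_width_mm full transition width of the linear ramp (> 0). The
#'   20-80 percent rise distance of such a ramp is `0.6 * edge_width_mm`,
#'   so the ground-truth sharpness is `1 / (0.6 * edge_width_mm)`.
#' @param center_mm ellipse center (mm); default image center.
#' @param semi_axes_mm ellipse semi-axes (mm), major then minor.
#' @param tilt_deg rotation of the major axis from the x-axis (degrees).
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param seed integer seed for the noise.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 96, pixel_spacing_mm = 1.5,
                           blood_intensity = 900, myocardium_intensity = 300,
                           edge_width_mm = 3, center_mm = NULL,
                           semi_axes_mm = c(40, 28), tilt_deg = 20,
                           noise_sd = 0, seed = 1) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  if (!is_number(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop_stage("phantom", "pixel spacing must be > 0")
  if (!is_number(edge_width_mm) || edge_width_mm <= 0)
    stop_stage("phantom", "edge width must be > 0")
  if (blood_intensity == myocardium_intensity)
    stop_stage("phantom", "blood-pool and myocardium intensities must differ")
  if (is.null(center_mm)) center_mm <- image_size * pixel_spacing_mm / 2
  if (any(semi_axes_mm <= 0)) stop_stage("phantom", "semi-axes must be > 0")
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing_mm = pixel_spacing_mm,
                 blood_intensity = blood_intensity,
                 myocardium_intensity = myocardium_intensity,
                 edge_width_mm = edge_width_mm, center_mm = center_mm,
                 semi_axes_mm = semi_axes_mm, tilt_deg = tilt_deg,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# Signed distance (mm, positive outside) from points to an axis-aligned
# ellipse with semi-axes a >= along x, b along y. Exact within `band` of the
# boundary via damped Newton on the boundary angle; far points get the fast
# algebraic approximation (only their sign matters for rendering).
ellipse_signed_distance <- function(px, py, a, b, band) {
  qx <- abs(px); qy <- abs(py)
  inside <- (px / a)^2 + (py / b)^2 < 1
  # algebraic first guess
  f <- sqrt((px / a)^2 + (py / b)^2) - 1
  gn <- sqrt((px / a^2)^2 + (py / b^2)^2)
  approx_d <- ifelse(gn > 0, f * (sqrt((px/a)^2 + (py/b)^2) + 1e-12) / (gn + 1e-12), -b)
  d <- approx_d
  near <- abs(approx_d) < band
  if (any(near)) {
    x <- qx[near]; y <- qy[near]
    th <- atan2(a * y, b * x)
    for (i in 1:12) {
      c0 <- cos(th); s0 <- sin(th)
      g <- (b^2 - a^2) * s0 * c0 + a * x * s0 - b * y * c0
      gp <- (b^2 - a^2) * (c0^2 - s0^2) + a * x * c0 + b * y * s0
      step <- g / ifelse(abs(gp) > 1e-12, gp, 1e-12)
      step <- pmax(pmin(step, 0.5), -0.5)
      th <- pmin(pmax(th - step, 0), pi / 2)
    }
    dn <- sqrt((a * cos(th) - x)^2 + (b * sin(th) - y)^2)
    d[near] <- ifelse(inside[near], -dn, dn)
  }
  d[!near] <- ifelse(inside[!near], -abs(d[!near]), abs(d[!near]))
  d
}

#' Render a cine-like edge phantom frame
#'
#' Produces the grayscale image described by a [phantom_config()] together
#' with its JSON-able sidecar metadata. Intensity at each pixel center is
#' `myocardium + (blood - myocardium) * clamp(1/2 - d/w, 0, 1)` where `d` is
#' the signed distance to the ellipse boundary (positive outside) and `w`
#' the edge width, i.e. a linear ramp of width `w` normal to the boundary.
#' Seeded Gaussian noise is added when `noise_sd > 0`. Edges narrower than
#' two pixel spacings set the `under_resolved` sidecar flag.
#'
#' @param config a [phantom_config()].
#' @return An object of class `phantom_frame`: list with `image` (numeric
#'   matrix, rows = y) and `sidecar` (pixel spacing, ground-truth edge width
#'   and sharpness, seed, flags).
#' @export
render_phantom_frame <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  nx <- config$image_size[1]; ny <- config$image_size[2]
  sp <- config$pixel_spacing_mm
  xs <- (seq_len(nx) - 0.5) * sp - config$center_mm[1]
  ys <- (seq_len(ny) - 0.5) * sp - config$center_mm[2]
  th <- config$tilt_deg * pi / 180
  X <- matrix(rep(xs, each = ny), nrow = ny)
  Y <- matrix(rep(ys, times = nx), nrow = ny)
  # rotate into the ellipse frame
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  w <- config$edge_width_mm
  d <- ellipse_signed_distance(as.vector(U), as.vector(V),
                               config$semi_axes_mm[1], config$semi_axes_mm[2],
                               band = w + 4 * sp)
  frac <- pmin(pmax(0.5 - d / w, 0), 1)
  img <- config$myocardium_intensity +
    (config$blood_intensity - config$myocardium_intensity) * frac
  img <- matrix(img, nrow = ny)
  if (config$noise_sd > 0) {
    img <- img + with_seed_or_current(config$seed,
      matrix(stats::rnorm(length(img), 0, config$noise_sd), nrow = ny))
  }
  structure(list(
    image = img,
    sidecar = list(
      pixel_spacing_mm = sp,
      edge_width_mm = w,
      seed = config$seed,
      ground_truth_sharpness = 1 / (0.6 * w),
      under_resolved = w < 2 * sp,
      blood_intensity = config$blood_intensity,
      myocardium_intensity = config$myocardium_intensity,
      semi_axes_mm = config$semi_axes_mm,
      tilt_deg = config$tilt_deg,
      noise_sd = config$noise_sd
    )), class = "phantom_frame")
}

#' @export
print.phantom_frame <- function(x, ...) {
  cat(sprintf(
    "Phantom frame %dx%d px @ %.2f mm, edge width %.1f mm (sharpness truth %.3f /mm)%s\n",
    ncol(x$image), nrow(x$image), x$sidecar$pixel_spacing_mm,
    x$sidecar$edge_width_mm, x$sidecar$ground_truth_sharpness,
    if (isTRUE(x$sidecar$under_resolved)) " [ramp under-resolved]" else ""))
  invisible(x)
}

#' Write / read a phantom frame as grayscale image plus JSON sidecar
#'
#' TIFF files (`.tif`/`.tiff`) are written with 16-bit depth, PNG files
#' (`.png`) with 8-bit depth. Intensities are linearly mapped onto the full
#' sample range; the mapping is stored in the sidecar (`intensity_range`) so
#' reading restores absolute units to within the quantization step.
#'
#' @param frame a `phantom_frame`.
#' @param path path of the image; the sidecar is written to `<path>.json`.
#' @return `read_phantom_image` returns a `phantom_frame`; the writer
#'   returns `path` invisibly.
#' @export
write_phantom_image <- function(frame, path) {
  stopifnot(inherits(frame, "phantom_frame"))
  lo <- min(frame$image); hi <- max(frame$image)
  rng <- if (hi > lo) c(lo, hi) else c(lo, lo + 1)
  norm <- (frame$image - rng[1]) / (rng[2] - rng[1])
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(norm, path, bits.per.sample = 16)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(norm, path)
  } else {
    stop_stage("phantom-io", "unsupported image extension: ", path)
  }
  sc <- frame$sidecar
  sc$intensity_range <- rng
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 10)
  invisible(path)
}

#' @rdname write_phantom_image
#' @export
read_phantom_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rng <- sc$intensity_range
  structure(list(image = img * (rng[2] - rng[1]) + rng[1], sidecar = sc),
            class = "phantom_frame")
}
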