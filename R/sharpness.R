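#' Sharpness analysis configuration
#'
#' Parameters of the edge-sharpness workflow: ROI crop, bilinear
#' upsampling, Deriche first-derivative edge image, threshold + Hough
#' longest-line detection, and orthogonal intensity profiles whose 20-80
#' percent rise distances define sharpness as mean(1/d).
#'
#' @param roi ROI as `c(x0, y0, x1, y1)` in pixels (1-based, inclusive), or
#'   `NULL` for the full image.
#' @param upsample_factor integer bilinear upsampling factor (>= 1).
#' @param deriche_alpha Deriche filter scale (dimensionless, on the
#'   upsampled grid; larger = less smoothing).
#' @param edge_threshold_fraction gradient threshold as a fraction of the
#'   maximum gradient magnitude, in (0, 1].
#' @param n_profiles number of orthogonal intensity profiles (default 8).
#' @param profile_half_length half-length of each profile in mm.
#' @param profile_sample_step sampling step along profiles, in upsampled
#'   pixels.
#' @param min_line_px minimum collinear run (upsampled pixels) for a
#'   detection to count as an edge.
#' @return An object of class `sharpness_config`.
#' @export
sharpness_config <- function(roi = NULL, upsample_factor = 4,
                             deriche_alpha = 1.0,
                             edge_threshold_fraction = 0.5,
                             n_profiles = 8, profile_half_length = 8,
                             profile_sample_step = 0.25,
                             min_line_px = 10) {
  if (!is_number(upsample_factor) || upsample_factor < 1)
    stop_stage("sharpness-config", "upsample_factor must be >= 1")
  if (!is_number(deriche_alpha) || deriche_alpha <= 0)
    stop_stage("sharpness-config", "deriche_alpha must be > 0")
  if (!is_number(edge_threshold_fraction) || edge_threshold_fraction <= 0 ||
      edge_threshold_fraction > 1)
    stop_stage("sharpness-config", "edge_threshold_fraction must be in (0, 1]")
  if (!is_number(n_profiles) || n_profiles < 1)
    stop_stage("sharpness-config", "n_profiles must be >= 1")
  if (!is_number(profile_half_length) || profile_half_length <= 0 ||
      !is_number(profile_sample_step) || profile_sample_step <= 0)
    stop_stage("sharpness-config", "profile geometry must be positive")
  structure(list(roi = roi, upsample_factor = as.integer(upsample_factor),
                 deriche_alpha = deriche_alpha,
                 edge_threshold_fraction = edge_threshold_fraction,
                 n_profiles = as.integer(n_profiles),
                 profile_half_length = profile_half_length,
                 profile_sample_step = profile_sample_step,
                 min_line_px = min_line_px),
            class = "sharpness_config")
}

#' Crop and bilinearly upsample a region of interest
#'
#' Bilinear resampling by an integer factor in both dimensions with
#' endpoint-aligned geometry: output pixel `j` samples input coordinate
#' `1 + (j-1)/factor`, so the output has `(n-1)*factor + 1` samples per
#' axis, factor 1 is an identity crop, and the effective pixel spacing is
#' divided by `factor`.
#'
#' @param image numeric matrix (rows = y).
#' @param roi `c(x0, y0, x1, y1)` in pixels, or `NULL` for the full image.
#' @param factor integer upsampling factor (>= 1).
#' @return Upsampled numeric matrix.
#' @export
upsample_roi <- function(image, roi = NULL, factor = 4) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_stage("upsample", "image must be a numeric matrix")
  if (is.null(roi)) roi <- c(1, 1, ncol(image), nrow(image))
  roi <- as.integer(round(roi))
  if (roi[1] < 1 || roi[2] < 1 || roi[3] > ncol(image) ||
      roi[4] > nrow(image) || roi[1] >= roi[3] || roi[2] >= roi[4])
    stop_stage("upsample", "roi outside image or empty")
  crop <- image[roi[2]:roi[4], roi[1]:roi[3], drop = FALSE]
  factor <- as.integer(factor)
  if (factor == 1L) return(crop)
  nx <- (ncol(crop) - 1L) * factor + 1L
  ny <- (nrow(crop) - 1L) * factor + 1L
  xo <- 1 + (seq_len(nx) - 1) / factor
  yo <- 1 + (seq_len(ny) - 1) / factor
  matrix(bilinear_sample(crop,
                         x = rep(xo, each = ny),
                         y = rep(yo, times = nx)),
         nrow = ny)
}

# --- Deriche recursive filtering -------------------------------------------
# Smoothing kernel s(n) = k (alpha|n| + 1) e^{-alpha|n|} (unit DC gain) and
# antisymmetric first-derivative kernel proportional to -n e^{-alpha|n|},
# both implemented as causal + anticausal second-order recursions. The
# derivative is normalized empirically to unit response on a unit-slope
# ramp, so gradient units are intensity per (upsampled) pixel.

deriche_pad <- function(alpha) max(8L, as.integer(ceiling(20 / alpha)))

# shift matrix rows down by k with edge replication (row 1 repeated)
shift_down <- function(m, k) {
  n <- nrow(m)
  m[c(rep(1L, k), seq_len(n - k)), , drop = FALSE]
}

deriche_pass_cols <- function(m, alpha, type = c("smooth", "derive")) {
  type <- match.arg(type)
  e <- exp(-alpha)
  b1 <- 2 * e; b2 <- -e^2
  pad <- deriche_pad(alpha)
  n <- nrow(m)
  mp <- m[c(rep(1L, pad), seq_len(n), rep(n, pad)), , drop = FALSE]
  if (type == "smooth") {
    k <- (1 - e)^2 / (1 + 2 * alpha * e - e^2)
    a0 <- k; a1 <- k * e * (alpha - 1)
    a2 <- k * e * (alpha + 1); a3 <- -k * e^2
    zc <- a0 * mp + a1 * shift_down(mp, 1L)
    yc <- stats::filter(zc, c(b1, b2), method = "recursive")
    mr <- mp[rev(seq_len(nrow(mp))), , drop = FALSE]
    za <- a2 * shift_down(mr, 1L) + a3 * shift_down(mr, 2L)
    ya <- stats::filter(za, c(b1, b2), method = "recursive")
    ya <- ya[rev(seq_len(nrow(ya))), , drop = FALSE]
  } else {
    zc <- shift_down(mp, 1L)
    yc <- stats::filter(zc, c(b1, b2), method = "recursive")
    mr <- mp[rev(seq_len(nrow(mp))), , drop = FALSE]
    za <- shift_down(mr, 1L)
    ya <- stats::filter(za, c(b1, b2), method = "recursive")
    ya <- -ya[rev(seq_len(nrow(ya))), , drop = FALSE]
  }
  out <- yc + ya
  matrix(as.numeric(out[pad + seq_len(n), ]), nrow = n)
}

# response of the discrete derivative pass to a unit-slope ramp (per alpha);
# used to normalize gradients to intensity-per-pixel units
deriche_derivative_gain <- function(alpha) {
  n <- 4L * deriche_pad(alpha) + 1L
  ramp <- matrix(seq_len(n), ncol = 1)
  deriche_pass_cols(ramp, alpha, "derive")[(n + 1L) %/% 2L, 1]
}

#' Deriche gradient-magnitude edge image
#'
#' Recursive Deriche smoothing along one axis combined with the recursive
#' Deriche first-derivative along the other, in both orientations; the edge
#' image is the gradient magnitude `sqrt(gx^2 + gy^2)`. Borders are handled
#' by edge replication. Gradients are normalized to intensity units per
#' pixel (unit response on a unit-slope ramp).
#'
#' @param image numeric matrix (rows = y).
#' @param alpha Deriche scale parameter (> 0); smoothing scale ~ 1/alpha
#'   pixels.
#' @return Numeric matrix of gradient magnitudes, same size as `image`.
#' @export
deriche_gradient <- function(image, alpha = 1.0) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_stage("deriche", "image must be a numeric matrix")
  if (any(!is.finite(image)))
    stop_stage("deriche", "image contains non-finite pixels")
  if (!is_number(alpha) || alpha <= 0)
    stop_stage("deriche", "alpha must be > 0")
  gain <- deriche_derivative_gain(alpha)
  gy <- deriche_pass_cols(image, alpha, "derive") / gain
  gy <- t(deriche_pass_cols(t(gy), alpha, "smooth"))
  gx <- t(deriche_pass_cols(t(image), alpha, "derive")) / gain
  gx <- deriche_pass_cols(gx, alpha, "smooth")
  sqrt(gx^2 + gy^2)
}

#' Detect the longest straight edge line by Hough transform
#'
#' Binarizes the gradient image at `threshold_fraction * max(gradient)` and
#' runs a standard (rho, theta) Hough accumulator (theta step 1 degree, rho
#' step 1 pixel). Among the highest-vote bins, the contiguous collinear
#' point run with the greatest spatial extent is returned as a segment;
#' ties break toward higher votes, then smaller theta.
#'
#' @param gradient numeric matrix of gradient magnitudes.
#' @param threshold_fraction fraction of the maximum gradient in (0, 1].
#' @param min_line_px minimum run length (pixels) to accept a line.
#' @return List with `p1`, `p2` (endpoints, pixel coordinates `c(x, y)`),
#'   `theta_deg` (line normal angle), `length_px`, and `votes`.
#' @export
detect_edge_line <- function(gradient, threshold_fraction = 0.5,
                             min_line_px = 10) {
  if (max(gradient) <= 0)
    stop_stage("hough", "no edge: gradient image is empty")
  # thin the supra-threshold band to its ridge (non-maximum suppression
  # along each axis) so the accumulator sees a line, not a stripe
  nr <- nrow(gradient); nc <- ncol(gradient)
  shift <- function(m, dy, dx) {
    ys <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    m[ys, xs, drop = FALSE]
  }
  l <- shift(gradient, 0, -1); r <- shift(gradient, 0, 1)
  u <- shift(gradient, -1, 0); d <- shift(gradient, 1, 0)
  ridge <- ((gradient >= l & gradient > r) | (gradient > l & gradient >= r)) |
    ((gradient >= u & gradient > d) | (gradient > u & gradient >= d))
  idx <- which(ridge & gradient >= threshold_fraction * max(gradient))
  if (!length(idx)) stop_stage("hough", "no edge: no supra-threshold pixels")
  py <- ((idx - 1L) %% nrow(gradient)) + 1L
  px <- ((idx - 1L) %/% nrow(gradient)) + 1L
  thetas <- (0:179) * pi / 180
  rho_off <- ceiling(sqrt(nrow(gradient)^2 + ncol(gradient)^2)) + 2L
  nbin <- 2L * rho_off + 1L
  votes <- matrix(0L, nrow = nbin, ncol = length(thetas))
  for (t in seq_along(thetas)) {
    rho <- round(px * cos(thetas[t]) + py * sin(thetas[t]))
    votes[, t] <- tabulate(rho + rho_off + 1L, nbins = nbin)
  }
  vmax <- max(votes)
  cand <- which(votes >= 0.98 * vmax, arr.ind = TRUE)
  # cap the candidate set (densest bins first) to bound the extent scan
  if (nrow(cand) > 40L) {
    ord <- order(votes[cand], decreasing = TRUE)[1:40]
    cand <- cand[ord, , drop = FALSE]
  }
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    t <- cand[i, 2]; rho0 <- cand[i, 1] - rho_off - 1L
    on_line <- which(round(px * cos(thetas[t]) + py * sin(thetas[t])) == rho0)
    if (!length(on_line)) next
    # position along the line
    s <- -px[on_line] * sin(thetas[t]) + py[on_line] * cos(thetas[t])
    o <- order(s); s <- s[o]; pts <- on_line[o]
    runs <- c(0L, which(diff(s) > 3), length(s))
    for (rlev in seq_len(length(runs) - 1L)) {
      sel <- (runs[rlev] + 1L):runs[rlev + 1L]
      extent <- s[sel[length(sel)]] - s[sel[1]]
      cur <- list(extent = extent, votes = votes[cand[i, 1], t],
                  theta = t - 1L,
                  i1 = pts[sel[1]], i2 = pts[sel[length(sel)]])
      if (is.null(best) ||
          cur$extent > best$extent + 1e-9 ||
          (abs(cur$extent - best$extent) <= 1e-9 &&
           (cur$votes > best$votes ||
            (cur$votes == best$votes && cur$theta < best$theta))))
        best <- cur
    }
  }
  if (is.null(best) || best$extent < min_line_px)
    stop_stage("hough", "no edge: longest collinear run below ",
               min_line_px, " px")
  list(p1 = c(px[best$i1], py[best$i1]), p2 = c(px[best$i2], py[best$i2]),
       theta_deg = best$theta, length_px = best$extent, votes = best$votes)
}

#' Orthogonal-profile 20-80 percent rise distances
#'
#' Plots `n_profiles` intensity profiles orthogonal to the detected edge
#' segment, equally spaced over its central 80 percent, each sampled
#' bilinearly. Per profile, the 0.2 and 0.8 levels of that profile's
#' intensity range are located by linear interpolation between samples,
#' taking the crossing pair bracketing the steepest intensity change; the
#' rise distance `d` is their separation in mm. A profile is invalid if a
#' level is crossed more than twice or not at all, or if it leaves the
#' image.
#'
#' @param image upsampled numeric matrix the line was detected on.
#' @param line line as returned by [detect_edge_line()].
#' @param config a [sharpness_config()].
#' @param spacing_mm effective pixel spacing of `image` in mm.
#' @return Data.frame with one row per profile: `d_mm` and `valid`.
#' @export
profile_rise_distance <- function(image, line, config, spacing_mm) {
  u <- line$p2 - line$p1
  len <- sqrt(sum(u^2))
  if (len <= 0) stop_stage("profiles", "degenerate line")
  u <- u / len
  nv <- c(-u[2], u[1])
  np <- config$n_profiles
  frac <- if (np == 1) 0.5 else 0.1 + 0.8 * (seq_len(np) - 1) / (np - 1)
  hl_px <- config$profile_half_length / spacing_mm
  tseq <- seq(-hl_px, hl_px, by = config$profile_sample_step)
  out <- data.frame(d_mm = rep(NA_real_, np), valid = rep(FALSE, np))
  for (i in seq_len(np)) {
    ctr <- line$p1 + u * frac[i] * len
    xs <- ctr[1] + nv[1] * tseq
    ys <- ctr[2] + nv[2] * tseq
    if (any(xs < 1 | xs > ncol(image) | ys < 1 | ys > nrow(image))) next
    vals <- bilinear_sample(image, xs, ys)
    i_min <- min(vals); i_max <- max(vals)
    if (i_max <= i_min) next
    d <- rise_distance_1d(vals, tseq, i_min, i_max)
    if (!is.na(d)) {
      out$d_mm[i] <- d * spacing_mm
      out$valid[i] <- TRUE
    }
  }
  if (!any(out$valid))
    stop_stage("profiles", "no valid intensity profile across the edge")
  out
}

# 20-80% rise distance of one sampled profile (positions in sample units);
# NA when a level is not crossed exactly once or twice.
rise_distance_1d <- function(vals, pos, i_min, i_max) {
  l20 <- 0.2 * (i_max - i_min) + i_min
  l80 <- 0.8 * (i_max - i_min) + i_min
  cross <- function(level) {
    s <- vals - level
    j <- which(s[-length(s)] * s[-1] < 0 | (s[-length(s)] == 0 & s[-1] != 0))
    pos[j] + (pos[j + 1] - pos[j]) * (level - vals[j]) / (vals[j + 1] - vals[j])
  }
  c20 <- cross(l20); c80 <- cross(l80)
  if (length(c20) < 1 || length(c20) > 2 || length(c80) < 1 || length(c80) > 2)
    return(NA_real_)
  steep <- which.max(abs(diff(vals)))
  p_st <- (pos[steep] + pos[steep + 1]) / 2
  p20 <- c20[which.min(abs(c20 - p_st))]
  p80 <- c80[which.min(abs(c80 - p_st))]
  abs(p80 - p20)
}

#' Edge sharpness of a cine frame
#'
#' Chains the full workflow: ROI crop and bilinear upsampling, Deriche
#' first-derivative edge image, threshold + Hough longest-line detection,
#' and orthogonal 20-80 percent rise-distance profiles. Sharpness is the
#' mean of `1/d` over valid profiles, in 1/mm.
#'
#' @param frame a `phantom_frame`, or a numeric matrix (then
#'   `pixel_spacing_mm` is required).
#' @param config a [sharpness_config()].
#' @param pixel_spacing_mm pixel spacing in mm (taken from the sidecar when
#'   `frame` is a `phantom_frame`).
#' @return An object of class `sharpness_result`: list with `sharpness`
#'   (1/mm), `profiles` (per-profile rise distances + validity), `line`
#'   (endpoints in mm on the upsampled grid), and the effective spacing.
#' @export
compute_sharpness <- function(frame, config = sharpness_config(),
                              pixel_spacing_mm = NULL) {
  if (inherits(frame, "phantom_frame")) {
    image <- frame$image
    pixel_spacing_mm <- frame$sidecar$pixel_spacing_mm
  } else {
    image <- frame
  }
  if (is.null(pixel_spacing_mm))
    stop_stage("sharpness", "pixel_spacing_mm required (no sidecar)")
  stopifnot(inherits(config, "sharpness_config"))
  up <- upsample_roi(image, config$roi, config$upsample_factor)
  spacing <- pixel_spacing_mm / config$upsample_factor
  grad <- deriche_gradient(up, config$deriche_alpha)
  line <- detect_edge_line(grad, config$edge_threshold_fraction,
                           config$min_line_px)
  prof <- profile_rise_distance(up, line, config, spacing)
  structure(list(
    sharpness = mean(1 / prof$d_mm[prof$valid]),
    profiles = prof,
    line = list(p1_mm = line$p1 * spacing, p2_mm = line$p2 * spacing,
                theta_deg = line$theta_deg, length_mm = line$length_px * spacing),
    pixel_spacing_mm = spacing
  ), class = "sharpness_result")
}

#' @export
print.sharpness_result <- function(x, ...) {
  cat(sprintf(
    "Edge sharpness: %.3f /mm (mean 1/d over %d/%d valid profiles; mean d %.2f mm)\n",
    x$sharpness, sum(x$profiles$valid), nrow(x$profiles),
    mean(x$profiles$d_mm[x$profiles$valid])))
  invisible(x)
}
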