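test_that("upsampling: identity crop, plane preservation, checkerboard stencil", {
  img <- matrix(runif(100), 10, 10)
  expect_identical(upsample_roi(img, c(2, 3, 8, 9), 1), img[3:9, 2:8])
  # bilinear preserves planes: a linear ramp stays exactly linear
  ramp <- outer(1:10, 1:10, function(y, x) 3 * x + 2 * y)
  up <- upsample_roi(ramp, NULL, 4)
  xs <- 1 + (seq_len(ncol(up)) - 1) / 4
  ys <- 1 + (seq_len(nrow(up)) - 1) / 4
  expect_equal(up, outer(ys, xs, function(y, x) 3 * x + 2 * y),
               tolerance = 1e-12)
  # checkerboard 2x: intermediate samples are 2-point axis averages
  cb <- outer(1:4, 1:4, function(y, x) (x + y) %% 2)
  up2 <- upsample_roi(cb, NULL, 2)
  expect_equal(up2[1, 2], mean(cb[1, 1:2]))
  expect_equal(up2[2, 1], mean(cb[1:2, 1]))
  expect_equal(up2[2, 2], mean(cb[1:2, 1:2]))
  expect_error(upsample_roi(img, c(0, 1, 11, 10), 2), "roi")
})

test_that("Deriche gradient: null on constants, localized on steps, isotropic", {
  expect_lt(max(deriche_gradient(matrix(7, 30, 30), 1)), 1e-6)
  # vertical step edge: gradient ridge on the step column +- 1 px
  m <- matrix(0, 40, 40); m[, 21:40] <- 50
  g <- deriche_gradient(m, 1)
  expect_lte(abs(which.max(g[20, ]) - 20.5), 1.5)
  # compare against finite difference of a densely Gaussian-smoothed oracle:
  # ridge position must agree
  xs <- 1:40
  sm <- sapply(xs, function(x) sum(50 * (xs >= 21) * dnorm(xs - x, 0, 1)))
  fd <- abs(diff(sm))
  expect_lte(abs(which.max(fd) + 0.5 - which.max(g[20, ])), 1.5)
  # 90-degree rotation maps the gradient field onto itself
  g_rot <- deriche_gradient(t(m)[40:1, ], 1)
  expect_equal(max(g), max(g_rot), tolerance = 0.01 * max(g))
  expect_error(deriche_gradient(matrix(c(1, NA, 1, 1), 2, 2), 1),
               "non-finite")
})

test_that("Hough detection finds the longest straight edge", {
  # single straight edge at 30 degrees through a 100x100 image
  n <- 100
  th_true <- 30 * pi / 180
  m <- outer(1:n, 1:n, function(y, x)
    100 * pmin(pmax((cos(th_true) * x + sin(th_true) * y - 60) / 4 + 0.5, 0), 1))
  g <- deriche_gradient(m, 1)
  ln <- detect_edge_line(g, 0.5)
  expect_lte(min(abs(ln$theta_deg - 30), abs(ln$theta_deg - 210)), 1)
  # two parallel edges, one twice as long: the longer one wins
  m2 <- matrix(0, 80, 80)
  m2[10:70, 30] <- 1   # long vertical strip of edge points
  m2[20:40, 60] <- 1
  ln2 <- detect_edge_line(m2, 0.5)
  expect_equal(ln2$p1[1], 30)
  expect_gte(ln2$length_px, 55)
  # noise-only image: no coherent line -> no-edge error
  withr::with_seed(2, {
    noise <- matrix(runif(60 * 60), 60, 60)
    expect_error(detect_edge_line(noise, 0.995), "no edge")
  })
})

test_that("rise distance: linear ramp, noisy ramp, and logistic closed form", {
  # ideal linear ramp of width 3 mm crossed perpendicularly -> d = 1.8 mm
  w <- 3; spacing <- 0.25
  n <- 161
  img <- matrix(rep(pmin(pmax(((1:n) - 81) * spacing / w + 0.5, 0), 1),
                    each = n), n, n)   # ramp along x
  line <- list(p1 = c(81, 30), p2 = c(81, 130))
  cfg <- sharpness_config(profile_half_length = 10, profile_sample_step = 0.2)
  pr <- profile_rise_distance(img, line, cfg, spacing)
  expect_true(all(pr$valid))
  expect_equal(pr$d_mm, rep(0.6 * w, 8), tolerance = 1e-6)
  # plateau noise at 1% of contrast: mean d within 5%
  withr::with_seed(9, {
    ds <- replicate(100, {
      noisy <- img + matrix(rnorm(n * n, 0, 0.01), n, n)
      mean(profile_rise_distance(noisy, line, cfg, spacing)$d_mm)
    })
    expect_lt(abs(mean(ds) - 1.8) / 1.8, 0.05)
  })
  # logistic edge of scale s: 20-80 distance is s * ln(16)
  s <- 1.2
  imgl <- matrix(rep(stats::plogis(((1:n) - 81) * spacing, scale = s),
                     each = n), n, n)
  prl <- profile_rise_distance(imgl, line, cfg, spacing)
  expect_equal(mean(prl$d_mm), s * log(16), tolerance = 0.02)
})

test_that("phantom sharpness matches the closed-form ramp oracle", {
  # well-resolved rendering: 0.5 mm pixels, 2x upsampling
  meas <- function(w, tilt = 20, sp = 0.5) {
    fr <- render_phantom_frame(phantom_config(
      image_size = round(144 / sp), pixel_spacing_mm = sp,
      edge_width_mm = w, tilt_deg = tilt))
    compute_sharpness(fr, sharpness_config(upsample_factor = 2))$sharpness
  }
  s3 <- meas(3)
  expect_equal(s3, 1 / 1.8, tolerance = 0.05)
  expect_equal(meas(5), 1 / 3, tolerance = 0.05)
  # monotone decreasing in edge width at the native cine resolution
  f2 <- compute_sharpness(render_phantom_frame(phantom_config(edge_width_mm = 2)))
  f5 <- compute_sharpness(render_phantom_frame(phantom_config(edge_width_mm = 5)))
  expect_gt(f2$sharpness, f5$sharpness)
  # rotation invariance within 5%
  expect_equal(meas(3, tilt = 55), s3, tolerance = 0.05)
})

test_that("sharpness is invariant under affine intensity rescaling", {
  fr <- render_phantom_frame(phantom_config(edge_width_mm = 3))
  fr2 <- fr; fr2$image <- fr$image * 4.2 - 350
  cfg <- sharpness_config()
  expect_equal(compute_sharpness(fr, cfg)$sharpness,
               compute_sharpness(fr2, cfg)$sharpness, tolerance = 1e-9)
})

test_that("additional blurring never increases measured sharpness", {
  fr <- render_phantom_frame(phantom_config(edge_width_mm = 3))
  s0 <- compute_sharpness(fr)$sharpness
  # 3x3 box blur (non-negative kernel)
  blur <- function(m) {
    p <- m[c(1, 1:nrow(m), nrow(m)), c(1, 1:ncol(m), ncol(m))]
    n <- nrow(m); k <- ncol(m)
    (p[1:n, 1:k] + p[1:n, 2:(k+1)] + p[1:n, 3:(k+2)] +
     p[2:(n+1), 1:k] + p[2:(n+1), 2:(k+1)] + p[2:(n+1), 3:(k+2)] +
     p[3:(n+2), 1:k] + p[3:(n+2), 2:(k+1)] + p[3:(n+2), 3:(k+2)]) / 9
  }
  fr2 <- fr; fr2$image <- blur(fr$image)
  expect_lte(compute_sharpness(fr2)$sharpness, s0 * 1.001)
})

test_that("under-resolved edges are flagged in the sidecar", {
  expect_true(render_phantom_frame(
    phantom_config(edge_width_mm = 2))$sidecar$under_resolved)
  expect_false(render_phantom_frame(
    phantom_config(edge_width_mm = 4))$sidecar$under_resolved)
})

test_that("conventional-vs-accelerated phantom pair preserves the sharpness ordering", {
  conv <- compute_sharpness(render_phantom_frame(phantom_config(edge_width_mm = 3)))
  cs <- compute_sharpness(render_phantom_frame(phantom_config(edge_width_mm = 4)))
  expect_gt(conv$sharpness, cs$sharpness)
})
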