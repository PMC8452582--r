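test_that("shoelace area: unit square, orientation invariance, circle limit", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)
  # closed dialect (repeated last vertex) accepted
  expect_equal(polygon_area(rbind(sq, sq[1, ])), 1)
  phi <- 2 * pi * (0:199) / 200
  circ <- cbind(10 * cos(phi), 10 * sin(phi))
  # inscribed n-gon closed form: n/2 r^2 sin(2 pi / n)
  expect_equal(polygon_area(circ), 200 / 2 * 100 * sin(2 * pi / 200),
               tolerance = 1e-12)
  expect_lt(abs(polygon_area(circ) - 100 * pi) / (100 * pi), 5e-4)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3")
})

test_that("atrial length: constructions and brute-force oracle", {
  # circle of radius 10 with annulus midpoint at the center
  phi <- 2 * pi * (0:99) / 100
  circ <- cbind(10 * cos(phi), 10 * sin(phi))
  ann <- rbind(c(-5, 0), c(5, 0))   # midpoint (0,0)
  expect_equal(atrial_length(circ, ann), 10, tolerance = 1e-9)
  # synthetic ellipse layout: annulus midpoint at the basal apex -> 2a
  poly <- ellipse_polygon(30, 20, 200)
  ann2 <- poly[c(2, 200), ]
  expect_equal(atrial_length(poly, ann2), 60, tolerance = 0.02)
  # random convex polygons: equals exhaustive vertex scan
  withr::with_seed(1, for (i in 1:20) {
    ang <- sort(runif(12, 0, 2 * pi))
    p <- cbind(cos(ang), sin(ang)) * runif(1, 1, 50)
    a <- p[1:2, ]
    mid <- colMeans(a)
    brute <- max(sqrt((p[, 1] - mid[1])^2 + (p[, 2] - mid[2])^2))
    expect_equal(atrial_length(p, a), brute)
  })
  expect_error(atrial_length(circ, NULL), "annulus")
})

test_that("area-length volume formulas", {
  expect_equal(biplane_volume(1000, 1000, 50, 50), 16.98, tolerance = 1e-3)
  expect_equal(monoplane_volume(1000, 50), 16.98, tolerance = 1e-3)
  # min rule across views
  expect_equal(biplane_volume(1000, 1000, 50, 60),
               biplane_volume(1000, 1000, 50, 50))
  # prolate spheroid a=30, b=20: both views the meridian ellipse ->
  # exactly (4 pi / 3) a b^2
  A <- pi * 30 * 20
  expect_equal(biplane_volume(A, A, 60, 60), 4 * pi / 3 * 30 * 400 / 1000,
               tolerance = 1e-12)
  expect_equal(round(biplane_volume(A, A, 60, 60), 2), 50.27)
  expect_equal(monoplane_volume(A, 60), biplane_volume(A, A, 60, 60))
  # A^2 scaling at fixed length
  expect_equal(monoplane_volume(2000, 50), 4 * monoplane_volume(1000, 50))
  expect_error(biplane_volume(-1, 1, 1, 1), "positive")
})

test_that("spheroid volume agrees with numerical integration oracle", {
  a <- 30; b <- 20
  # solid of revolution about the long axis: V = int pi r(z)^2 dz
  z <- seq(-a, a, length.out = 2e5)
  r2 <- b^2 * (1 - (z / a)^2)
  v_int <- sum(pi * r2) * (z[2] - z[1]) / 1000
  expect_equal(biplane_volume(pi * a * b, pi * a * b, 2 * a, 2 * a), v_int,
               tolerance = 1e-6)
})

test_that("contours_from_curve inverts the area-length volumetry", {
  # unit sphere: V = 4 pi / 3 mm^3 (in ml) with r = 1 -> a = b = 1 mm
  cv1 <- tv_curve(rep(4 * pi / 3 / 1000, 8))
  cs1 <- contours_from_curve(cv1, aspect_ratio = 1, vertices = 400)
  p <- cs1$views$LA2CH[[1]]$polygon
  expect_equal(max(sqrt(p[, 1]^2 + (p[, 2] - 1)^2)), 1, tolerance = 1e-9)
  # V = 70 ml round trip within 1% with 200 vertices
  cv <- generate_volume_curve(hv_phenotype(), 25)
  cs <- contours_from_curve(cv, aspect_ratio = 0.7, vertices = 200)
  back <- curve_from_contours(cs, "LA")
  expect_lt(max(abs(back$volumes - cv$volumes) / cv$volumes), 0.01)
  # polygon-inscription convergence: error strictly decreases with vertices
  err <- sapply(c(16, 400), function(nv) {
    b <- curve_from_contours(contours_from_curve(cv, vertices = nv), "LA")
    max(abs(b$volumes - cv$volumes) / cv$volumes)
  })
  expect_lt(err[2], err[1])
  # monoplane route for the right atrium
  back_ra <- curve_from_contours(
    contours_from_curve(cv, vertices = 200, chamber = "RA"), "RA")
  expect_lt(max(abs(back_ra$volumes - cv$volumes) / cv$volumes), 0.01)
  expect_error(contours_from_curve(tv_curve(c(1, -1, 1, 1, 1, 1, 1, 1))),
               "finite|positive")
})

test_that("volumes are rigid-motion invariant and scale as c^3", {
  cv <- generate_volume_curve(hv_phenotype(), 10)
  cs <- contours_from_curve(cv, vertices = 120)
  rot <- function(p, th, dx, dy) cbind(
    p[, 1] * cos(th) - p[, 2] * sin(th) + dx,
    p[, 1] * sin(th) + p[, 2] * cos(th) + dy)
  moved <- cs
  for (v in names(moved$views)) for (k in seq_along(moved$views[[v]])) {
    moved$views[[v]][[k]]$polygon <- rot(moved$views[[v]][[k]]$polygon, 0.7, 31, -12)
    moved$views[[v]][[k]]$annulus <- rot(moved$views[[v]][[k]]$annulus, 0.7, 31, -12)
  }
  expect_equal(curve_from_contours(moved, "LA")$volumes,
               curve_from_contours(cs, "LA")$volumes, tolerance = 1e-12)
  scaled <- cs
  for (v in names(scaled$views)) for (k in seq_along(scaled$views[[v]])) {
    scaled$views[[v]][[k]]$polygon <- scaled$views[[v]][[k]]$polygon * 2
    scaled$views[[v]][[k]]$annulus <- scaled$views[[v]][[k]]$annulus * 2
  }
  expect_equal(curve_from_contours(scaled, "LA")$volumes,
               8 * curve_from_contours(cs, "LA")$volumes, tolerance = 1e-12)
})

test_that("missing views are reported", {
  cv <- tv_curve(rep(50, 8))
  cs <- contours_from_curve(cv, chamber = "LA")
  cs$views$LA4CH <- NULL
  expect_error(curve_from_contours(cs, "LA"), "LA4CH")
  expect_error(curve_from_contours(contours_from_curve(cv, chamber = "LA"),
                                   "RA"), "RA4CH")
})
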