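#' Synthetic elliptical contours reproducing a time-volume curve
#'
#' Inverts the area-length volume formula: for each phase, emits an
#' elliptical contour whose biplane (LA) or monoplane (RA) area-length
#' volume equals the curve's volume up to polygonal inscription error.
#' The ellipse has semi-major axis `a = (3V / (4 pi r^2))^(1/3)` along the
#' long (apex-base) axis and semi-minor axis `b = r a`; identical contours
#' are emitted for both LA views. The two annulus landmarks are the polygon
#' vertices flanking the basal apex, so their midpoint sits at the base and
#' the atrial length evaluates to `2a` up to `O(vertices^-2)`.
#'
#' @param curve a [tv_curve()] with strictly positive volumes.
#' @param aspect_ratio minor/major semi-axis ratio `r` in (0, 1].
#' @param vertices polygon vertex count (>= 16).
#' @param chamber `"LA"` (views LA2CH + LA4CH) or `"RA"` (view RA4CH).
#' @return A `contour_set`: per view, per phase, a list with `polygon`
#'   (`vertices x 2` matrix, mm, y-down) and `annulus` (2 x 2 matrix).
#' @export
contours_from_curve <- function(curve, aspect_ratio = 0.7, vertices = 96,
                                chamber = c("LA", "RA")) {
  chamber <- match.arg(chamber)
  stopifnot(inherits(curve, "tv_curve"))
  if (!is_number(aspect_ratio) || aspect_ratio <= 0 || aspect_ratio > 1)
    stop_stage("contours", "aspect_ratio must be in (0, 1]")
  if (!is_number(vertices) || vertices < 16)
    stop_stage("contours", "vertices must be >= 16")
  vertices <- as.integer(vertices)
  bad <- which(curve$volumes <= 0)
  if (length(bad))
    stop_stage("contours", "non-positive volume at phase ",
               paste(bad, collapse = ", "))
  phi <- 2 * pi * (seq_len(vertices) - 1) / vertices
  per_phase <- lapply(curve$volumes, function(v) {
    # volumes are ml = cm^3; work in mm^3
    a <- (3 * (v * 1000) / (4 * pi * aspect_ratio^2))^(1 / 3)
    b <- aspect_ratio * a
    poly <- cbind(x = b * sin(phi), y = a - a * cos(phi))
    annulus <- poly[c(2L, vertices), , drop = FALSE]
    list(polygon = poly, annulus = annulus)
  })
  views <- if (chamber == "LA") {
    list(LA2CH = per_phase, LA4CH = per_phase)
  } else {
    list(RA4CH = per_phase)
  }
  structure(list(views = views, phases = curve$phases, chamber = chamber),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("Contour set: views %s, %d phases\n",
              paste(names(x$views), collapse = "/"), x$phases))
  invisible(x)
}

#' Write / read a contour set as JSON
#'
#' Layout: `view -> phase -> {polygon: [[x_mm, y_mm], ...], annulus: [[...],
#' [...]]}` with coordinates in physical mm (y-down image convention).
#'
#' @param contours a `contour_set`.
#' @param path file path.
#' @return `read_contour_json` returns a `contour_set`; the writer returns
#'   `path` invisibly.
#' @export
write_contour_json <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  out <- lapply(contours$views, function(phs)
    lapply(phs, function(p)
      list(polygon = unname(apply(p$polygon, 1, as.numeric, simplify = FALSE)),
           annulus = unname(apply(p$annulus, 1, as.numeric, simplify = FALSE)))))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = 10)
  invisible(path)
}

#' @rdname write_contour_json
#' @export
read_contour_json <- function(path) {
  raw <- jsonlite::read_json(path)
  views <- lapply(raw, function(phs)
    lapply(phs, function(p) list(
      polygon = do.call(rbind, lapply(p$polygon, function(v)
        c(x = as.numeric(v[[1]]), y = as.numeric(v[[2]])))),
      annulus = do.call(rbind, lapply(p$annulus, function(v)
        c(x = as.numeric(v[[1]]), y = as.numeric(v[[2]])))))))
  chamber <- if (any(grepl("^LA", names(views)))) "LA" else "RA"
  structure(list(views = views, phases = length(views[[1]]),
                 chamber = chamber),
            class = "contour_set")
}
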