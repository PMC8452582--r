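#' Polygon area by the shoelace formula
#'
#' Orientation-independent absolute area of a simple closed polygon. The
#' closing edge is implicit; a repeated final vertex is tolerated.
#'
#' @param polygon numeric `n x 2` matrix of vertices (mm).
#' @return Area in mm^2.
#' @export
polygon_area <- function(polygon) {
  polygon <- close_polygon(polygon)
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- nrow(polygon)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# drop a duplicated closing vertex; validate
close_polygon <- function(polygon) {
  if (!is.matrix(polygon) || ncol(polygon) != 2 || !is.numeric(polygon))
    stop_stage("volumetry", "polygon must be an n x 2 numeric matrix")
  n <- nrow(polygon)
  if (n >= 2 && all(polygon[1, ] == polygon[n, ]))
    polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3)
    stop_stage("volumetry", "polygon needs >= 3 distinct vertices")
  polygon
}

#' Atrial length from a contour and its annulus landmarks
#'
#' The atrial long-axis length is taken as the maximum distance from the
#' midpoint of the two annulus (valve-plane) landmarks to any contour
#' vertex — the apex-to-base extent used in the area-length formula.
#'
#' @param polygon numeric `n x 2` vertex matrix (mm).
#' @param annulus `2 x 2` matrix of the two annulus landmark points (mm).
#' @return Length in mm.
#' @export
atrial_length <- function(polygon, annulus) {
  polygon <- close_polygon(polygon)
  if (is.null(annulus) || !is.matrix(annulus) || nrow(annulus) != 2)
    stop_stage("volumetry", "annulus must be a 2 x 2 matrix of landmarks")
  mid <- colMeans(annulus)
  sqrt(max((polygon[, 1] - mid[1])^2 + (polygon[, 2] - mid[2])^2))
}

#' Biplane area-length atrial volume
#'
#' `V = 8/(3 pi) * A_2ch * A_4ch / L` with `L = min(length_2ch,
#' length_4ch)` (the conservative convention), converted from mm^3 to ml.
#' Exact for prolate spheroids imaged along their meridian in both views.
#'
#' @param area_2ch,area_4ch view areas in mm^2.
#' @param length_2ch,length_4ch atrial lengths in mm.
#' @return Volume in ml.
#' @export
biplane_volume <- function(area_2ch, area_4ch, length_2ch, length_4ch) {
  vals <- c(area_2ch, area_4ch, length_2ch, length_4ch)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_stage("volumetry", "areas and lengths must be positive")
  8 / (3 * pi) * area_2ch * area_4ch / min(length_2ch, length_4ch) / 1000
}

#' Monoplane (single-view) area-length atrial volume
#'
#' `V = 8/(3 pi) * A^2 / L`, the 4-chamber-only variant used for the right
#' atrium when no dedicated right-heart 2-chamber view exists.
#'
#' @param area_4ch view area in mm^2.
#' @param length_4ch atrial length in mm.
#' @return Volume in ml.
#' @export
monoplane_volume <- function(area_4ch, length_4ch) {
  biplane_volume(area_4ch, area_4ch, length_4ch, length_4ch)
}

#' Time-volume curve from a contour set
#'
#' Applies the biplane area-length formula per phase for the left atrium
#' (views LA2CH + LA4CH) or the monoplane formula for the right atrium
#' (view RA4CH).
#'
#' @param contours a `contour_set` (see [contours_from_curve()] or
#'   [read_contour_json()]).
#' @param chamber `"LA"` or `"RA"`.
#' @return A [tv_curve()] with phase order preserved.
#' @export
curve_from_contours <- function(contours, chamber = c("LA", "RA")) {
  chamber <- match.arg(chamber)
  stopifnot(inherits(contours, "contour_set"))
  need <- if (chamber == "LA") c("LA2CH", "LA4CH") else "RA4CH"
  missing_views <- setdiff(need, names(contours$views))
  if (length(missing_views))
    stop_stage("volumetry", "missing view(s): ",
               paste(missing_views, collapse = ", "))
  n_phase <- vapply(contours$views[need], length, integer(1))
  if (length(unique(n_phase)) != 1)
    stop_stage("volumetry", "views disagree on phase count")
  vols <- vapply(seq_len(n_phase[[1]]), function(k) {
    per_view <- lapply(contours$views[need], function(v) {
      p <- v[[k]]
      if (is.null(p$polygon))
        stop_stage("volumetry", "missing polygon at phase ", k)
      list(area = polygon_area(p$polygon),
           len = atrial_length(p$polygon, p$annulus))
    })
    if (chamber == "LA") {
      biplane_volume(per_view$LA2CH$area, per_view$LA4CH$area,
                     per_view$LA2CH$len, per_view$LA4CH$len)
    } else {
      monoplane_volume(per_view$RA4CH$area, per_view$RA4CH$len)
    }
  }, numeric(1))
  tv_curve(vols)
}
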