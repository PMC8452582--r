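#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG seed when `seed` is given, leaving the
# caller's RNG stream untouched; with seed = NULL the current stream is used.
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Bilinear sampling of a matrix image at arbitrary continuous coordinates
#'
#' Images are stored as numeric matrices with rows indexing y (down) and
#' columns indexing x, pixel centers at integer coordinates (1-based).
#' Coordinates outside the grid are clamped to the border (edge replication).
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of equal length, continuous pixel coordinates.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 1L); y1 <- y0 + 1
  if (nc == 1L) { x0 <- x1 <- rep(1, length(x)) }
  if (nr == 1L) { y0 <- y1 <- rep(1, length(y)) }
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)]; i01 <- img[cbind(y0, x1)]
  i10 <- img[cbind(y1, x0)]; i11 <- img[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}
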