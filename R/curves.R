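#' Time-volume curve container
#'
#' @param volumes numeric vector of per-phase atrial volumes (ml), one full
#'   cardiac cycle sampled at equispaced cycle fractions `(k-1)/phases`.
#' @param truth optional list of ground-truth metadata (attached by the
#'   synthetic generator).
#' @return An object of class `tv_curve`.
#' @export
tv_curve <- function(volumes, truth = NULL) {
  volumes <- as.numeric(volumes)
  if (length(volumes) < 1L || any(!is.finite(volumes)))
    stop_stage("curve", "volumes must be finite")
  structure(list(volumes = volumes, phases = length(volumes),
                 periodic = TRUE, truth = truth),
            class = "tv_curve")
}

#' @export
print.tv_curve <- function(x, ...) {
  cat(sprintf("Atrial time-volume curve: %d phases, %.1f-%.1f ml\n",
              x$phases, min(x$volumes), max(x$volumes)))
  invisible(x)
}

# Cosine-smoothed monotone interpolant through the phenotype control points
# (0, v_min) -> (t_max, v_max) -> (t_dia, v_dia) -> (t_preA, v_preA) ->
# (1, v_min). Each segment is v1 + (v2 - v1) (1 - cos(pi u))/2, which is
# monotone with zero slope at both knots, so the landmarks are exact local
# extrema of the continuous curve.
curve_interpolant <- function(phenotype) {
  tt <- c(0, phenotype$t_max, phenotype$t_dia, phenotype$t_preA, 1)
  vv <- c(phenotype$v_min, phenotype$v_max, phenotype$v_dia,
          phenotype$v_preA, phenotype$v_min)
  function(t) {
    t <- t %% 1
    seg <- findInterval(t, tt, rightmost.closed = TRUE)
    seg[seg > 4L] <- 4L
    u <- (t - tt[seg]) / (tt[seg + 1L] - tt[seg])
    vv[seg] + (vv[seg + 1L] - vv[seg]) * (1 - cos(pi * u)) / 2
  }
}

#' Generate a synthetic atrial time-volume curve
#'
#' Samples the phenotype's cosine-smoothed monotone interpolant at `phases`
#' equispaced cycle fractions and adds seeded Gaussian noise of SD
#' `phenotype$noise_sd` per sample. Ground-truth emptying fractions computed
#' from the control values (reservoir TEF, conduit PEF, booster AEF) are
#' attached as `$truth`.
#'
#' @param phenotype a [curve_phenotype()].
#' @param phases number of phases (>= 8), default 25.
#' @param seed optional integer; when given, noise is drawn under a local
#'   seed so repeated calls are reproducible.
#' @return A [tv_curve()] with `$truth` containing the phenotype and its
#'   TEF/PEF/AEF.
#' @export
generate_volume_curve <- function(phenotype, phases = 25, seed = NULL) {
  if (!inherits(phenotype, "curve_phenotype"))
    stop_stage("curve-gen", "phenotype must be a curve_phenotype")
  if (!is_number(phases) || phases < 8)
    stop_stage("curve-gen", "invalid config: phases must be >= 8")
  phases <- as.integer(phases)
  f <- curve_interpolant(phenotype)
  t <- (seq_len(phases) - 1) / phases
  v <- f(t)
  if (phenotype$noise_sd > 0) {
    v <- v + with_seed_or_current(seed,
      stats::rnorm(phases, 0, phenotype$noise_sd))
    v <- pmax(v, 0.1)   # a chamber volume cannot be non-positive
  }
  tv_curve(v, truth = list(
    phenotype = phenotype,
    tef = phenotype$tef, pef = phenotype$pef, aef = phenotype$aef))
}

#' Write / read time-volume curves as CSV
#'
#' Long format with header `subject,group,technique,reader,phase,volume_ml`.
#'
#' @param curves data.frame in the long schema above (as produced by
#'   [cohort_curve_table()]).
#' @param path file path.
#' @return `read_curve_csv` returns the long data.frame; `write_curve_csv`
#'   returns `path` invisibly.
#' @export
write_curve_csv <- function(curves, path) {
  need <- c("subject", "group", "technique", "reader", "phase", "volume_ml")
  if (!all(need %in% names(curves)))
    stop_stage("curve-io", "missing columns: ",
               paste(setdiff(need, names(curves)), collapse = ", "))
  cols <- if ("chamber" %in% names(curves)) {
    c("subject", "group", "technique", "reader", "chamber", "phase",
      "volume_ml")
  } else need
  utils::write.csv(curves[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "technique", "reader", "phase", "volume_ml")
  if (!all(need %in% names(x)))
    stop_stage("curve-io", "missing columns: ",
               paste(setdiff(need, names(x)), collapse = ", "))
  x
}
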