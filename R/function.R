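#' Curve landmarks container
#'
#' The four functional landmarks of an atrial time-volume curve, each a
#' volume (ml) plus the phase index it was read at.
#'
#' @param v_max,v_mid_min,v_mid_max,v_min landmark volumes (ml); must
#'   satisfy `v_min <= v_mid_min <= v_mid_max <= v_max`.
#' @param phases optional named integer vector of phase indices
#'   (`v_max`, `v_mid_min`, `v_mid_max`, `v_min`).
#' @param no_kick logical flag: no mid-diastolic atrial kick was detected
#'   and the mid-diastolic landmarks fell back to the midway phase.
#' @return An object of class `curve_landmarks`.
#' @export
curve_landmarks <- function(v_max, v_mid_min, v_mid_max, v_min,
                            phases = NULL, no_kick = FALSE) {
  vals <- c(v_max, v_mid_min, v_mid_max, v_min)
  if (any(!is.finite(vals)))
    stop_stage("landmarks", "landmark volumes must be finite")
  if (!(v_min <= v_mid_min && v_mid_min <= v_mid_max && v_mid_max <= v_max))
    stop_stage("landmarks",
               "ordering violation: need v_min <= v_mid_min <= v_mid_max <= v_max")
  structure(list(v_max = v_max, v_mid_min = v_mid_min,
                 v_mid_max = v_mid_max, v_min = v_min,
                 phases = phases, no_kick = isTRUE(no_kick)),
            class = "curve_landmarks")
}

#' @export
print.curve_landmarks <- function(x, ...) {
  cat(sprintf(
    "Curve landmarks (ml): Vmax %.1f, mid-dia Vmin %.1f, mid-dia Vmax %.1f, Vmin %.1f%s\n",
    x$v_max, x$v_mid_min, x$v_mid_max, x$v_min,
    if (x$no_kick) " [no atrial kick]" else ""))
  invisible(x)
}

# circular moving average, odd window
circular_smooth <- function(v, window) {
  if (window <= 1) return(v)
  h <- (window - 1L) %/% 2L
  n <- length(v)
  idx <- outer(seq_len(n), -h:h, `+`)
  idx <- ((idx - 1L) %% n) + 1L
  rowMeans(matrix(v[idx], nrow = n))
}

#' Locate the four functional landmarks of an atrial time-volume curve
#'
#' The curve is first smoothed with a circular moving average (default
#' window 3 phases) for robust extremum *location*; each located phase is
#' then refined on the unsmoothed curve within half a window (smoothing can
#' displace an extremum by that much) and the landmark *volumes* are read
#' from the unsmoothed curve there, avoiding the amplitude bias of
#' smoothing. Anchored at the global maximum (atrial
#' reservoir peak), the cyclic forward search finds the first local minimum
#' (diastasis), the first subsequent local maximum (pre-contraction volume),
#' and finally the global minimum of the remaining segment (post-contraction
#' Vmin). Curves without interior extrema (no atrial kick) set `no_kick` and
#' place both mid-diastolic landmarks at the phase cyclically midway between
#' the maximum and the minimum.
#'
#' @param curve a [tv_curve()] with >= 8 phases.
#' @param smooth_window odd moving-average window in phases (>= 1).
#' @return A [curve_landmarks()].
#' @export
find_landmarks <- function(curve, smooth_window = 3) {
  stopifnot(inherits(curve, "tv_curve"))
  v <- curve$volumes
  n <- length(v)
  if (n < 8) stop_stage("landmarks", "need >= 8 phases, got ", n)
  if (diff(range(v)) == 0)
    stop_stage("landmarks", "degenerate constant curve")
  if (!is_number(smooth_window) || smooth_window < 1 || smooth_window %% 2 == 0)
    stop_stage("landmarks", "smooth_window must be odd and >= 1")
  s <- circular_smooth(v, as.integer(smooth_window))

  i_max <- which.max(s)                     # earliest phase on ties
  rot <- ((i_max - 1L + seq_len(n) - 1L) %% n) + 1L  # rotated phase indices
  r <- s[rot]

  # The rotated series descends from the anchor maximum, so the first
  # position where it starts rising is the first (interior) local minimum —
  # the diastasis — and the first subsequent fall is the pre-contraction
  # local maximum. Ties resolve to the earliest phase in cyclic order.
  j_dia <- NA_integer_; j_preA <- NA_integer_
  rises <- which(r[2:(n - 1L)] < r[3:n]) + 1L      # r[j] < r[j+1]
  if (length(rises)) {
    j <- rises[1L]
    if (j < n - 1L) {
      falls <- which(r[(j + 1L):(n - 1L)] > r[(j + 2L):n]) + j
      if (length(falls)) { j_dia <- j; j_preA <- falls[1L] }
    }
  }

  # smoothing can displace an extremum by up to half the window; refine each
  # located phase on the unsmoothed curve within that reach before reading
  h <- (as.integer(smooth_window) - 1L) %/% 2L
  refine <- function(phase, what) {
    idx <- ((phase - 1L + (-h:h)) %% n) + 1L
    idx[if (what == "min") which.min(v[idx]) else which.max(v[idx])]
  }

  fallback <- is.na(j_dia)
  if (!fallback) {
    seg <- (j_preA + 1L):n
    j_min <- seg[which.min(r[seg])]
    p <- c(v_max = refine(rot[1L], "max"),
           v_mid_min = refine(rot[j_dia], "min"),
           v_mid_max = refine(rot[j_preA], "max"),
           v_min = refine(rot[j_min], "min"))
    lm <- try(curve_landmarks(
      v_max = v[p[["v_max"]]], v_mid_min = v[p[["v_mid_min"]]],
      v_mid_max = v[p[["v_mid_max"]]], v_min = v[p[["v_min"]]],
      phases = p, no_kick = FALSE), silent = TRUE)
    if (inherits(lm, "try-error")) fallback <- TRUE else return(lm)
  }

  # no-kick fallback: single-trough cycle
  j_min <- which.min(r)
  j_mid <- 1L + ((j_min - 1L) %/% 2L)
  p <- c(v_max = refine(rot[1L], "max"), v_mid_min = rot[j_mid],
         v_mid_max = rot[j_mid], v_min = refine(rot[j_min], "min"))
  vm <- v[p[["v_min"]]]; vx <- v[p[["v_max"]]]
  if (vm > vx) {
    # near-flat noisy cycle: smoothed extremum phases are uninformative,
    # fall back to the unsmoothed global extremes
    p[["v_max"]] <- which.max(v); p[["v_min"]] <- which.min(v)
    vx <- v[p[["v_max"]]]; vm <- v[p[["v_min"]]]
    p[["v_mid_min"]] <- p[["v_mid_max"]] <-
      1L + (((p[["v_max"]] - 1L) + ((p[["v_min"]] - p[["v_max"]]) %% n) %/% 2L) %% n)
  }
  vmid <- min(max(v[p[["v_mid_min"]]], vm), vx)
  curve_landmarks(v_max = vx, v_mid_min = vmid, v_mid_max = vmid,
                  v_min = vm, phases = p, no_kick = TRUE)
}

#' Atrial emptying fractions and volumes from curve landmarks
#'
#' Computes the three functional parameters of the atrium:
#' total emptying fraction `TEF = 100 (Vmax - Vmin) / Vmax` (reservoir),
#' passive emptying fraction `PEF = 100 (Vmax - mid-diastolic Vmin) / Vmax`
#' (conduit), and active emptying fraction
#' `AEF = 100 (mid-diastolic Vmax - Vmin) / mid-diastolic Vmax` (booster),
#' plus the corresponding emptying volumes TEV/PEV/AEV in ml.
#'
#' @param landmarks a [curve_landmarks()].
#' @return An object of class `atrial_function`: list with `tef`, `pef`,
#'   `aef` (percent) and `tev`, `pev`, `aev` (ml).
#' @export
compute_function <- function(landmarks) {
  if (!inherits(landmarks, "curve_landmarks"))
    stop_stage("function", "landmarks must be a curve_landmarks object")
  with(landmarks, {
    if (v_max <= 0 || v_mid_max <= 0)
      stop_stage("function", "zero or negative denominator (Vmax, mid-diastolic Vmax)")
    structure(list(
      tef = 100 * (v_max - v_min) / v_max,
      pef = 100 * (v_max - v_mid_min) / v_max,
      aef = 100 * (v_mid_max - v_min) / v_mid_max,
      tev = v_max - v_min,
      pev = v_max - v_mid_min,
      aev = v_mid_max - v_min,
      no_kick = no_kick
    ), class = "atrial_function")
  })
}

#' @export
print.atrial_function <- function(x, ...) {
  cat(sprintf("Atrial function: TEF %.1f%%, PEF %.1f%%, AEF %.1f%% (TEV %.1f, PEV %.1f, AEV %.1f ml)%s\n",
              x$tef, x$pef, x$aef, x$tev, x$pev, x$aev,
              if (x$no_kick) " [no atrial kick]" else ""))
  invisible(x)
}
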