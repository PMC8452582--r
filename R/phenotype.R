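#' Atrial time-volume curve phenotype
#'
#' A phenotype fixes the four physiological landmarks of one atrial cycle:
#' the minimal volume `v_min` (after atrial contraction), the mid-diastolic
#' diastasis minimum `v_dia`, the pre-contraction maximum `v_preA`, and the
#' maximal volume `v_max` (end ventricular systole), together with the cycle
#' fractions at which the maximum, diastasis, and pre-contraction volumes
#' occur. The cycle is anchored at `v_min` at cycle fraction 0 and 1.
#'
#' @param v_min,v_dia,v_preA,v_max landmark volumes in ml; must satisfy
#'   `0 < v_min <= v_dia <= v_preA <= v_max`.
#' @param t_max,t_dia,t_preA cycle fractions in (0, 1) of the maximal,
#'   diastasis, and pre-contraction volumes; must be strictly increasing.
#' @param noise_sd standard deviation (ml) of additive Gaussian measurement
#'   noise applied per sampled phase.
#' @return An object of class `curve_phenotype` with ground-truth emptying
#'   fractions (`tef`, `pef`, `aef`, percent) attached.
#' @seealso [generate_volume_curve()]
#' @export
curve_phenotype <- function(v_min, v_dia, v_preA, v_max,
                            t_max = 0.40, t_dia = 0.65, t_preA = 0.875,
                            noise_sd = 0) {
  vals <- c(v_min = v_min, v_dia = v_dia, v_preA = v_preA, v_max = v_max)
  if (!all(vapply(vals, is_number, logical(1))))
    stop_stage("phenotype", "landmark volumes must be finite numbers")
  if (!(v_min > 0 && v_min <= v_dia && v_dia <= v_preA && v_preA <= v_max))
    stop_stage("phenotype",
               "invalid ordering: need 0 < v_min <= v_dia <= v_preA <= v_max")
  if (!(0 < t_max && t_max < t_dia && t_dia < t_preA && t_preA < 1))
    stop_stage("phenotype", "invalid timing: need 0 < t_max < t_dia < t_preA < 1")
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_stage("phenotype", "noise_sd must be >= 0")
  structure(list(
    v_min = v_min, v_dia = v_dia, v_preA = v_preA, v_max = v_max,
    t_max = t_max, t_dia = t_dia, t_preA = t_preA, noise_sd = noise_sd,
    tef = 100 * (v_max - v_min) / v_max,
    pef = 100 * (v_max - v_dia) / v_max,
    aef = 100 * (v_preA - v_min) / v_preA
  ), class = "curve_phenotype")
}

#' @export
print.curve_phenotype <- function(x, ...) {
  cat(sprintf(
    "Atrial curve phenotype: Vmin %.1f / Vdia %.1f / VpreA %.1f / Vmax %.1f ml\n",
    x$v_min, x$v_dia, x$v_preA, x$v_max))
  cat(sprintf("  timing (cycle fractions): tmax %.3f, tdia %.3f, tpreA %.3f\n",
              x$t_max, x$t_dia, x$t_preA))
  cat(sprintf("  ground truth TEF/PEF/AEF: %.1f / %.1f / %.1f %%; noise sd %.2f ml\n",
              x$tef, x$pef, x$aef, x$noise_sd))
  invisible(x)
}

#' Inter-technique disagreement model
#'
#' Models the systematic and random disagreement between the conventional
#' and the accelerated (CS) acquisition at the derived-parameter level.
#' For each parameter, the simulated CS value is
#' `conventional - bias + N(0, sd)`, so the paired difference
#' conventional - CS has mean `bias` and standard deviation `sd` —
#' the Bland-Altman convention used throughout the package.
#'
#' Defaults are calibrated to published method-comparison values for atrial
#' cine measurements: bias from the reported mean difference and
#' `sd = (upper LoA - bias) / 1.96` per parameter. The total emptying
#' fraction has no independent dial: it is algebraically determined by the
#' minimal and maximal volumes, so its disagreement emerges from theirs.
#'
#' @param bias named numeric vector of mean differences (conventional - CS);
#'   units are ml for volumes and percentage points for emptying fractions.
#' @param sd named numeric vector of the corresponding difference SDs
#'   (same names, all `>= 0`).
#' @return An object of class `disagreement_model`.
#' @export
disagreement_model <- function(
    bias = c(LAVmin = -2.0, LAVmax = 3.0, RAVmin = -3.0, RAVmax = -0.8,
             PEF = 3.3, AEF = 6.99),
    sd = c(LAVmin = (5.6 - -2.0) / 1.96, LAVmax = (13.8 - 3.0) / 1.96,
           RAVmin = (10.4 - -3.0) / 1.96, RAVmax = (17.9 - -0.8) / 1.96,
           PEF = (13.4 - 3.3) / 1.96, AEF = (22.2 - 6.99) / 1.96)) {
  need <- c("LAVmin", "LAVmax", "RAVmin", "RAVmax", "PEF", "AEF")
  if (!all(need %in% names(bias)) || !all(need %in% names(sd)))
    stop_stage("disagreement", "bias and sd must name: ",
               paste(need, collapse = ", "))
  if (any(!is.finite(bias[need])) || any(!is.finite(sd[need])))
    stop_stage("disagreement", "bias and sd must be finite")
  if (any(sd[need] < 0))
    stop_stage("disagreement", "sd must be >= 0 for every parameter")
  structure(list(bias = bias[need], sd = sd[need]),
            class = "disagreement_model")
}

#' Zero-disagreement model (identical techniques)
#'
#' Convenience constructor for the degenerate model in which both techniques
#' agree exactly; useful for pipeline identity checks.
#' @return A `disagreement_model` with all biases and SDs equal to zero.
#' @export
no_disagreement <- function() {
  z <- c(LAVmin = 0, LAVmax = 0, RAVmin = 0, RAVmax = 0, PEF = 0, AEF = 0)
  disagreement_model(bias = z, sd = z)
}

# Per-group phenotype parameter distributions. Each group draws, per
# chamber, four normal variates (mean, sd pairs below):
#   v_max          maximal volume (ml)
#   tef            total emptying fraction (%)        -> v_min
#   diastasis_frac (Vdia - Vmin)/TEV, the share of the total emptying
#                  volume still to be emptied at diastasis -> v_dia
#   refill_frac    (VpreA - Vdia)/TEV, the mid-diastolic refill share
#                  -> v_preA
# This parameterization makes the landmark ordering structural (only range
# clipping needs redraws), so group centers are not distorted by
# feasibility truncation. PEF = TEF (1 - diastasis_frac) and AEF follow.
# Healthy-volunteer centers reproduce the published conventional medians
# (LAVmin 24.0 / LAVmax 70.3 ml, TEF 67.8 / PEF 53.9 / AEF 40.3 %), with
# spreads from the published IQRs (sd = IQR/1.349). The heart-failure
# (HFrEF) group is a calibration choice targeting the published ranking of
# diagnostic power — PEF and LAVmin on top — with dilated atria and blunted
# emptying (see the methods vignette).
group_phenotype_defaults <- function(group = c("HV", "HFrEF")) {
  group <- match.arg(group)
  if (group == "HV") {
    list(
      LA = list(v_max = c(70.3, 22.1), tef = c(67.8, 7.9),
                diastasis_frac = c(0.205, 0.089), refill_frac = c(0.115, 0.06)),
      RA = list(v_max = c(77.6, 25.9), tef = c(54.6, 8.0),
                diastasis_frac = c(0.304, 0.09), refill_frac = c(0.06, 0.04)),
      t_max = c(0.40, 0.02), t_dia = c(0.65, 0.02), t_preA = c(0.875, 0.015),
      noise_sd = 1.0
    )
  } else {
    list(
      LA = list(v_max = c(110, 26), tef = c(53.3, 10),
                diastasis_frac = c(0.475, 0.10), refill_frac = c(0.12, 0.05)),
      RA = list(v_max = c(89, 26), tef = c(45.0, 9.0),
                diastasis_frac = c(0.44, 0.10), refill_frac = c(0.05, 0.035)),
      t_max = c(0.40, 0.02), t_dia = c(0.65, 0.02), t_preA = c(0.875, 0.015),
      noise_sd = 1.0
    )
  }
}

#' Cohort simulation configuration
#'
#' @param n_hv,n_hfref number of healthy-volunteer and HFrEF subjects.
#' @param phases number of reconstructed cardiac phases per cycle (>= 8).
#' @param seed integer seed controlling every random draw.
#' @param reader_jitter_sd relative (multiplicative) SD of repeat-reader
#'   jitter applied per landmark volume; 0 disables reader variation.
#' @param hv,hfref per-group phenotype distributions as returned by
#'   `group_phenotype_defaults()`; override fields to move the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_hv = 82, n_hfref = 19, phases = 25, seed = 1,
                          reader_jitter_sd = 0.03,
                          hv = group_phenotype_defaults("HV"),
                          hfref = group_phenotype_defaults("HFrEF")) {
  if (n_hv < 0 || n_hfref < 0 || (n_hv + n_hfref) < 0)
    stop_stage("cohort-config", "group sizes must be non-negative")
  if (!is_number(phases) || phases < 8)
    stop_stage("cohort-config", "phases must be >= 8")
  if (!is_number(reader_jitter_sd) || reader_jitter_sd < 0)
    stop_stage("cohort-config", "reader_jitter_sd must be >= 0")
  structure(list(n_hv = as.integer(n_hv), n_hfref = as.integer(n_hfref),
                 phases = as.integer(phases), seed = as.integer(seed),
                 reader_jitter_sd = reader_jitter_sd,
                 hv = hv, hfref = hfref),
            class = "cohort_config")
}
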