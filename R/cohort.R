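max_redraws <- 100L

# Draw (v_max, TEF, diastasis_frac, refill_frac) for one chamber from the
# group distribution. The ordering v_min <= v_dia <= v_preA <= v_max is
# structural in this parameterization; redraws (capped) only enforce range
# clipping of the individual variates.
draw_chamber_params <- function(dist, timing, noise_sd, who) {
  for (i in seq_len(max_redraws)) {
    v_max <- stats::rnorm(1, dist$v_max[1], dist$v_max[2])
    tef <- stats::rnorm(1, dist$tef[1], dist$tef[2])
    q1 <- stats::rnorm(1, dist$diastasis_frac[1], dist$diastasis_frac[2])
    dq <- stats::rnorm(1, dist$refill_frac[1], dist$refill_frac[2])
    if (!(v_max > 10 && tef > 5 && tef < 95 &&
          q1 > 0.01 && dq >= 0 && (q1 + dq) < 0.985)) next
    v_min <- v_max * (1 - tef / 100)
    tev <- v_max - v_min
    ph <- try(curve_phenotype(
      v_min, v_min + q1 * tev, v_min + (q1 + dq) * tev, v_max,
      t_max = timing$t_max, t_dia = timing$t_dia, t_preA = timing$t_preA,
      noise_sd = noise_sd), silent = TRUE)
    if (!inherits(ph, "try-error")) return(ph)
  }
  stop_stage("cohort", "generation failed for ", who,
             ": parameter ranges could not be satisfied after ", max_redraws,
             " redraws (degenerate distribution?)")
}

draw_timing <- function(g) {
  for (i in seq_len(max_redraws)) {
    t_max <- stats::rnorm(1, g$t_max[1], g$t_max[2])
    t_dia <- stats::rnorm(1, g$t_dia[1], g$t_dia[2])
    t_preA <- stats::rnorm(1, g$t_preA[1], g$t_preA[2])
    if (0.05 < t_max && t_max < t_dia && t_dia < t_preA && t_preA < 0.98)
      return(list(t_max = t_max, t_dia = t_dia, t_preA = t_preA))
  }
  stop_stage("cohort", "timing draw failed")
}

rebuild_phenotype <- function(v_min, v_dia, v_preA, v_max, template) {
  curve_phenotype(v_min, v_dia, v_preA, v_max,
                  t_max = template$t_max, t_dia = template$t_dia,
                  t_preA = template$t_preA, noise_sd = template$noise_sd)
}

# CS variant of a phenotype. Minimal and maximal volumes get
# `conventional - bias + N(0, sd)` drawn unconditionally (so their marginal
# disagreement distribution is exactly the configured one); the mid-diastolic
# landmarks are then filled in: for the left atrium the conduit and booster
# fractions get their own `- bias + N(0, sd)` perturbation, redrawn (capped)
# until they are orderable given the fixed volumes; the right atrium (no
# published fraction disagreement) keeps the conventional curve's ordered
# emptying-volume fractions, which is feasible by construction.
cs_phenotype <- function(ph, dm, chamber, who) {
  keys <- if (chamber == "LA") c("LAVmin", "LAVmax") else c("RAVmin", "RAVmax")
  fkeys <- if (chamber == "LA") c("PEF", "AEF") else character(0)
  if (all(dm$bias[c(keys, fkeys)] == 0) && all(dm$sd[c(keys, fkeys)] == 0))
    return(ph)   # zero-disagreement identity, bit-exact
  v_min <- NA_real_
  for (i in seq_len(max_redraws)) {
    v_min <- ph$v_min - dm$bias[[keys[1]]] + stats::rnorm(1, 0, dm$sd[[keys[1]]])
    v_max <- ph$v_max - dm$bias[[keys[2]]] + stats::rnorm(1, 0, dm$sd[[keys[2]]])
    if (v_min > 0 && v_min <= v_max) break
    v_min <- NA_real_
  }
  if (!is.finite(v_min))
    stop_stage("cohort", "generation failed for ", who,
               ": CS volume perturbation stayed unordered after ",
               max_redraws, " redraws")
  tev <- v_max - v_min
  conv_fracs <- function() {
    q1 <- (ph$v_dia - ph$v_min) / (ph$v_max - ph$v_min)
    q2 <- (ph$v_preA - ph$v_min) / (ph$v_max - ph$v_min)
    rebuild_phenotype(v_min, v_min + q1 * tev, v_min + q2 * tev, v_max, ph)
  }
  if (chamber == "RA" || !all(c("PEF", "AEF") %in% names(dm$bias)))
    return(conv_fracs())
  for (i in seq_len(max_redraws)) {
    pef <- ph$pef - dm$bias[["PEF"]] + stats::rnorm(1, 0, dm$sd[["PEF"]])
    aef <- ph$aef - dm$bias[["AEF"]] + stats::rnorm(1, 0, dm$sd[["AEF"]])
    out <- try({
      if (aef >= 99.5 || aef <= 0 || pef <= 0) stop("fractions out of range")
      rebuild_phenotype(v_min, v_max * (1 - pef / 100),
                        v_min / (1 - aef / 100), v_max, ph)
    }, silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  # the drawn CS volumes admit no orderable perturbed fraction pair (e.g. a
  # near-zero total emptying volume): keep the conventional curve's ordered
  # fractions so the calibrated volume disagreement is preserved
  conv_fracs()
}

# Repeat-reader variant: independent multiplicative jitter per landmark
# volume, redrawn until the ordering invariant survives.
jitter_phenotype <- function(ph, jitter_sd, who) {
  if (jitter_sd == 0) return(ph)
  for (i in seq_len(max_redraws)) {
    f <- 1 + stats::rnorm(4, 0, jitter_sd)
    out <- try(rebuild_phenotype(ph$v_min * f[1], ph$v_dia * f[2],
                                 ph$v_preA * f[3], ph$v_max * f[4], ph),
               silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop_stage("cohort", "generation failed for ", who,
             ": reader jitter violated ordering after ", max_redraws,
             " redraws")
}

#' Simulate a cohort of paired-technique, repeat-reader atrial measurements
#'
#' For every subject, draws a left- and right-atrial phenotype from the
#' group's distribution, derives the paired accelerated-technique ("cs")
#' phenotype through the disagreement model, optionally adds repeat-reader
#' variants (second reader `R2` and a re-read `R1b` by the primary reader,
#' both multiplicative jitter), and samples one noisy time-volume curve per
#' phenotype. All draws run under the configuration seed and are fully
#' reproducible.
#'
#' @param config a [cohort_config()].
#' @param disagreement a [disagreement_model()].
#' @param readers generate repeat-reader readings (`R1b`, `R2`) in addition
#'   to the primary reader `R1`? Default `TRUE`.
#' @return An object of class `atrial_cohort`: a list with `$subjects`
#'   (per-subject records holding `curve_phenotype`s and [tv_curve()]s per
#'   technique, reader, and chamber) plus the configuration.
#' @export
generate_cohort <- function(config, disagreement = disagreement_model(),
                            readers = TRUE) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(disagreement, "disagreement_model"))
  groups <- c(rep("HV", config$n_hv), rep("HFrEF", config$n_hfref))
  reader_set <- if (readers) c("R1", "R1b", "R2") else "R1"
  subjects <- with_seed_or_current(config$seed, lapply(seq_along(groups), function(i) {
    grp <- groups[[i]]
    g <- if (grp == "HV") config$hv else config$hfref
    who <- sprintf("subject %d (%s)", i, grp)
    timing <- draw_timing(g)
    conv <- list(LA = draw_chamber_params(g$LA, timing, g$noise_sd, who),
                 RA = draw_chamber_params(g$RA, timing, g$noise_sd, who))
    cs <- list(LA = cs_phenotype(conv$LA, disagreement, "LA", who),
               RA = cs_phenotype(conv$RA, disagreement, "RA", who))
    tech <- list(conventional = conv, cs = cs)
    readings <- list()
    for (tc in names(tech)) {
      for (rd in reader_set) {
        readings[[tc]][[rd]] <- lapply(tech[[tc]], function(ph) {
          ph_r <- if (rd == "R1") ph else
            jitter_phenotype(ph, config$reader_jitter_sd, who)
          list(phenotype = ph_r,
               curve = generate_volume_curve(ph_r, config$phases))
        })
      }
    }
    list(id = sprintf("S%03d", i), group = grp, readings = readings)
  }))
  structure(list(subjects = subjects, config = config,
                 disagreement = disagreement),
            class = "atrial_cohort")
}

#' @export
print.atrial_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("Atrial cohort: %d subjects (%d HV, %d HFrEF), %d phases\n",
              length(grp), sum(grp == "HV"), sum(grp == "HFrEF"),
              x$config$phases))
  invisible(x)
}

#' Ground-truth parameter table of a simulated cohort
#'
#' Extracts the phenotype-level (noise-free) derived parameters per subject,
#' technique, and reader: LAVmin, LAVmax, RAVmin, RAVmax and the LA emptying
#' fractions TEF/PEF/AEF.
#'
#' @param cohort an `atrial_cohort`.
#' @return A data.frame with one row per subject x technique x reader.
#' @export
cohort_parameter_table <- function(cohort) {
  stopifnot(inherits(cohort, "atrial_cohort"))
  rows <- list()
  for (s in cohort$subjects) {
    for (tc in names(s$readings)) {
      for (rd in names(s$readings[[tc]])) {
        la <- s$readings[[tc]][[rd]]$LA$phenotype
        ra <- s$readings[[tc]][[rd]]$RA$phenotype
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s$id, group = s$group, technique = tc, reader = rd,
          LAVmin = la$v_min, LAVmax = la$v_max,
          RAVmin = ra$v_min, RAVmax = ra$v_max,
          TEF = la$tef, PEF = la$pef, AEF = la$aef)
      }
    }
  }
  do.call(rbind, rows)
}

#' Long-format curve table of a simulated cohort
#'
#' @param cohort an `atrial_cohort`.
#' @return Data.frame with columns
#'   `subject,group,technique,reader,chamber,phase,volume_ml` (the curve CSV
#'   schema plus a chamber column distinguishing LA and RA).
#' @export
cohort_curve_table <- function(cohort) {
  stopifnot(inherits(cohort, "atrial_cohort"))
  rows <- list()
  for (s in cohort$subjects) {
    for (tc in names(s$readings)) {
      for (rd in names(s$readings[[tc]])) {
        for (ch in names(s$readings[[tc]][[rd]])) {
          cv <- s$readings[[tc]][[rd]][[ch]]$curve
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s$id, group = s$group, technique = tc, reader = rd,
            chamber = ch, phase = seq_len(cv$phases), volume_ml = cv$volumes)
        }
      }
    }
  }
  do.call(rbind, rows)
}
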