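atrial_parameters <- c("LAVmin", "LAVmax", "RAVmin", "RAVmax",
                       "TEF", "PEF", "AEF")

# a priori ROC orientation per parameter: atrial volumes are higher in
# heart failure, emptying fractions lower
parameter_direction <- function(p) {
  if (p %in% c("LAVmin", "LAVmax", "RAVmin", "RAVmax")) "higher" else "lower"
}

#' Study run configuration
#'
#' @param mode `"simulate"` (generate a cohort) or `"load"` (read a curve
#'   CSV written by [write_curve_csv()]/[cohort_curve_table()]).
#' @param seed integer seed; mandatory in simulate mode.
#' @param n_hv,n_hfref simulated group sizes.
#' @param curves_path curve CSV path for load mode.
#' @param smooth_window landmark-detection smoothing window (odd phases).
#' @param disagreement a [disagreement_model()] for the simulation.
#' @param reader_jitter_sd relative repeat-reader jitter SD.
#' @param readers simulate repeat-reader readings (needed for the observer
#'   agreement table)?
#' @param through_contours route every curve through synthetic contours and
#'   area-length volumetry (full-pipeline mode) instead of reading volumes
#'   off the curve directly.
#' @param contour_vertices polygon vertex count for the contour route.
#' @param sharpness_widths_mm edge widths (mm) of the conventional and
#'   accelerated phantom used for the sharpness comparison, or `NULL` to
#'   skip it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"), seed = NULL,
                       n_hv = 82, n_hfref = 19, curves_path = NULL,
                       smooth_window = 3,
                       disagreement = disagreement_model(),
                       reader_jitter_sd = 0.03, readers = TRUE,
                       through_contours = TRUE, contour_vertices = 96,
                       sharpness_widths_mm = c(conventional = 3, cs = 4)) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(seed))
    stop_stage("run-config", "seed is mandatory in simulate mode")
  if (mode == "load" && is.null(curves_path))
    stop_stage("run-config", "curves_path is mandatory in load mode")
  structure(list(mode = mode, seed = seed, n_hv = n_hv, n_hfref = n_hfref,
                 curves_path = curves_path, smooth_window = smooth_window,
                 disagreement = disagreement,
                 reader_jitter_sd = reader_jitter_sd, readers = readers,
                 through_contours = through_contours,
                 contour_vertices = contour_vertices,
                 sharpness_widths_mm = sharpness_widths_mm),
            class = "run_config")
}

# measure one reading: curve -> [contours -> area-length volumes] ->
# landmarks -> derived parameters
measure_curves <- function(la_curve, ra_curve, smooth_window,
                           through_contours, vertices) {
  if (through_contours) {
    la_curve <- curve_from_contours(
      contours_from_curve(la_curve, vertices = vertices, chamber = "LA"), "LA")
    ra_curve <- curve_from_contours(
      contours_from_curve(ra_curve, vertices = vertices, chamber = "RA"), "RA")
  }
  la <- find_landmarks(la_curve, smooth_window)
  ra <- find_landmarks(ra_curve, smooth_window)
  f <- compute_function(la)
  data.frame(LAVmin = la$v_min, LAVmax = la$v_max,
             RAVmin = ra$v_min, RAVmax = ra$v_max,
             TEF = f$tef, PEF = f$pef, AEF = f$aef,
             VmidMin = la$v_mid_min, VmidMax = la$v_mid_max,
             TEV = f$tev, PEV = f$pev, AEV = f$aev,
             no_kick = la$no_kick)
}

#' Measure every reading of a cohort
#'
#' Runs the measurement pipeline (optionally through synthetic contours and
#' area-length volumetry) on every subject x technique x reader curve pair
#' and returns the per-reading parameter table.
#'
#' @param cohort an `atrial_cohort`.
#' @param config a [run_config()].
#' @return Data.frame with one row per reading.
#' @export
measure_cohort <- function(cohort, config = run_config("simulate", seed = 1)) {
  rows <- list()
  for (s in cohort$subjects) {
    for (tc in names(s$readings)) {
      for (rd in names(s$readings[[tc]])) {
        m <- measure_curves(s$readings[[tc]][[rd]]$LA$curve,
                            s$readings[[tc]][[rd]]$RA$curve,
                            config$smooth_window, config$through_contours,
                            config$contour_vertices)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(subject = s$id, group = s$group, technique = tc,
                     reader = rd), m)
      }
    }
  }
  do.call(rbind, rows)
}

#' Distribution summary in the reporting convention
#'
#' A Kolmogorov-Smirnov normality screen gates the form: mean +/- SD for
#' normal-looking samples, median with interquartile range otherwise.
#' Quartiles use linear interpolation (type 7).
#'
#' @param values numeric vector (n >= 5, non-constant).
#' @return List with `form` (`"mean_sd"` or `"median_iqr"`), `text`, and
#'   the underlying statistics.
#' @export
summarize_distribution <- function(values) {
  if (length(values) < 5) stop_stage("summary", "need n >= 5")
  if (diff(range(values)) == 0)
    stop_stage("summary", "degenerate constant sample")
  ks <- ks_normality(values)
  if (ks$normal) {
    list(form = "mean_sd", mean = mean(values), sd = stats::sd(values),
         text = sprintf("%.1f ± %.1f", mean(values), stats::sd(values)))
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(form = "median_iqr", median = q[2], q1 = q[1], q3 = q[3],
         text = sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3]))
  }
}

technique_row <- function(param, mtab) {
  r1 <- mtab[mtab$reader == "R1", ]
  conv <- r1[r1$technique == "conventional", ]
  cs <- r1[r1$technique == "cs", ]
  cs <- cs[match(conv$subject, cs$subject), ]
  a <- conv[[param]]; b <- cs[[param]]
  ba <- bland_altman(a, b)
  data.frame(
    parameter = param,
    conventional = summarize_distribution(a)$text,
    cs = summarize_distribution(b)$text,
    p = mann_whitney_u(a, b)$p,
    r2 = r_squared(a, b),
    bias = ba$bias, loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
    icc = icc_absolute(cbind(a, b)),
    failed = FALSE, reason = "")
}

failed_row <- function(param, e, cols) {
  out <- data.frame(parameter = param, failed = TRUE,
                    reason = conditionMessage(e))
  for (cl in setdiff(cols, names(out))) out[[cl]] <- NA
  out[, cols]
}

observer_rows <- function(param, mtab) {
  out <- list()
  for (tc in c("conventional", "cs")) {
    t1 <- mtab[mtab$technique == tc & mtab$reader == "R1", ]
    for (cmp in c("inter", "intra")) {
      other <- mtab[mtab$technique == tc &
                      mtab$reader == ifelse(cmp == "inter", "R2", "R1b"), ]
      other <- other[match(t1$subject, other$subject), ]
      out[[paste(tc, cmp)]] <- data.frame(
        parameter = param, technique = tc, comparison = cmp,
        icc = icc_absolute(cbind(t1[[param]], other[[param]])))
    }
  }
  do.call(rbind, out)
}

diagnostic_row <- function(param, mtab) {
  r1 <- mtab[mtab$reader == "R1", ]
  conv <- r1[r1$technique == "conventional", ]
  cs <- r1[r1$technique == "cs", ]
  cs <- cs[match(conv$subject, cs$subject), ]
  lab <- conv$group == "HFrEF"
  dir <- parameter_direction(param)
  ra <- roc_auc(conv[[param]], lab, dir)
  rb <- roc_auc(cs[[param]], lab, dir)
  dl <- delong_test(conv[[param]], cs[[param]], lab, dir)
  data.frame(parameter = param,
             auc_conventional = ra$auc, sens_conventional = ra$sensitivity,
             spec_conventional = ra$specificity,
             auc_cs = rb$auc, sens_cs = rb$sensitivity,
             spec_cs = rb$specificity, delong_p = dl$p)
}

#' Run an end-to-end study
#'
#' Simulates (or loads) a cohort, measures every reading through the
#' volumetry and atrial-function pipeline, and assembles the three report
#' tables: the per-parameter technique comparison (summary per technique,
#' Mann-Whitney p, R-squared, Bland-Altman bias and limits of agreement,
#' ICC), the inter-/intra-observer ICC table, and the diagnostic table
#' (ROC AUC, sensitivity, specificity per technique plus the paired DeLong
#' p), along with an optional phantom-pair sharpness comparison. A failed
#' parameter row is marked and the run continues. Fully deterministic for
#' a given seed.
#'
#' @param config a [run_config()].
#' @return An object of class `study_report`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    cohort <- generate_cohort(
      cohort_config(n_hv = config$n_hv, n_hfref = config$n_hfref,
                    seed = config$seed,
                    reader_jitter_sd = config$reader_jitter_sd),
      disagreement = config$disagreement, readers = config$readers)
    mtab <- measure_cohort(cohort, config)
  } else {
    curves <- read_curve_csv(config$curves_path)
    mtab <- measure_curve_table(curves, config)
  }

  tc_cols <- c("parameter", "conventional", "cs", "p", "r2", "bias",
               "loa_lower", "loa_upper", "icc", "failed", "reason")
  tech <- do.call(rbind, lapply(atrial_parameters, function(p)
    tryCatch(technique_row(p, mtab)[, tc_cols],
             error = function(e) failed_row(p, e, tc_cols))))

  obs <- NULL
  if (all(c("R1b", "R2") %in% mtab$reader)) {
    obs <- do.call(rbind, lapply(
      c("LAVmin", "LAVmax", "RAVmin", "RAVmax"),
      function(p) observer_rows(p, mtab)))
    rownames(obs) <- NULL
  }

  diag_tab <- NULL
  if (length(unique(mtab$group)) == 2) {
    dg_cols <- c("parameter", "auc_conventional", "sens_conventional",
                 "spec_conventional", "auc_cs", "sens_cs", "spec_cs",
                 "delong_p")
    diag_tab <- do.call(rbind, lapply(atrial_parameters, function(p)
      tryCatch(diagnostic_row(p, mtab),
               error = function(e) failed_row(p, e, dg_cols))))
  }

  sharp <- NULL
  if (!is.null(config$sharpness_widths_mm)) {
    w <- config$sharpness_widths_mm
    sh <- vapply(w, function(wi)
      compute_sharpness(render_phantom_frame(
        phantom_config(edge_width_mm = wi)))$sharpness, numeric(1))
    sharp <- data.frame(technique = names(w), edge_width_mm = unname(w),
                        sharpness_per_mm = unname(sh))
  }

  structure(list(technique_comparison = tech, observer_agreement = obs,
                 diagnostics = diag_tab, sharpness = sharp,
                 measurements = mtab, config = config),
            class = "study_report")
}

# measurement path for externally loaded curve tables (long CSV schema with
# a chamber column)
measure_curve_table <- function(curves, config) {
  if (!"chamber" %in% names(curves))
    stop_stage("pipeline", "curve table needs a chamber column (LA/RA)")
  key <- unique(curves[, c("subject", "group", "technique", "reader")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- curves$subject == key$subject[i] &
      curves$technique == key$technique[i] & curves$reader == key$reader[i]
    la <- curves[sel & curves$chamber == "LA", ]
    ra <- curves[sel & curves$chamber == "RA", ]
    if (!nrow(la) || !nrow(ra))
      stop_stage("pipeline", "missing chamber curve for subject ",
                 key$subject[i])
    m <- measure_curves(tv_curve(la$volume_ml[order(la$phase)]),
                        tv_curve(ra$volume_ml[order(ra$phase)]),
                        config$smooth_window, config$through_contours,
                        config$contour_vertices)
    cbind(key[i, , drop = FALSE], m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

round_df <- function(df, rules) {
  for (nm in names(rules)) {
    hit <- grep(rules[[nm]], names(df))
    for (j in hit) if (is.numeric(df[[j]]))
      df[[j]] <- round(df[[j]], as.integer(nm))
  }
  df
}

#' Serialize a study report
#'
#' Writes the report tables as CSV files (`technique_comparison.csv`,
#' `observer_agreement.csv`, `diagnostics.csv`, `sharpness.csv`) plus a
#' combined `report.json`. Numbers are rounded only here: one decimal for
#' volumes/percent, two for ICC, R-squared, and AUC; p-values keep four
#' significant digits.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    if (is.null(df)) return(NULL)
    df <- round_df(df, list(
      `2` = "^(icc|r2|auc_conventional|auc_cs)$",
      `1` = "^(bias|loa_lower|loa_upper|sens_|spec_|sharpness|edge_width)"))
    for (j in grep("^(p|delong_p)$", names(df)))
      df[[j]] <- signif(df[[j]], 4)
    df
  }
  tabs <- list(technique_comparison = fmt(report$technique_comparison),
               observer_agreement = fmt(report$observer_agreement),
               diagnostics = fmt(report$diagnostics),
               sharpness = fmt(report$sharpness))
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]]))
      utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(Filter(Negate(is.null), tabs),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n\nTechnique comparison (conventional vs CS):\n")
  df <- x$technique_comparison
  df$p <- signif(df$p, 3)
  for (nm in c("r2", "icc")) df[[nm]] <- round(df[[nm]], 2)
  for (nm in c("bias", "loa_lower", "loa_upper"))
    df[[nm]] <- round(df[[nm]], 1)
  print(df[, c("parameter", "conventional", "cs", "p", "r2", "bias",
               "loa_lower", "loa_upper", "icc")], row.names = FALSE)
  if (!is.null(x$observer_agreement)) {
    cat("\nObserver agreement (ICC):\n")
    oa <- x$observer_agreement
    oa$icc <- round(oa$icc, 3)
    print(oa, row.names = FALSE)
  }
  if (!is.null(x$diagnostics)) {
    cat("\nDiagnostic performance (HV vs HFrEF):\n")
    dg <- x$diagnostics
    for (nm in grep("^auc", names(dg))) dg[[nm]] <- round(dg[[nm]], 2)
    for (nm in grep("^(sens|spec)", names(dg))) dg[[nm]] <- round(dg[[nm]], 1)
    dg$delong_p <- signif(dg$delong_p, 3)
    print(dg, row.names = FALSE)
  }
  if (!is.null(x$sharpness)) {
    cat("\nPhantom edge sharpness:\n")
    print(x$sharpness, row.names = FALSE)
  }
  invisible(x)
}
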