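#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank tie
#' handling: exact two-sided p for small tie-free samples, otherwise the
#' normal approximation with tie and continuity correction (the behaviour
#' of [stats::wilcox.test()], which backs this interface).
#'
#' @param x,y numeric vectors (each non-empty).
#' @return List with `u` (U statistic of `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y))
    stop_stage("mwu", "both groups must be non-empty")
  if (diff(range(c(x, y))) == 0) return(list(u = length(x) * length(y) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Intraclass correlation, two-way, absolute agreement, single measures
#'
#' ICC(A,1) from the two-way ANOVA decomposition of a complete subjects x
#' raters matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`,
#' where MSR, MSC, MSE are the subject, rater, and residual mean squares.
#' Mean squares are obtained from [stats::aov()]. The absolute-agreement
#' form penalizes systematic rater offsets, unlike the consistency form.
#'
#' @param m numeric matrix, subjects in rows, raters in columns, no missing
#'   cells.
#' @param type `"single"` (default, ICC(A,1)) or `"average"` (ICC(A,k)).
#' @return ICC value in `[-1, 1]`.
#' @export
icc_absolute <- function(m, type = c("single", "average")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (any(!is.finite(m)))
    stop_stage("icc", "matrix has missing or non-finite cells (no imputation)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_stage("icc", "need >= 2 subjects and >= 2 raters")
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (type == "single") {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    if (denom == 0) return(1)
    (msr - mse) / denom
  } else {
    denom <- msr + (msc - mse) / n
    if (denom == 0) return(1)
    (msr - mse) / denom
  }
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented `a - b`. Bias is their mean, `sd_diff` the
#' sample SD (n-1 denominator), and the limits of agreement are
#' `bias +/- 1.96 sd_diff` — exactly symmetric about the bias.
#'
#' @param a,b paired numeric vectors (>= 2 pairs).
#' @return List with `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_stage("bland-altman", "unequal lengths")
  if (length(a) < 2) stop_stage("bland-altman", "need >= 2 pairs")
  d <- a - b
  if (any(!is.finite(d))) stop_stage("bland-altman", "non-finite differences")
  bias <- mean(d); s <- stats::sd(d)
  res <- list(bias = bias, sd_diff = s,
              loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
              n = length(d))
  stopifnot(isTRUE(all.equal(res$loa_upper - bias, bias - res$loa_lower)))
  res
}

#' Coefficient of determination between paired measurements
#'
#' Square of the Pearson correlation (sign-insensitive).
#'
#' @param a,b paired numeric vectors (>= 3 pairs, both non-constant).
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop_stage("r-squared", "need >= 3 pairs of equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_stage("r-squared", "zero variance")
  stats::cor(a, b)^2
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `items x raters` categorical ratings with
#' the same number of raters per item. Also reports the qualitative band
#' (poor / slight / fair / moderate / substantial / almost excellent).
#'
#' @param ratings matrix or data.frame, items in rows, raters in columns;
#'   entries are category labels.
#' @return List with `kappa` and `band`.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n_r <- ncol(ratings); n_i <- nrow(ratings)
  if (n_r < 2) stop_stage("fleiss", "need >= 2 raters")
  if (any(is.na(ratings)))
    stop_stage("fleiss", "every item must be rated by every rater")
  cats <- sort(unique(as.vector(ratings)))
  counts <- t(apply(ratings, 1, function(r)
    vapply(cats, function(ct) sum(r == ct), numeric(1))))
  if (length(cats) == 1L) counts <- matrix(counts, ncol = 1)
  p_j <- colSums(counts) / (n_i * n_r)
  pe <- sum(p_j^2)
  if (pe >= 1)
    stop_stage("fleiss", "kappa undefined: all ratings in a single category")
  po <- mean((rowSums(counts^2) - n_r) / (n_r * (n_r - 1)))
  kappa <- (po - pe) / (1 - pe)
  band <- if (kappa < 0) "poor" else if (kappa <= 0.2) "slight" else
    if (kappa <= 0.4) "fair" else if (kappa <= 0.6) "moderate" else
    if (kappa <= 0.8) "substantial" else "almost excellent"
  list(kappa = kappa, band = band)
}

# empirical AUC via the Mann-Whitney identity with midranks; values must
# already be oriented so that larger predicts the positive class
auc_mw <- function(values, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(values)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical AUC by the Mann-Whitney identity `AUC = U / (n1 n0)` with
#' midrank tie handling. `direction` fixes the predictor orientation a
#' priori (e.g. volumes are higher in disease, emptying fractions lower);
#' sensitivity and specificity are reported at the cutoff maximizing the
#' Youden index `J = sens + spec - 1` (ties resolve to the lower cutoff).
#'
#' @param values numeric predictor.
#' @param labels logical or 0/1 vector; `TRUE`/1 is the positive (diseased)
#'   class.
#' @param direction `"higher"` if larger values indicate the positive
#'   class, `"lower"` otherwise.
#' @return List with `auc`, `sensitivity` and `specificity` (percent),
#'   `cutoff` (on the original scale), `direction`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(values, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  positive <- as.logical(labels)
  if (!any(positive) || all(positive))
    stop_stage("roc", "both classes must be present")
  v <- if (direction == "higher") values else -values
  auc <- auc_mw(v, positive)
  cuts <- sort(unique(v))
  thr <- c(-Inf, (cuts[-1] + cuts[-length(cuts)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(v[positive] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(v[!positive] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]            # lowest cutoff on ties
  cutoff <- thr[best]
  list(auc = auc, sensitivity = 100 * sens[best],
       specificity = 100 * spec[best],
       cutoff = if (direction == "higher") cutoff else -cutoff,
       direction = direction, n_pos = sum(positive), n_neg = sum(!positive))
}

# DeLong structural components: V10 per positive case, V01 per control
delong_components <- function(values, positive) {
  xs <- values[positive]; ys <- values[!positive]
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two paired (correlated) AUCs
#'
#' Compares the AUCs of two predictors measured on the same subjects using
#' the DeLong structural-component covariance estimate;
#' `z = (AUC_A - AUC_B) / sqrt(var(dAUC))` with a two-sided normal p.
#'
#' @param values_a,values_b paired numeric predictors.
#' @param labels positive-class indicator (logical or 0/1).
#' @param direction orientation applied to both predictors (see
#'   [roc_auc()]).
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `var_diff`, and
#'   `identical` (flag: zero-variance difference).
#' @export
delong_test <- function(values_a, values_b, labels,
                        direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  positive <- as.logical(labels)
  if (!any(positive) || all(positive))
    stop_stage("delong", "both classes must be present")
  if (length(values_a) != length(values_b) ||
      length(values_a) != length(labels))
    stop_stage("delong", "predictors must be paired on the same subjects")
  if (direction == "lower") { values_a <- -values_a; values_b <- -values_b }
  ca <- delong_components(values_a, positive)
  cb <- delong_components(values_b, positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  s10 <- stats::var(ca$v10 - cb$v10)
  s01 <- stats::var(ca$v01 - cb$v01)
  var_diff <- s10 / n1 + s01 / n0
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    return(list(auc_a = ca$auc, auc_b = cb$auc, z = 0, p = 1,
                var_diff = 0, identical = TRUE))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff, identical = FALSE)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS distance against a normal with the sample mean and SD,
#' with the asymptotic KS null distribution (parameters estimated from the
#' data — the Lilliefors caveat applies, mirroring common statistical
#' software usage). Used only to choose between mean +/- SD and median/IQR
#' reporting.
#'
#' @param values numeric vector, n >= 5.
#' @return List with `d`, `p`, and `normal` (`p > 0.05`).
#' @export
ks_normality <- function(values) {
  if (length(values) < 5) stop_stage("ks", "need n >= 5")
  if (stats::sd(values) == 0) stop_stage("ks", "degenerate constant sample")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(d = unname(kt$statistic), p = kt$p.value, normal = kt$p.value > 0.05)
}
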