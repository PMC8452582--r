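# shared fixtures built in code

hv_phenotype <- function(noise_sd = 0) {
  curve_phenotype(24, 35, 40, 70, noise_sd = noise_sd)
}

# independent dense evaluation of the cosine-segment interpolant, written
# against the documented control-point contract (not the package internals)
oracle_curve_value <- function(t, v_min, v_max, v_dia, v_preA,
                               t_max = 0.40, t_dia = 0.65, t_preA = 0.875) {
  tt <- c(0, t_max, t_dia, t_preA, 1)
  vv <- c(v_min, v_max, v_dia, v_preA, v_min)
  t <- t %% 1
  sapply(t, function(ti) {
    k <- max(which(tt <= ti + 1e-15)); k <- min(k, 4)
    u <- (ti - tt[k]) / (tt[k + 1] - tt[k])
    vv[k] + (vv[k + 1] - vv[k]) * (1 - cos(pi * u)) / 2
  })
}

# regular polygon inscribed in an ellipse, apex-at-origin layout
ellipse_polygon <- function(a, b, n = 200) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = b * sin(phi), y = a - a * cos(phi))
}

# random valid landmark quadruple generator (v_min <= v_mid_min <=
# v_mid_max <= v_max), vectorized
random_quadruples <- function(n) {
  v <- matrix(stats::runif(4 * n, 1, 200), ncol = 4)
  t(apply(v, 1, sort))   # columns: v_min, v_mid_min, v_mid_max, v_max
}

# Random phenotype within the physiological envelope: emptying fraction
# <= 85%, a pre-contraction peak distinguishable from the reservoir peak
# (VpreA <= 0.95 Vmax), an atrial kick large enough to survive 25-phase
# sampling (>= 3 ml), and landmark timing in the normal human ranges.
# Curve-shape landmark detection is only well-posed on such cycles.
random_physiological_phenotype <- function() {
  repeat {
    v <- sort(stats::runif(4, 10, 160))
    if (100 * (v[4] - v[1]) / v[4] <= 85 && v[3] <= 0.95 * v[4] &&
        (v[3] - v[2]) >= 3) break
  }
  curve_phenotype(v[1], v[2], v[3], v[4],
                  t_max = stats::runif(1, 0.35, 0.48),
                  t_dia = stats::runif(1, 0.60, 0.75),
                  t_preA = stats::runif(1, 0.80, 0.92))
}

# brute-force two-way ANOVA mean squares from explicit sums of squares
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
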