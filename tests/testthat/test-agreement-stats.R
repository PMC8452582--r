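test_that("Mann-Whitney U: enumeration oracle and complement identity", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  # exact two-sided p by enumeration: 2 / choose(4, 2) extreme assignments
  expect_equal(r$p, 2 / choose(4, 2), tolerance = 1e-12)
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p, 1)
  x <- c(1.2, 3.1, 0.5, 7); y <- c(2.2, 4.4, 0.1)
  expect_equal(mann_whitney_u(x, y)$u + mann_whitney_u(y, x)$u,
               length(x) * length(y))
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("ICC equals the brute-force ANOVA oracle", {
  withr::with_seed(5, {
    for (i in 1:20) {
      m <- matrix(rnorm(6 * 3, mean = rep(rnorm(6, sd = 3), 3)), 6, 3)
      expect_equal(icc_absolute(m), icc_oracle(m), tolerance = 1e-10)
    }
  })
  # identical columns -> perfect agreement
  base <- c(1, 5, 9, 2, 7)
  expect_equal(icc_absolute(cbind(base, base)), 1)
  # constant offset: absolute agreement penalized, consistency would not be
  m_off <- cbind(base, base + 10)
  expect_lt(icc_absolute(m_off), 1)
  expect_equal(icc_absolute(m_off), icc_oracle(m_off), tolerance = 1e-10)
  # pure noise, no subject effect: near zero
  withr::with_seed(8, {
    m0 <- matrix(rnorm(12), 6, 2)
    expect_lt(abs(icc_absolute(m0)), 0.6)
    expect_equal(icc_absolute(m0), icc_oracle(m0), tolerance = 1e-10)
  })
  expect_error(icc_absolute(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("Bland-Altman: constants, two-point SD, antisymmetry, symmetric LoA", {
  r <- bland_altman(c(6, 7, 8), c(1, 2, 3))
  expect_equal(r$bias, 5); expect_equal(r$sd_diff, 0)
  expect_equal(r$loa_lower, 5); expect_equal(r$loa_upper, 5)
  r2 <- bland_altman(c(0, 2), c(1, 1))   # differences -1, +1
  expect_equal(r2$bias, 0)
  expect_equal(r2$sd_diff, sqrt(2))
  expect_equal(r2$loa_upper, 1.96 * sqrt(2))
  a <- rnorm(10); b <- rnorm(10)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(g$bias, -f$bias)
  expect_equal(g$loa_lower, -f$loa_upper)
  expect_equal(g$loa_upper - g$loa_lower, f$loa_upper - f$loa_lower)
  expect_error(bland_altman(1, 2), "pairs")
})

test_that("R-squared: exact fits and independence bound", {
  x <- 1:50
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(x, -x), 1)
  withr::with_seed(10, {
    expect_lt(r_squared(rnorm(1000), rnorm(1000)), 0.02)
  })
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("Fleiss kappa: perfect, perfectly discordant, degenerate", {
  perfect <- cbind(c("a", "b", "a", "c"), c("a", "b", "a", "c"))
  expect_equal(fleiss_kappa(perfect)$kappa, 1)
  expect_equal(fleiss_kappa(perfect)$band, "almost excellent")
  # 2 items x 2 raters, (A,B) and (B,A): Po = 0, Pe = 0.5 -> kappa = -1
  disc <- rbind(c("A", "B"), c("B", "A"))
  expect_equal(fleiss_kappa(disc)$kappa, -1)
  expect_error(fleiss_kappa(rbind(c("A", "A"), c("A", "A"))), "single")
})

test_that("AUC: separation, null bound, and trapezoidal equivalence", {
  r <- roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1), "higher")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  withr::with_seed(12, {
    v <- rnorm(2000); l <- sample(rep(c(0, 1), 1000))
    expect_lt(abs(roc_auc(v, l, "higher")$auc - 0.5), 0.03)
  })
  # complement identity and the trapezoidal-integration dual computation
  withr::with_seed(13, {
    for (i in 1:50) {
      v <- rnorm(30); l <- c(rep(0, 15), rep(1, 15))[sample(30)]
      a1 <- roc_auc(v, l, "higher")$auc
      # trapezoidal integration of the empirical ROC sampled at thresholds
      # strictly between consecutive distinct values (staircase vertices)
      u <- sort(unique(v))
      th <- c(Inf, rev((u[-1] + u[-length(u)]) / 2), -Inf)
      sens <- sapply(th, function(t) mean(v[l == 1] > t))
      fpr <- sapply(th, function(t) mean(v[l == 0] > t))
      a2 <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
      expect_equal(a1, a2, tolerance = 1e-10)
      expect_equal(roc_auc(v, l, "higher")$auc +
                     roc_auc(-v, l, "higher")$auc, 1, tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:5, rep(1, 5), "higher"), "classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    for (i in 1:10) {
      v <- rnorm(40); l <- c(rep(0, 25), rep(1, 15))[sample(40)]
      ref <- as.numeric(pROC::auc(pROC::roc(l, v, direction = "<",
                                            quiet = TRUE)))
      expect_equal(roc_auc(v, l, "higher")$auc, ref, tolerance = 1e-12)
    }
  })
})

test_that("DeLong test: identity, antisymmetry, bootstrap variance oracle", {
  withr::with_seed(15, {
    v <- rnorm(60); l <- c(rep(0, 40), rep(1, 20))[sample(60)]
    r_id <- delong_test(v, v, l)
    expect_equal(r_id$p, 1)
    expect_true(r_id$identical)
    w <- v + rnorm(60, sd = 0.8)
    r1 <- delong_test(v, w, l); r2 <- delong_test(w, v, l)
    expect_equal(r1$z, -r2$z)
    expect_equal(r1$p, r2$p)
    # subject-level bootstrap of the paired AUC difference
    boot <- replicate(2000, {
      idx <- c(sample(which(l == 0), 40, TRUE), sample(which(l == 1), 20, TRUE))
      av <- roc_auc(v[idx], l[idx], "higher")$auc
      aw <- roc_auc(w[idx], l[idx], "higher")$auc
      av - aw
    })
    expect_lt(abs(r1$var_diff - var(boot)) / var(boot), 0.15)
  })
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(16, {
    v <- rnorm(50); l <- c(rep(0, 30), rep(1, 20))[sample(50)]
    w <- v + rnorm(50)
    mine <- delong_test(v, w, l)
    ref <- pROC::roc.test(pROC::roc(l, v, direction = "<", quiet = TRUE),
                          pROC::roc(l, w, direction = "<", quiet = TRUE),
                          method = "delong")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  })
})

test_that("KS normality screen: calibration, power, sup-distance oracle", {
  withr::with_seed(17, {
    hits <- mean(replicate(100, ks_normality(rnorm(1000))$p > 0.05))
    expect_gte(hits, 0.95)
    expect_lt(ks_normality(rexp(1000))$p, 0.05)
    x <- rnorm(200)
    d_pkg <- ks_normality(x)$d
    xs <- sort(x)
    fhat_hi <- seq_along(xs) / length(xs)
    fhat_lo <- (seq_along(xs) - 1) / length(xs)
    f0 <- pnorm(xs, mean(x), sd(x))
    d_brute <- max(pmax(abs(fhat_hi - f0), abs(fhat_lo - f0)))
    expect_equal(d_pkg, d_brute, tolerance = 1e-12)
  })
  expect_error(ks_normality(1:4), "n >= 5")
})

test_that("reported p-values always lie in the unit interval", {
  withr::with_seed(18, {
    for (i in 1:20) {
      x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1))
      expect_true(mann_whitney_u(x, y)$p >= 0 && mann_whitney_u(x, y)$p <= 1)
      n <- 30; l <- c(rep(0, 20), rep(1, 10))[sample(n)]
      p <- delong_test(rnorm(n), rnorm(n), l)$p
      expect_true(p >= 0 && p <= 1)
    }
  })
})
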