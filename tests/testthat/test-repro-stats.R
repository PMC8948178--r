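# ICC(1,1), exact Wilcoxon signed-rank, COV, isometric ratios,
# landmark variability.

test_that("icc_1_1 hits its limit cases and bounds", {
  perfect <- matrix(rep(c(1, 2, 3), 2), 3, 2)
  expect_equal(icc_1_1(perfect)$icc, 1)
  expect_warning(z <- icc_1_1(matrix(5, 3, 3)), "zero total variance")
  expect_equal(z$icc, 0)
  set.seed(61)
  flat <- matrix(rnorm(20), 4, 5)      # no subject effect
  r <- icc_1_1(flat)
  k <- 5
  expect_gte(r$icc, -1 / (k - 1) - 1e-12)
  expect_lte(r$icc, 1)
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
  expect_error(repeated_measures(matrix(1, 1, 5)), ">= 2 subjects")
  expect_warning(repeated_measures(rbind(c(1, NA), c(2, 3), c(4, 5))),
                 "missing")
})

test_that("icc_1_1 equals the aov oracle on random tables", {
  set.seed(62)
  for (i in 1:20) {
    x <- matrix(rnorm(25, sd = runif(1, 0.5, 3)), 5, 5) +
      rnorm(5, sd = runif(1, 0, 2))
    expect_equal(icc_1_1(x)$icc, aov_icc_oracle(x), tolerance = 1e-10)
  }
})

test_that("icc_1_1 recovers the population ICC in simulation", {
  set.seed(63)
  # 5 x 5 tables, sigma2_between = 4, sigma2_within = 1 -> ICC = 0.8.
  # At 5 subjects the ICC(1,1) estimator carries its well-known
  # negative small-sample bias (Monte-Carlo mean ~0.72, not 0.8); the
  # unbiased-recovery claim holds as the number of subjects grows.
  icc_mean <- function(n_subj, reps) mean(replicate(reps, {
    subj <- rnorm(n_subj, sd = 2)
    icc_1_1(matrix(rnorm(n_subj * 5), n_subj, 5) + subj)$icc
  }))
  m5 <- icc_mean(5, 2000)
  expect_gt(m5, 0.65)
  expect_lt(m5, 0.8)
  m50 <- icc_mean(50, 300)
  expect_equal(m50, 0.8, tolerance = 0.03 / 0.8)
  expect_lt(abs(m50 - 0.8), abs(m5 - 0.8))   # bias shrinks with n
})

test_that("wilcoxon_signed_rank is exact for small samples", {
  w <- wilcoxon_signed_rank(c(-1, 1, -2, 2))
  expect_equal(w$p_value, 1)
  w5 <- wilcoxon_signed_rank(c(1.2, 1.9, 1.5, 2.1, 1.4))
  expect_equal(w5$p_value, 2 / 32, tolerance = 1e-12)
  expect_equal(w5$statistic, 15)
  expect_warning(w0 <- wilcoxon_signed_rank(c(3, 3, 3), null = 3),
                 "equal the null")
  expect_equal(w0$p_value, 1)
})

test_that("wilcoxon agrees with enumeration and wilcox.test oracles", {
  set.seed(64)
  # tie/zero-free samples: R's wilcox.test exact p is an oracle
  for (i in 1:10) {
    x <- round(rnorm(sample(6:12, 1), mean = 0.4), 3)
    x <- x[x != 0]
    if (length(x) < 5 || anyDuplicated(abs(x))) next
    ours <- wilcoxon_signed_rank(x)
    ref <- stats::wilcox.test(x, mu = 0, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # ties and zeros: literal 2^m enumeration
  cases <- list(c(1, 1, -1, 2, 3), c(0, 0, 1, -1, 2, 2),
                c(0.5, 0.5, 0.5, -0.5, 1, -2, 2))
  for (x in cases) {
    ours <- wilcoxon_signed_rank(x)
    orc <- wsr_enum_oracle(x)
    expect_equal(ours$statistic, orc$statistic)
    expect_equal(ours$p_value, orc$p_value, tolerance = 1e-12)
  }
})

test_that("the normal approximation is close beyond n = 25", {
  set.seed(65)
  x <- rnorm(30, mean = 0.3)
  approx <- wilcoxon_signed_rank(x)
  expect_equal(approx$method, "normal approximation")
  ref <- stats::wilcox.test(x, mu = 0, exact = FALSE, correct = TRUE)
  expect_equal(approx$p_value, ref$p.value, tolerance = 0.05)
})

test_that("cov_summary reproduces printed coefficients of variation", {
  expect_equal(round(cov_summary(6180, 524)$cov_percent, 1), 8.5)
  expect_equal(round(cov_summary(6912, 470)$cov_percent, 1), 6.8)
  expect_equal(cov_summary(100, 0)$cov_percent, 0)
  expect_error(cov_summary(-5, 2), "positive")
  expect_error(cov_summary(0, 2), "positive")
  set.seed(66)
  vals <- rnorm(50, 100, 10)
  s <- cov_summary(values = vals)
  expect_equal(s$cov_percent, 100 * sd(vals) / mean(vals))
  expect_equal(s$n, 50L)
})

test_that("isometric_ratio matches linear and volume conventions", {
  expect_equal(isometric_ratio(2.0, 0.5, "linear"), 4.0)
  expect_equal(isometric_ratio(0.6, 0.5, "linear"), 1.2)
  expect_equal(isometric_ratio(7, 7, "linear"), 1.0)
  expect_equal(isometric_ratio(8, 1, "volume"), 2.0)
  expect_error(isometric_ratio(-1, 2), "positive")
})

test_that("landmark_variability summarises cohorts per landmark/axis", {
  lm <- landmark_set(AC = c(0, 0, 0), bregma = c(-0.1, -7, 10))
  v0 <- landmark_variability(list(lm, lm, lm))
  expect_true(all(v0[, c("sd_x", "sd_y", "sd_z")] == 0))
  expect_true(all(v0$n == 3))
  sim <- simulate_cohort_landmarks(200, per_axis_sd = c(0.2, 1.0, 0.3),
                                   seed = 67)
  v <- landmark_variability(sim$cohort)
  expect_equal(mean(v$sd_x), 0.2, tolerance = 0.1)
  expect_equal(mean(v$sd_y), 1.0, tolerance = 0.1)
  expect_equal(mean(v$sd_z), 0.3, tolerance = 0.1)
  # a rigid reporting frame must not change the per-axis SDs' overall scale
  g <- rigid_transform(diag(3), c(10, -5, 2))
  v_t <- landmark_variability(sim$cohort, g)
  expect_equal(v_t$sd_x, v$sd_x, tolerance = 1e-9)
  # partially present landmark: reduced n reported
  sim2 <- simulate_cohort_landmarks(
    20, presence = c(bregma = 0.35), seed = 68)
  v2 <- landmark_variability(sim2$cohort)
  expect_equal(v2$n[v2$landmark == "bregma"],
               unname(sim2$n_present["bregma"]))
  expect_lt(v2$n[v2$landmark == "bregma"], 20)
})

test_that("borderline power of the N = 5 bias design is reproduced", {
  # representative-value rule: average each subject's repetitions, then
  # one-sample signed-rank across subjects. With N = 5 the smallest
  # attainable two-sided exact p is 2/32 = 0.0625 — never < 0.05, which
  # is why a clear 1.6 degree pitch bias can only ever be borderline.
  set.seed(69)
  ps <- replicate(100, {
    sim <- simulate_positionings(n_subjects = 5, n_reps = 5)
    subj_means <- rowMeans(sim$tables$pitch$values)
    wilcoxon_signed_rank(subj_means)$p_value
  })
  expect_gte(min(ps), 0.0625)
  expect_gt(mean(ps <= 0.0625 + 1e-12), 0.5)
})
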