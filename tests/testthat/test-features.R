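test_that("basic features of a minimum-jerk pulse match closed forms", {
  A <- 29; T <- 1.5
  f <- pulse_features(pulse_trace(A = A, T = T, spec = NULL))
  expect_equal(f$amplitude, A, tolerance = 0.1 / A)
  expect_equal(f$duration, T, tolerance = 1e-3)
  expect_equal(f$v_mean, A / T, tolerance = 0.01)
  expect_equal(f$v_max, 1.875 * A / T, tolerance = 0.4 / (1.875 * A / T))
  expect_equal(f$a_max, 5.7735 * A / T^2, tolerance = 0.01)
  # construction identity
  expect_equal(f$v_mean * f$duration, f$amplitude, tolerance = 1e-12)
})

test_that("basic features reject degenerate windows", {
  p <- pulse_trace(spec = NULL)
  expect_error(basic_features(p$trace, list(onset_i = 5L, offset_i = 5L)),
               "zero-length")
  t <- seq(0, 2, by = 1e-3)
  static <- kinematic_trace(t, rep(50, length(t)), spec = NULL)
  expect_error(basic_features(static, list(onset_i = 100L, offset_i = 900L)),
               "static")
})

test_that("symmetry is 1 for minimum jerk and reciprocal under time reversal", {
  p <- pulse_trace(A = 29, T = 1.5, spec = NULL)
  expect_equal(symmetry_coefficient(p$trace, p$w), 1.0, tolerance = 0.02)

  # Beta(2, 4): mode at tau = 0.25, deceleration three times the acceleration
  pb <- pulse_trace(A = 29, T = 1.5, shape = c(2, 4), spec = NULL)
  s_fwd <- symmetry_coefficient(pb$trace, pb$w)
  expect_gt(s_fwd, 1)
  expect_equal(s_fwd, 3.0, tolerance = 0.02)
  # time reversal swaps acceleration and deceleration
  tr <- pb$trace
  rev_tr <- kinematic_trace(tr$t, rev(tr$x), spec = NULL)
  s_rev <- symmetry_coefficient(rev_tr, pb$w)
  expect_equal(s_fwd * s_rev, 1.0, tolerance = 0.02)
})

test_that("morphology moments match Beta closed forms", {
  # minimum jerk: |v| is the Beta(3,3) density in normalised time
  p <- pulse_trace(A = 29, T = 1.5, x0 = 90, spec = NULL)
  m <- morphology_moments(p$trace, p$w)
  expect_equal(m$p_mean, 104.5, tolerance = 1 / 104.5)
  expect_equal(m$skewness, 0, tolerance = 0.02)
  expect_equal(m$kurtosis, 3 - 2 / 3, tolerance = 0.02)

  # Beta(2,4): skewness 2(b-a)sqrt(a+b+1) / ((a+b+2) sqrt(ab))
  pb <- pulse_trace(A = 29, T = 1.5, shape = c(2, 4), spec = NULL)
  mb <- morphology_moments(pb$trace, pb$w)
  skew_beta <- 2 * (4 - 2) * sqrt(7) / ((2 + 4 + 2) * sqrt(2 * 4))
  expect_equal(mb$skewness, skew_beta, tolerance = 0.02 / skew_beta)

  # location/scale moments are position statistics
  idx <- p$w$onset_i:p$w$offset_i
  x <- p$trace$x[idx]
  expect_equal(m$p_root_mean, mean(x^2), tolerance = 1e-12)
  expect_equal(m$variance, stats::var(x), tolerance = 1e-12)
})

test_that("shape moments are invariant to amplitude scale and time shift", {
  p1 <- pulse_trace(A = 10, T = 2, shape = c(2.5, 4.5), spec = NULL)
  p2 <- pulse_trace(A = 55, T = 2, shape = c(2.5, 4.5), spec = NULL)
  m1 <- morphology_moments(p1$trace, p1$w)
  m2 <- morphology_moments(p2$trace, p2$w)
  expect_equal(m1$skewness, m2$skewness, tolerance = 1e-6)
  expect_equal(m1$kurtosis, m2$kurtosis, tolerance = 1e-6)
  shifted <- p1$trace; shifted$t <- shifted$t + 11
  ms <- morphology_moments(shifted, p1$w)
  expect_equal(ms$skewness, m1$skewness, tolerance = 1e-9)
  expect_equal(ms$kurtosis, m1$kurtosis, tolerance = 1e-9)
})

test_that("morphology handles forced degenerate windows", {
  t <- seq(0, 2, by = 1e-3)
  tr <- kinematic_trace(t, rep(12, length(t)), spec = NULL)
  w <- list(onset_i = 100L, offset_i = 1500L)
  # time-density moments need movement; position statistics do not
  expect_error(morphology_moments(tr, w), "zero total")
  m <- morphology_moments(tr, w, feature_config(shape_basis = "position"))
  expect_equal(m$variance, 0)
  expect_equal(m$p_root_mean, 144)
  expect_true(is.nan(m$skewness))
})

test_that("jerk-integral smoothness equals four peak accelerations for minimum jerk", {
  f <- pulse_features(pulse_trace(A = 29, T = 1.5, spec = NULL))
  expect_equal(f$smoothness / f$a_max, 4, tolerance = 0.02)
  # dimensionless variant: sqrt(int J^2 T^5/A^2) = sqrt(720) for minimum jerk
  p <- pulse_trace(A = 29, T = 1.5, spec = NULL)
  dj <- smoothness(p$trace, p$w,
                   feature_config(smoothness_metric = "dimensionless_jerk"))
  expect_equal(dj, sqrt(720), tolerance = 0.01)
  # tremor ripple strictly increases the jerk integral
  pr <- pulse_trace(A = 29, T = 1.5, spec = NULL,
                    extra = function(t) 0.3 * sin(2 * pi * 5 * t))
  expect_gt(smoothness(pr$trace, pr$w), f$smoothness)
})

test_that("minimum jerk minimises the jerk integral among two-pulse composites", {
  A <- 29; T <- 1.5; fs <- 1000
  base <- pulse_features(pulse_trace(A = A, T = T, fs = fs, spec = NULL))
  # composites: same endpoints and duration, displacement split across two
  # sub-pulses meeting at time fraction q
  for (case in 1:10) {
    q <- 0.3 + 0.04 * case
    frac <- 0.2 + 0.05 * case
    t <- seq(0, T + 1, by = 1 / fs)
    mj <- function(t0, dur) {
      tau <- pmin(pmax((t - t0) / dur, 0), 1)
      10 * tau^3 - 15 * tau^4 + 6 * tau^5
    }
    x <- 90 + A * frac * mj(0.5, q * T) + A * (1 - frac) * mj(0.5 + q * T, (1 - q) * T)
    tr <- kinematic_trace(t, x, spec = NULL)
    w <- list(onset_i = which(t >= 0.5)[1], offset_i = max(which(t <= 0.5 + T)))
    expect_gt(smoothness(tr, w), base$smoothness)
  }
})

test_that("extracted features recover generative parameters across random draws", {
  set.seed(101)
  for (i in 1:100) {
    A <- stats::runif(1, 15, 45)
    T <- stats::runif(1, 0.8, 3)
    alpha <- stats::runif(1, 2, 4)
    beta <- stats::runif(1, 2, 5)
    p <- pulse_trace(A = A, T = T, fs = 500, shape = c(alpha, beta),
                     dwell = 0.3, spec = NULL)
    f <- pulse_features(p)
    expect_equal(f$amplitude, A, tolerance = 0.005)
    expect_equal(f$duration, T, tolerance = 0.01)
    peak_v <- stats::dbeta((alpha - 1) / (alpha + beta - 2), alpha, beta) * A / T
    expect_equal(f$v_max, peak_v, tolerance = 0.01)
    skew_beta <- 2 * (beta - alpha) * sqrt(alpha + beta + 1) /
      ((alpha + beta + 2) * sqrt(alpha * beta))
    expect_lt(abs(f$skewness - skew_beta), 0.02)
  }
})

test_that("average_features is the arithmetic mean with a minimum-phase rule", {
  params <- kinematic_parameters()
  make_tab <- function(n) {
    tab <- as.data.frame(matrix(rep(1:n, length(params)), nrow = n,
                                dimnames = list(NULL, params)))
    tab
  }
  avg <- average_features(make_tab(8))
  expect_true(all(unlist(avg[params]) == 4.5))
  expect_equal(avg$n_phases, 8L)

  const <- make_tab(8); const[params] <- 7.25
  expect_true(all(unlist(average_features(const)[params]) == 7.25))

  expect_warning(avg7 <- average_features(make_tab(7)), "7 of 8")
  expect_equal(avg7$n_phases, 7L)
  expect_equal(avg7$amplitude, 4)
  expect_error(average_features(make_tab(5)), "at least 6")
  expect_error(average_features(make_tab(8)[, -1]), "amplitude")
})
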