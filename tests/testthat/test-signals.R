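test_that("read_recording parses delimited files and infers the rate", {
  t <- seq(0, 5, by = 0.05)
  df <- data.frame(time_s = t, horizontal_deg = 90 + t, vertical_deg = 90)
  rec <- read_recording(temp_recording_csv(df), subject_id = "a")
  expect_s3_class(rec, "reach_recording")
  expect_equal(length(rec$t), 101L)
  expect_equal(rec$fs_raw, 20, tolerance = 1e-9)

  # column order is header-driven
  rec2 <- read_recording(temp_recording_csv(df[, c(3, 1, 2)]))
  expect_equal(rec2$horizontal, rec$horizontal)
  expect_equal(rec2$vertical, rec$vertical)

  # tab-separated variant
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_recording(tsv)$t, rec$t)
})

test_that("read_recording rejects malformed input", {
  t <- seq(0, 5, by = 0.05)
  df <- data.frame(time_s = t, horizontal_deg = 90, vertical_deg = 90)
  bad <- df; names(bad)[2] <- "horiz"
  expect_error(read_recording(temp_recording_csv(bad)), "horizontal_deg")
  dup <- df; dup$time_s[5] <- dup$time_s[4]
  expect_error(read_recording(temp_recording_csv(dup)), "strictly increasing")
  expect_error(read_recording(temp_recording_csv(df[1, ])), "at least 2")
  # fs_raw inconsistent with the time stamps
  expect_error(read_recording(temp_recording_csv(df), fs_raw = 100), "10%")
})

test_that("write_recording round-trips through read_recording", {
  t <- seq(0, 3, by = 0.05)
  rec <- reach_recording(t, 90 + sin(t), 90 + cos(t), subject_id = "rt",
                         group = "parkinson", trial = 2L)
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, subject_id = "rt", group = "parkinson",
                         trial = 2L)
  expect_equal(back$horizontal, rec$horizontal, tolerance = 1e-12)
  expect_equal(back$vertical, rec$vertical, tolerance = 1e-12)
})

test_that("resample_spline is exact on low-degree polynomials and endpoints", {
  t <- seq(0, 5, by = 0.05)
  rs <- resample_spline(t, rep(30, 101), 1000)
  expect_length(rs$x, 5001L)
  expect_true(all(abs(rs$x - 30) < 1e-12))

  rs <- resample_spline(t, 2 * t, 1000)
  expect_lt(max(abs(rs$x - 2 * rs$t)), 1e-9)

  x3 <- 1 + t - 0.5 * t^2 + 0.1 * t^3
  rs <- resample_spline(t, x3, 1000)
  expect_lt(max(abs(rs$x - (1 + rs$t - 0.5 * rs$t^2 + 0.1 * rs$t^3))), 1e-9)
  # decimating back to the original grid recovers the samples
  back <- rs$x[match(round(t * 1000), round(rs$t * 1000))]
  expect_lt(max(abs(back - x3)), 1e-9)

  expect_error(resample_spline(t, 2 * t, -5), "positive")
  expect_error(resample_spline(t[1:3], rep(0, 3), 1000), "at least 4")
})

test_that("zero-phase Butterworth meets its frequency-response contract", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  # DC passes at unit gain
  y <- lowpass_zero_phase(rep(10, length(t)), fs)
  expect_lt(max(abs(y - 10)), 1e-9)
  # forward-backward squares the magnitude response: gain 1/2 at the cutoff
  y <- lowpass_zero_phase(sin(2 * pi * 1.5 * t), fs)
  mid <- t > 3 & t < 7
  expect_equal(max(abs(y[mid])), 0.5, tolerance = 0.01)
  # strong stop-band attenuation at 10 Hz (analytic |H|^2 ~ 5.9e-9)
  y <- lowpass_zero_phase(sin(2 * pi * 10 * t), fs)
  expect_lt(max(abs(y[t > 4.8 & t < 5.2])), 1e-6)
  # attenuation is monotone in frequency (amplitude by demodulation over the
  # central seconds, away from edge transients)
  amps <- vapply(c(0.5, 1, 2, 3, 5), function(f) {
    y <- lowpass_zero_phase(sin(2 * pi * f * t), fs)
    mid <- t > 3 & t < 7
    s <- sin(2 * pi * f * t[mid]); c2 <- cos(2 * pi * f * t[mid])
    sqrt(mean(y[mid] * s)^2 + mean(y[mid] * c2)^2) * 2
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("zero-phase filtering introduces no lag", {
  fs <- 1000
  # band-limited input: the bell-shaped velocity of a minimum-jerk movement
  p <- pulse_trace(A = 30, T = 1.5, dwell = 1)
  x <- p$trace$v
  y <- lowpass_zero_phase(x, fs)
  expect_equal(which.max(y), which.max(x), tolerance = 3)
  cc <- stats::convolve(y - mean(y), rev(x - mean(x)), type = "open")
  expect_equal(which.max(cc) - length(x), 0L)
})

test_that("filter rejects invalid usage", {
  expect_error(lowpass_zero_phase(rnorm(1000), 1000, filter_spec(cutoff_hz = 600)),
               "Nyquist")
  expect_error(lowpass_zero_phase(rnorm(10), 1000), "too short")
  expect_error(filter_spec(order = 0), "order")
  expect_error(filter_spec(cutoff_hz = -1), "positive")
})

test_that("forward-Euler differentiation is exact on low-degree polynomials", {
  t <- seq(0, 2, by = 1e-3)
  v <- differentiate(t, 3 * t)
  expect_true(all(abs(v - 3) < 1e-9))
  expect_length(v, length(t))

  a <- differentiate(t, differentiate(t, t^2))
  interior <- 2:(length(t) - 2)
  expect_true(all(abs(a[interior] - 2) < 1e-6))

  expect_error(differentiate(c(0, 1, 3), c(0, 1, 2)), "uniform")
  expect_error(differentiate(1, 1), "at least 2")
})

test_that("Euler differentiation recovers the minimum-jerk peak velocity", {
  A <- 29; T <- 1.5
  mj <- minimum_jerk(90, 90 + A, T, fs = 1000)
  v <- differentiate(mj$t, mj$x)
  expect_equal(max(v), 1.875 * A / T, tolerance = 0.005)
})

test_that("preprocess reproduces closed-form extrema for in-band movements", {
  # cutoff well above the movement band: closed forms to < 1%
  rec <- mj_recording(A = 29, T = 1.5)
  tr <- preprocess(rec, spec = filter_spec(order = 5, cutoff_hz = 4))$horizontal
  expect_equal(max(abs(tr$v)), 1.875 * 29 / 1.5, tolerance = 0.01)
  expect_equal(max(abs(tr$a)), 5.7735 * 29 / 1.5^2, tolerance = 0.01)
  # clinical default cutoff grazes the band of a 1.5 s movement: still < 5%
  trd <- preprocess(rec)$horizontal
  expect_equal(max(abs(trd$v)), 1.875 * 29 / 1.5, tolerance = 0.05)
  expect_equal(max(abs(trd$a)), 5.7735 * 29 / 1.5^2, tolerance = 0.05)
})

test_that("derivative re-filtering keeps jerk bounded under noise", {
  set.seed(1)
  rec <- mj_recording(noise_sd = 0.2)
  tr <- preprocess(rec)$horizontal
  clean <- preprocess(mj_recording())$horizontal
  expect_lt(max(abs(tr$J)), 5 * max(abs(clean$J)))
  # unfiltered triple Euler differencing on the same noisy signal blows up
  raw <- resample_spline(rec$t, rec$horizontal, 1000)
  trr <- kinematic_trace(raw$t, raw$x, spec = NULL)
  expect_gt(max(abs(trr$J)), 100 * max(abs(tr$J)))
})

test_that("constant-position recordings yield null derivatives", {
  t <- seq(0, 5, by = 0.05)
  rec <- reach_recording(t, rep(42, 101), rep(7, 101))
  tr <- preprocess(rec)$horizontal
  expect_lt(max(abs(tr$v)), 1e-6)
  expect_lt(max(abs(tr$a)), 1e-6)
  expect_lt(max(abs(tr$J)), 1e-6)
})

test_that("trace derivatives integrate back to the position", {
  p <- pulse_trace(A = 20, T = 1.2, spec = NULL)
  tr <- p$trace
  xi <- tr$x[1] + cumsum(tr$v) / tr$fs
  # forward-Euler: integral of v recovers x shifted by one sample
  expect_lt(max(abs(xi[-length(xi)] - tr$x[-1])), 1e-6 * max(abs(tr$x)))
})
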