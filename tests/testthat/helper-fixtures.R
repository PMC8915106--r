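# Closed-form single-submovement fixtures on a uniform grid.

# minimum-jerk (or Beta-shaped) pulse of amplitude A and duration T embedded
# between two rest dwells; returns the trace and the ground-truth window
pulse_trace <- function(A = 29, T = 1.5, fs = 1000, x0 = 90, dwell = 0.5,
                        shape = NULL, spec = NULL, refilter = TRUE,
                        extra = function(t) 0) {
  t <- seq(0, T + 2 * dwell, by = 1 / fs)
  tau <- pmin(pmax((t - dwell) / T, 0), 1)
  s <- if (is.null(shape)) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
       else stats::pbeta(tau, shape[1], shape[2])
  x <- x0 + A * s + extra(t)
  tr <- kinematic_trace(t, x, "horizontal", spec = spec, refilter = refilter)
  onset_i <- which(t >= dwell - 1e-12)[1]
  offset_i <- max(which(t <= dwell + T + 1e-12))
  list(trace = tr, w = list(onset_i = onset_i, offset_i = offset_i), t = t)
}

# full 13-parameter vector for a ground-truth window
pulse_features <- function(p, config = feature_config()) {
  submovement_features(p$trace, p$w, config)
}

# noiseless minimum-jerk recording at the raw goniometer rate (one channel
# moving, the other at rest) for preprocessing tests
mj_recording <- function(A = 29, T = 1.5, fs_raw = 20, x0 = 90, dwell = 1,
                         noise_sd = 0) {
  t <- seq(0, T + 2 * dwell, by = 1 / fs_raw)
  tau <- pmin(pmax((t - dwell) / T, 0), 1)
  x <- x0 + A * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  if (noise_sd > 0) x <- x + stats::rnorm(length(t), sd = noise_sd)
  reach_recording(t, x, rep(x0, length(t)), group = "healthy")
}

# write a recording to a temporary CSV and return the path
temp_recording_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
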