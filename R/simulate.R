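# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Minimum-jerk point-to-point trajectory
#'
#' Hogan's quintic: `x(tau) = x0 + (xf - x0) (10 tau^3 - 15 tau^4 + 6 tau^5)`
#' with `tau = t/T`. Velocity and acceleration vanish at both endpoints, the
#' velocity profile is a symmetric bell with peak `1.875 (xf - x0) / T`, and
#' the trajectory minimises the integrated squared jerk among all motions
#' with the same endpoints and duration.
#'
#' @param x0,xf Start and end position (degrees).
#' @param T Movement duration in seconds (> 0).
#' @param fs Sampling rate in Hz.
#' @return List with `t` (from 0 to `T`) and `x`.
#' @export
minimum_jerk <- function(x0, xf, T, fs = 1000) {
  if (!is.finite(T) || T <= 0) stop("duration T must be positive")
  t <- seq(0, T, by = 1 / fs)
  tau <- t / T
  list(t = t, x = x0 + (xf - x0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5))
}

#' Point-to-point movement with a Beta-shaped velocity profile
#'
#' Generalises the minimum-jerk bell to asymmetric profiles: the velocity is
#' proportional to the Beta(`alpha`, `beta`) density in normalised time, so
#' the position is `x0 + (xf - x0) * pbeta(t/T, alpha, beta)` and the net
#' displacement is exactly `xf - x0`. Shape `(3, 3)` reproduces the
#' minimum-jerk trajectory; `beta > alpha` prolongs the deceleration phase
#' (positive skew), as observed in bradykinetic movement.
#'
#' @inheritParams minimum_jerk
#' @param shape Length-2 vector `(alpha, beta)`, both > 1 so the velocity
#'   vanishes at the endpoints.
#' @return List with `t` and `x`.
#' @export
beta_profile_movement <- function(x0, xf, T, shape = c(3, 3), fs = 1000) {
  if (!is.finite(T) || T <= 0) stop("duration T must be positive")
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape <= 1))
    stop("shape parameters must both exceed 1")
  t <- seq(0, T, by = 1 / fs)
  list(t = t, x = x0 + (xf - x0) * stats::pbeta(t / T, shape[1], shape[2]))
}

#' Subject motion profile for the simulator
#'
#' Parameters of the generative motion model for one subject. Healthy
#' defaults: minimum-jerk-like submovements (Beta(3,3) velocity shape) of
#' 1.5 s and 29 degrees, no tremor. Parkinsonian defaults follow the
#' direction and rough magnitude of the group contrasts reported for this
#' task: 2.2-fold slowing, a prolonged deceleration phase (Beta(2.5, 4.5),
#' time-density skewness about 0.37), and a 1.5-degree tremor at 5 Hz.
#' Measurement noise (0.1 degrees) and the 1 s inter-phase dwell are common
#' to both groups.
#'
#' @param group `"healthy"` or `"parkinson"` (sets the defaults below).
#' @param base_duration Healthy submovement duration in seconds.
#' @param duration_scale Multiplier on `base_duration`.
#' @param shape Beta velocity-profile shape `(alpha, beta)`.
#' @param tremor_freq Tremor frequency in Hz.
#' @param tremor_amp Tremor amplitude in degrees (0 disables).
#' @param noise_sd White measurement-noise standard deviation in degrees.
#' @param dwell Rest time between phases in seconds.
#' @param amplitude_deg Submovement amplitude in degrees.
#' @param middle_deg Named start angles of the two channels (degrees).
#' @param variability Between-subject multiplicative standard deviation
#'   applied by [generate_cohort()] to duration, amplitude and tremor.
#' @param fs_raw Raw sampling rate in Hz (goniometer nominal 20).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(group = c("healthy", "parkinson"),
                            base_duration = 1.5,
                            duration_scale = NULL,
                            shape = NULL,
                            tremor_freq = 5.0,
                            tremor_amp = NULL,
                            noise_sd = 0.1,
                            dwell = 1.0,
                            amplitude_deg = 29,
                            middle_deg = c(horizontal = 90, vertical = 90),
                            variability = 0.08,
                            fs_raw = 20) {
  group <- match.arg(group)
  pk <- group == "parkinson"
  if (is.null(duration_scale)) duration_scale <- if (pk) 2.2 else 1.0
  if (is.null(shape)) shape <- if (pk) c(2.5, 4.5) else c(3, 3)
  if (is.null(tremor_amp)) tremor_amp <- if (pk) 1.5 else 0
  stopifnot(base_duration > 0, duration_scale > 0, all(shape > 1),
            tremor_freq > 0, tremor_amp >= 0, noise_sd >= 0, dwell >= 0,
            amplitude_deg > 0, variability >= 0, fs_raw > 0)
  structure(list(group = group, base_duration = base_duration,
                 duration_scale = duration_scale, shape = shape,
                 tremor_freq = tremor_freq, tremor_amp = tremor_amp,
                 noise_sd = noise_sd, dwell = dwell,
                 amplitude_deg = amplitude_deg, middle_deg = middle_deg,
                 variability = variability, fs_raw = fs_raw),
            class = "subject_profile")
}

# normalised times at which the Beta(alpha, beta) velocity shape crosses
# `frac` of its peak value, on each side of the mode
.beta_floor_crossings <- function(shape, frac = 0.05) {
  mode_tau <- (shape[1] - 1) / (sum(shape) - 2)
  target <- frac * stats::dbeta(mode_tau, shape[1], shape[2])
  f <- function(tau) stats::dbeta(tau, shape[1], shape[2]) - target
  c(stats::uniroot(f, c(1e-12, mode_tau), tol = 1e-10)$root,
    stats::uniroot(f, c(mode_tau, 1 - 1e-12), tol = 1e-10)$root)
}

# the eight protocol phases: channel and signed displacement sign, in order
.phase_plan <- function() {
  data.frame(
    phase_id = 1:8,
    channel = c("horizontal", "horizontal", "vertical", "vertical",
                "horizontal", "horizontal", "vertical", "vertical"),
    sign = c(1, -1, 1, -1, -1, 1, -1, 1),
    stringsAsFactors = FALSE)
}

#' Generate one synthetic two-channel recording
#'
#' Emits the eight-phase reaching protocol at the raw goniometer rate
#' (nominally 20 Hz, forcing the downstream resampling path): each phase is a
#' Beta-profile submovement of the profile's amplitude and duration on its
#' channel, separated by rest dwells, with the untouched channel holding its
#' last position. A fixed-frequency tremor sinusoid with a random phase per
#' channel (present during movement and dwell) and white measurement noise
#' are then added. Deterministic given `seed`.
#'
#' @param profile A [subject_profile()].
#' @param seed Integer seed.
#' @param subject_id,trial Metadata attached to the recording.
#' @return List with `recording` (a [reach_recording()]) and `truth`, a
#'   data.frame of per-phase ground truth: `phase_id`, `channel`, `onset`,
#'   `peak`, `offset` (s, nominal phase boundaries), `onset_eff`,
#'   `offset_eff` (observable boundaries: 5%-of-peak crossings of the ideal
#'   velocity profile), `x0`, `xf`, `amplitude`, `duration`, `alpha`, `beta`.
#' @export
generate_recording <- function(profile, seed = 1L, subject_id = "sim",
                               trial = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  .with_seed(seed, {
    plan <- .phase_plan()
    T_mv <- profile$base_duration * profile$duration_scale
    A <- profile$amplitude_deg
    fs <- profile$fs_raw
    total <- profile$dwell + nrow(plan) * (T_mv + profile$dwell)
    t <- seq(0, total, by = 1 / fs)
    pos <- list(horizontal = rep(profile$middle_deg[["horizontal"]], length(t)),
                vertical = rep(profile$middle_deg[["vertical"]], length(t)))
    cur <- profile$middle_deg
    truth <- plan
    truth$onset <- profile$dwell + (seq_len(nrow(plan)) - 1L) *
      (T_mv + profile$dwell)
    truth$offset <- truth$onset + T_mv
    mode_tau <- (profile$shape[1] - 1) / (sum(profile$shape) - 2)
    truth$peak <- truth$onset + mode_tau * T_mv
    truth$x0 <- NA_real_; truth$xf <- NA_real_
    for (i in seq_len(nrow(plan))) {
      ch <- plan$channel[i]
      x0 <- cur[[ch]]
      xf <- x0 + plan$sign[i] * A
      in_mv <- t >= truth$onset[i] & t <= truth$offset[i]
      tau <- (t[in_mv] - truth$onset[i]) / T_mv
      pos[[ch]][in_mv] <- x0 + (xf - x0) *
        stats::pbeta(tau, profile$shape[1], profile$shape[2])
      pos[[ch]][t > truth$offset[i]] <- xf
      cur[[ch]] <- xf
      truth$x0[i] <- x0; truth$xf[i] <- xf
    }
    truth$amplitude <- abs(truth$xf - truth$x0)
    truth$duration <- T_mv
    truth$alpha <- profile$shape[1]; truth$beta <- profile$shape[2]
    # observable movement boundaries: where the ideal velocity profile crosses
    # 5% of its peak. Slow asymmetric profiles spend their last fraction of a
    # degree below any detectable velocity, so nominal phase ends overstate
    # what a rest-point detector (or a human rater) can mark.
    cross <- .beta_floor_crossings(profile$shape, frac = 0.05)
    truth$onset_eff <- truth$onset + cross[1] * T_mv
    truth$offset_eff <- truth$onset + cross[2] * T_mv
    for (ch in names(pos)) {
      tremor_phase <- stats::runif(1, 0, 2 * pi)
      pos[[ch]] <- pos[[ch]] +
        profile$tremor_amp * sin(2 * pi * profile$tremor_freq * t + tremor_phase) +
        stats::rnorm(length(t), sd = profile$noise_sd)
    }
    rec <- reach_recording(t, pos$horizontal, pos$vertical,
                           subject_id = subject_id, group = profile$group,
                           trial = trial, fs_raw = fs)
    list(recording = rec, truth = truth)
  })
}

#' Generate a two-group cohort of synthetic recordings
#'
#' Draws one motion profile per subject — multiplicative log-normal
#' between-subject factors (standard deviation `variability`) on duration
#' scale, amplitude and tremor amplitude — and generates `trials` recordings
#' per subject with that shared profile. Deterministic given `seed`.
#'
#' @param n_per_group Subjects per group.
#' @param trials Recordings per subject.
#' @param profiles Named list of group [subject_profile()]s.
#' @param seed Integer seed.
#' @return List with `recordings` (list of `list(recording, truth)`) and
#'   `manifest`, a data.frame with `subject`, `group`, `trial` and the list
#'   index of each recording.
#' @export
generate_cohort <- function(n_per_group = 6L, trials = 2L,
                            profiles = list(healthy = subject_profile("healthy"),
                                            parkinson = subject_profile("parkinson")),
                            seed = 1L) {
  stopifnot(n_per_group >= 1L, trials >= 1L,
            all(c("healthy", "parkinson") %in% names(profiles)))
  .with_seed(seed, {
    recordings <- list()
    manifest <- list()
    for (grp in c("healthy", "parkinson")) {
      base <- profiles[[grp]]
      for (s in seq_len(n_per_group)) {
        fac <- exp(stats::rnorm(3, 0, base$variability))
        prof <- base
        prof$duration_scale <- base$duration_scale * fac[1]
        prof$amplitude_deg <- base$amplitude_deg * fac[2]
        prof$tremor_amp <- base$tremor_amp * fac[3]
        subject_id <- sprintf("%s_%02d", substr(grp, 1, 1), s)
        for (tr in seq_len(trials)) {
          rec_seed <- sample.int(2147483646L, 1L)
          recordings[[length(recordings) + 1L]] <-
            generate_recording(prof, seed = rec_seed,
                               subject_id = subject_id, trial = tr)
          manifest[[length(manifest) + 1L]] <-
            data.frame(subject = subject_id, group = grp, trial = tr,
                       index = length(recordings), stringsAsFactors = FALSE)
        }
      }
    }
    list(recordings = recordings, manifest = do.call(rbind, manifest))
  })
}
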