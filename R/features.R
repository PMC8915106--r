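#' Names of the thirteen kinematic parameters
#'
#' @return Character vector of the parameter column names, in canonical order.
#' @export
kinematic_parameters <- function() {
  c("amplitude", "duration", "v_mean", "v_max", "a_max", "jerk_max",
    "symmetry", "p_mean", "p_root_mean", "variance", "skewness", "kurtosis",
    "smoothness")
}

#' Feature-extraction configuration
#'
#' @param shape_basis Basis for the two shape moments (skewness, kurtosis):
#'   `"velocity_time"` (default) treats normalised time as a random variable
#'   with density proportional to `|v(t)|` over the window — a prolonged
#'   deceleration then gives positive skew, and the minimum-jerk bell gives
#'   the Beta(3,3) kurtosis of 7/3; `"position"` computes the standardised
#'   moments of the position samples instead.
#' @param smoothness_metric `"jerk_integral"` (default) is the integral of
#'   `|J(t)|` over the submovement (deg/s^2, higher = less smooth);
#'   `"dimensionless_jerk"` is `sqrt(T^5 / A^2 * integral(J^2))`, a
#'   scale-free variant whose minimum-jerk value is `sqrt(360) ~ 18.97`.
#' @param min_phases Minimum number of phases required by
#'   [average_features()] (default 6 of the 8).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(shape_basis = c("velocity_time", "position"),
                           smoothness_metric = c("jerk_integral",
                                                 "dimensionless_jerk"),
                           min_phases = 6L) {
  structure(list(shape_basis = match.arg(shape_basis),
                 smoothness_metric = match.arg(smoothness_metric),
                 min_phases = as.integer(min_phases)),
            class = "feature_config")
}

.window_index <- function(trace, w) {
  on <- w$onset_i; off <- w$offset_i
  if (is.null(on) || is.null(off)) stop("window lacks onset_i/offset_i")
  if (off <= on) stop("zero-length submovement window")
  if (on < 1L || off > length(trace$t)) stop("window outside trace extent")
  on:off
}

#' Amplitude, duration and extrema of one submovement
#'
#' Amplitude is the absolute angular displacement between onset and offset;
#' duration is the elapsed time; mean velocity is their ratio (exactly, by
#' construction); `v_max`, `a_max` and `jerk_max` are maxima of the absolute
#' velocity, acceleration and jerk over the window, so submovements of either
#' direction report positive magnitudes.
#'
#' @param trace A [kinematic_trace()].
#' @param w One submovement window (a row of [segment_recording()] output, or
#'   any list with `onset_i` and `offset_i`).
#' @return Named list with `amplitude`, `duration`, `v_mean`, `v_max`,
#'   `a_max`, `jerk_max`.
#' @export
basic_features <- function(trace, w) {
  idx <- .window_index(trace, w)
  amplitude <- abs(trace$x[w$offset_i] - trace$x[w$onset_i])
  duration <- trace$t[w$offset_i] - trace$t[w$onset_i]
  if (max(abs(trace$v[idx])) == 0)
    stop("static window: no movement between onset and offset")
  list(amplitude = amplitude,
       duration = duration,
       v_mean = amplitude / duration,
       v_max = max(abs(trace$v[idx])),
       a_max = max(abs(trace$a[idx])),
       jerk_max = max(abs(trace$J[idx])))
}

#' Symmetry coefficient of one submovement
#'
#' Ratio of the deceleration-phase duration to the acceleration-phase
#' duration, the phases being separated by the instant of peak absolute
#' velocity within the window. 1 for a symmetric (minimum-jerk-like) bell;
#' above 1 when deceleration is prolonged, as in bradykinetic movement.
#'
#' @inheritParams basic_features
#' @return Positive scalar.
#' @export
symmetry_coefficient <- function(trace, w) {
  idx <- .window_index(trace, w)
  peak_rel <- which.max(abs(trace$v[idx]))
  if (peak_rel == 1L || peak_rel == length(idx))
    stop("degenerate window: velocity peak at the window edge")
  peak_t <- trace$t[idx[peak_rel]]
  (trace$t[w$offset_i] - peak_t) / (peak_t - trace$t[w$onset_i])
}

#' Morphology moments of one submovement
#'
#' Five statistics of the "Gaussian-like" morphology of the submovement.
#' Location and scale are computed on the position samples over the window:
#' `p_mean` (deg), `p_root_mean` (mean of squared position, deg^2) and
#' `variance` (deg^2). The two shape moments are computed, by default, on
#' time weighted by the absolute velocity: with `p(t) = |v(t)| / integral(|v|)`
#' over the window, `skewness` and `kurtosis` are the standardised third and
#' fourth moments of `t` under `p` (kurtosis is non-excess: a minimum-jerk
#' bell gives 7/3, a Gaussian-shaped profile 3). See [feature_config()] for
#' the alternative position basis.
#'
#' @inheritParams basic_features
#' @param config A [feature_config()].
#' @return Named list with `p_mean`, `p_root_mean`, `variance`, `skewness`,
#'   `kurtosis`.
#' @export
morphology_moments <- function(trace, w, config = feature_config()) {
  idx <- .window_index(trace, w)
  if (length(idx) < 10L) stop("window too short for morphology moments")
  x <- trace$x[idx]
  out <- list(p_mean = mean(x),
              p_root_mean = mean(x^2),
              variance = stats::var(x))
  if (config$shape_basis == "velocity_time") {
    wgt <- abs(trace$v[idx])
    tot <- sum(wgt)
    if (tot == 0) stop("zero total |v| in window; shape moments undefined")
    wgt <- wgt / tot
    tt <- trace$t[idx]
    mu <- sum(wgt * tt)
    m2 <- sum(wgt * (tt - mu)^2)
    out$skewness <- sum(wgt * (tt - mu)^3) / m2^1.5
    out$kurtosis <- sum(wgt * (tt - mu)^4) / m2^2
  } else {
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    # constant position: location moments are still defined, shapes are not
    out$skewness <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NaN
    out$kurtosis <- if (m2 > 0) mean((x - mu)^4) / m2^2 else NaN
  }
  out
}

#' Jerk-based smoothness of one submovement
#'
#' Default metric: the integral of the absolute jerk over the submovement
#' (rectangle rule at the trace sampling rate), in deg/s^2 — the total
#' variation of the acceleration profile. Higher values mean rougher
#' movement; for a noiseless minimum-jerk submovement it equals 4 times the
#' peak acceleration. The `"dimensionless_jerk"` variant rescales the
#' integrated squared jerk by duration and amplitude,
#' `sqrt(T^5 / A^2 * integral(J^2))`, with minimum-jerk value `sqrt(360)`.
#'
#' @inheritParams morphology_moments
#' @return Positive scalar.
#' @export
smoothness <- function(trace, w, config = feature_config()) {
  idx <- .window_index(trace, w)
  dt <- 1 / trace$fs
  if (config$smoothness_metric == "jerk_integral") {
    sum(abs(trace$J[idx])) * dt
  } else {
    A <- abs(trace$x[w$offset_i] - trace$x[w$onset_i])
    T <- trace$t[w$offset_i] - trace$t[w$onset_i]
    sqrt(T^5 / A^2 * sum(trace$J[idx]^2) * dt)
  }
}

#' Full feature vector of one submovement
#'
#' @inheritParams morphology_moments
#' @return One-row data.frame with the thirteen parameter columns of
#'   [kinematic_parameters()].
#' @export
submovement_features <- function(trace, w, config = feature_config()) {
  f <- c(basic_features(trace, w),
         list(symmetry = symmetry_coefficient(trace, w)),
         morphology_moments(trace, w, config),
         list(smoothness = smoothness(trace, w, config)))
  as.data.frame(f[kinematic_parameters()])
}

#' Extract features for every submovement of a recording
#'
#' @param traces List with `horizontal` and `vertical` [kinematic_trace()]s.
#' @param windows Output of [segment_recording()].
#' @param config A [feature_config()].
#' @return Data.frame with one row per window: `channel`, `phase_id`,
#'   `onset_t`, `offset_t`, `boundary`, plus the thirteen parameter columns.
#' @export
extract_features <- function(traces, windows, config = feature_config()) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    cbind(data.frame(channel = w$channel, phase_id = w$phase_id,
                     onset_t = w$onset_t, offset_t = w$offset_t,
                     boundary = w$boundary, stringsAsFactors = FALSE),
          submovement_features(traces[[w$channel]], w, config))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average the kinematic parameters across submovements
#'
#' Arithmetic mean of each parameter over the phases present (nominally the
#' eight protocol phases). Pathological recordings may drop a phase; the
#' average is still computed when at least `min_phases` (default 6) are
#' present, and the result carries the number of phases used.
#'
#' @param features Data.frame from [extract_features()] (one recording).
#' @param config A [feature_config()].
#' @return One-row data.frame with the thirteen averaged parameters and an
#'   `n_phases` column.
#' @export
average_features <- function(features, config = feature_config()) {
  params <- kinematic_parameters()
  missing_cols <- setdiff(params, names(features))
  if (length(missing_cols))
    stop("missing parameter column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(features)
  if (n < config$min_phases)
    stop(sprintf("only %d phases present; need at least %d to average",
                 n, config$min_phases))
  if (n < 8L)
    warning(sprintf("averaging over %d of 8 phases", n))
  out <- as.data.frame(lapply(features[params], mean))
  out$n_phases <- n
  out
}
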