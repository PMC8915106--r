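#' Low-pass filter specification
#'
#' Describes the smoothing filter applied to kinematic signals: a zero-phase
#' (forward-backward) low-pass Butterworth filter. The defaults — order 5,
#' cutoff 1.5 Hz — suit voluntary reaching movements, whose energy lies below
#' about 1 Hz, while rejecting parkinsonian tremor (4-6 Hz) and sensor noise.
#' Because the filter is run forward and backward, the effective magnitude
#' response is squared: gain at the cutoff is 1/2, not 1/sqrt(2).
#'
#' @param order Filter order `n` (default 5).
#' @param cutoff_hz Cutoff frequency in Hz (default 1.5). Must be below the
#'   Nyquist frequency when applied.
#' @param zero_phase Apply forward-backward (default `TRUE`). `FALSE` gives a
#'   single causal pass (mainly for diagnostics).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 5L, cutoff_hz = 1.5, zero_phase = TRUE) {
  order <- as.integer(order)
  if (order < 1L) stop("filter order must be >= 1")
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0) stop("cutoff_hz must be positive")
  structure(list(order = order, cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> order-%d low-pass Butterworth, cutoff %.3g Hz%s\n",
              x$order, x$cutoff_hz,
              if (x$zero_phase) ", zero-phase" else ""))
  invisible(x)
}

.butter_coefs <- function(spec, fs) {
  if (spec$cutoff_hz >= fs / 2)
    stop(sprintf("cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 spec$cutoff_hz, fs / 2))
  ba <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  list(b = ba$b, a = ba$a)
}

# Steady-state initial state vector of the direct-form-II-transposed filter
# for a unit-level constant input (solve (I - A') zi = B with A the companion
# matrix of a). Scaling zi by the first sample suppresses start-up transients.
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a1 <- a[1]
  a <- c(a, numeric(n - length(a))) / a1
  b <- c(b, numeric(n - length(b))) / a1
  comp <- rbind(-a[-1], cbind(diag(n - 2L), numeric(n - 2L)))
  solve(diag(n - 1L) - t(comp), b[-1] - a[-1] * b[1])
}

# Single IIR pass with initial state zi. Uses the superposition of the
# zero-state response and the zero-input response, both computed by
# signal::filter (C speed): the zero-input response of a DF2T filter with
# initial states z equals filtering the sequence (z1, ..., z_{n-1}, 0, ...)
# through 1/a.
.lfilter <- function(b, a, x, zi) {
  y <- as.numeric(signal::filter(b, a, x))
  if (!all(zi == 0)) {
    u <- numeric(length(x))
    u[seq_along(zi)] <- zi
    y <- y + as.numeric(signal::filter(1, a, u))
  }
  y
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies the Butterworth filter described by `spec` forward and backward
#' (zero net phase shift, squared magnitude response). Start-up transients are
#' controlled by odd-reflection padding of length `3 * (filter length)` at
#' both ends together with steady-state initial conditions, and the signal
#' mean is removed before filtering and restored afterwards, so a constant
#' signal is returned unchanged to machine precision.
#'
#' @param x Numeric signal (uniformly sampled).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, fs, spec = filter_spec()) {
  ba <- .butter_coefs(spec, fs)
  b <- ba$b; a <- ba$a
  padlen <- 3L * max(length(a), length(b))
  if (length(x) <= padlen)
    stop(sprintf("signal too short to filter: need more than %d samples", padlen))
  mu <- mean(x)
  xc <- x - mu
  # odd reflection about the end samples
  ext <- c(2 * xc[1] - xc[(padlen + 1L):2L],
           xc,
           2 * xc[length(xc)] - xc[(length(xc) - 1L):(length(xc) - padlen)])
  zi <- .lfilter_zi(b, a)
  y <- .lfilter(b, a, ext, zi * ext[1])
  if (spec$zero_phase) {
    y <- rev(y)
    y <- .lfilter(b, a, y, zi * y[1])
    y <- rev(y)
  }
  y[(padlen + 1L):(padlen + length(xc))] + mu
}

#' Resample a signal on a uniform grid by cubic-spline interpolation
#'
#' Interpolates `x(t)` with a cubic spline (Forsythe-Malcolm-Moler end
#' conditions, exact for polynomials up to degree 3) and evaluates it on a
#' uniform grid at `fs_target` spanning `[t[1], t[n]]`. The left endpoint is
#' always on the grid; the last grid point is the largest `t[1] + k/fs_target`
#' not exceeding `t[n]` (equal to `t[n]` when the span is a multiple of the
#' step, as with whole-second records).
#'
#' @param t Time stamps in seconds, strictly increasing, length >= 4.
#' @param x Signal values, same length as `t`.
#' @param fs_target Target sampling rate in Hz (default 1000).
#' @return A list with components `t` and `x` on the uniform grid.
#' @export
resample_spline <- function(t, x, fs_target = 1000) {
  if (!is.finite(fs_target) || fs_target <= 0) stop("fs_target must be positive")
  if (length(t) != length(x)) stop("t and x must have equal length")
  if (length(t) < 4L) stop("cubic-spline resampling needs at least 4 samples")
  if (any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  span <- t[length(t)] - t[1]
  m <- floor(span * fs_target + 1e-9)
  tt <- t[1] + (0:m) / fs_target
  f <- stats::splinefun(t, x, method = "fmm")
  xx <- f(tt)
  # endpoints are interpolation knots: preserve them exactly
  xx[1] <- x[1]
  if (abs(tt[m + 1L] - t[length(t)]) < 1e-12) xx[m + 1L] <- x[length(x)]
  list(t = tt, x = xx)
}

#' Forward-Euler differentiation
#'
#' `y[i] = (x[i+1] - x[i]) / dt` for interior samples; the final sample
#' repeats the last difference so the derivative stays on the same grid as
#' the signal. The grid must be uniform (resample first if not).
#'
#' @param t Uniform time grid in seconds.
#' @param x Signal samples.
#' @return Numeric vector of the same length as `x`.
#' @export
differentiate <- function(t, x) {
  n <- length(t)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  if (length(x) != n) stop("t and x must have equal length")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
    stop("time grid is not uniform; resample before differentiating")
  d <- diff(x) / dt[1]
  c(d, d[n - 1L])
}

#' Kinematic trace: position, velocity, acceleration, jerk on one grid
#'
#' Builds a `kinematic_trace` from a position signal on a uniform grid by
#' successive forward-Euler differentiation. If `spec` is supplied, the
#' position is low-pass filtered first and, when `refilter = TRUE`, each
#' derivative is re-filtered with the same zero-phase filter before the next
#' differentiation — bare triple differencing at 1 kHz amplifies even tiny
#' noise into an unusable jerk trace.
#'
#' @param t Uniform time grid (seconds).
#' @param x Angular position (degrees).
#' @param channel `"horizontal"` or `"vertical"`.
#' @param spec Optional [filter_spec()]; `NULL` skips filtering.
#' @param refilter Re-apply the filter after each differentiation stage
#'   (default `TRUE`; ignored when `spec` is `NULL`).
#' @return An object of class `kinematic_trace`: list with `channel`, `fs`,
#'   `t`, `x` (deg), `v` (deg/s), `a` (deg/s^2), `J` (deg/s^3).
#' @export
kinematic_trace <- function(t, x, channel = c("horizontal", "vertical"),
                            spec = NULL, refilter = TRUE) {
  channel <- match.arg(channel)
  fs <- 1 / (t[2] - t[1])
  smooth <- function(s) {
    if (is.null(spec)) s else lowpass_zero_phase(s, fs, spec)
  }
  resmooth <- function(s) {
    if (is.null(spec) || !refilter) s else lowpass_zero_phase(s, fs, spec)
  }
  xf <- smooth(x)
  v <- resmooth(differentiate(t, xf))
  a <- resmooth(differentiate(t, v))
  J <- resmooth(differentiate(t, a))
  structure(list(channel = channel, fs = fs, t = t, x = xf, v = v, a = a, J = J),
            class = "kinematic_trace")
}

#' @export
print.kinematic_trace <- function(x, ...) {
  cat(sprintf("<kinematic_trace> %s channel, %d samples at %.4g Hz\n",
              x$channel, length(x$t), x$fs))
  cat(sprintf("  x: [%.1f, %.1f] deg; max |v| = %.2f deg/s\n",
              min(x$x), max(x$x), max(abs(x$v))))
  invisible(x)
}

#' Preprocess a recording into two kinematic traces
#'
#' Runs the standard preprocessing chain on both channels of a recording:
#' cubic-spline resampling to `fs_target` (default 1 kHz), zero-phase
#' Butterworth smoothing of the position, then forward-Euler differentiation
#' to velocity, acceleration and jerk, re-smoothing each derivative before
#' the next differentiation (see [kinematic_trace()]).
#'
#' @param rec A [reach_recording()].
#' @param spec A [filter_spec()] (default order 5, 1.5 Hz, zero-phase).
#' @param fs_target Processed sampling rate in Hz (default 1000).
#' @param refilter_derivatives Re-filter each derivative (default `TRUE`).
#' @return A list with elements `horizontal` and `vertical`, each a
#'   `kinematic_trace`.
#' @export
preprocess <- function(rec, spec = filter_spec(), fs_target = 1000,
                       refilter_derivatives = TRUE) {
  validate_recording(rec)
  out <- lapply(c("horizontal", "vertical"), function(ch) {
    rs <- resample_spline(rec$t, rec[[ch]], fs_target)
    kinematic_trace(rs$t, rs$x, channel = ch, spec = spec,
                    refilter = refilter_derivatives)
  })
  names(out) <- c("horizontal", "vertical")
  out
}
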