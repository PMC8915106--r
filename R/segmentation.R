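#' Segmentation configuration
#'
#' Tunables of the velocity-threshold submovement detector. The detection
#' threshold is a fraction of the peak absolute velocity of the whole channel
#' (default 0.30). Spurious peaks are pruned by a prominence rule (fraction of
#' the peak absolute velocity, default 0.10) and a minimum peak separation in
#' seconds (default 0.5). Onsets and offsets are pushed out from the threshold
#' crossings to the nearest rest point: a local minimum of `|v|` or a sample
#' below the velocity floor (default 0.05 of the peak absolute velocity).
#'
#' @param threshold_frac Detection threshold as a fraction of `max(|v|)`,
#'   in (0, 1). Default 0.30.
#' @param min_peak_prominence_frac Minimum peak prominence as a fraction of
#'   `max(|v|)`. Default 0.10.
#' @param min_peak_separation Minimum time between retained peaks (s).
#'   Default 0.5.
#' @param velocity_floor_frac Rest-detection floor as a fraction of
#'   `max(|v|)`; must be below `threshold_frac`. Default 0.05.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_frac = 0.30,
                                min_peak_prominence_frac = 0.10,
                                min_peak_separation = 0.5,
                                velocity_floor_frac = 0.05) {
  if (!(threshold_frac > 0 && threshold_frac < 1))
    stop("threshold_frac must lie in (0, 1)")
  if (velocity_floor_frac >= threshold_frac)
    stop("velocity_floor_frac must be below threshold_frac")
  if (min_peak_prominence_frac < 0) stop("min_peak_prominence_frac must be >= 0")
  if (min_peak_separation < 0) stop("min_peak_separation must be >= 0")
  structure(list(threshold_frac = threshold_frac,
                 min_peak_prominence_frac = min_peak_prominence_frac,
                 min_peak_separation = min_peak_separation,
                 velocity_floor_frac = velocity_floor_frac),
            class = "segmentation_config")
}

#' Detection threshold from a velocity curve
#'
#' `threshold = threshold_frac * max(|v|)`. Computed once per channel over
#' the whole recording, so the same threshold applies to every submovement of
#' that channel.
#'
#' @param v Velocity samples (deg/s).
#' @param cfg A [segmentation_config()].
#' @return Threshold in deg/s (0 for an all-zero signal, which simply yields
#'   no detections downstream).
#' @export
compute_threshold <- function(v, cfg = segmentation_config()) {
  if (!length(v)) stop("empty velocity vector")
  cfg$threshold_frac * max(abs(v))
}

# Prominence of a local maximum of s at index i: height above the higher of
# the two deepest valleys separating it from higher terrain (or the signal
# edge) on each side.
.peak_prominence <- function(s, i) {
  h <- s[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && s[j] <= h) {
    if (s[j] < left_min) left_min <- s[j]
    j <- j - 1L
  }
  right_min <- h
  j <- i + 1L
  while (j <= length(s) && s[j] <= h) {
    if (s[j] < right_min) right_min <- s[j]
    j <- j + 1L
  }
  h - max(left_min, right_min)
}

#' Find submovement velocity peaks
#'
#' Local maxima of the absolute velocity strictly above the detection
#' threshold, pruned by minimum prominence and minimum pairwise separation
#' (higher peaks win). This is the "removal of spurious peaks" stage: tremor
#' ripple and noise produce shallow local maxima whose prominence falls below
#' the cut.
#'
#' @param v Velocity samples (deg/s).
#' @param t Time grid (s), same length as `v`.
#' @param cfg A [segmentation_config()].
#' @return Integer vector of peak indices, ordered in time (possibly empty).
#' @export
find_velocity_peaks <- function(v, t, cfg = segmentation_config()) {
  s <- abs(v)
  smax <- max(s)
  if (smax == 0) return(integer(0))
  thr <- compute_threshold(v, cfg)
  n <- length(s)
  if (n < 3L) return(integer(0))
  core <- 2:(n - 1L)
  cand <- core[s[core] > s[core - 1L] & s[core] >= s[core + 1L] & s[core] > thr]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) .peak_prominence(s, i), numeric(1))
  cand <- cand[prom >= cfg$min_peak_prominence_frac * smax]
  if (length(cand) <= 1L) return(cand)
  # enforce minimum separation, keeping higher peaks first
  keep <- logical(length(cand))
  ord <- order(s[cand], decreasing = TRUE)
  for (k in ord) {
    if (!any(keep & abs(t[cand] - t[cand[k]]) < cfg$min_peak_separation))
      keep[k] <- TRUE
  }
  sort(cand[keep])
}

#' Locate submovement onset and offset around a velocity peak
#'
#' From the peak, the upward and downward crossings of the detection threshold
#' are found on the absolute velocity; the onset (offset) is then pushed
#' backward (forward) from the crossing to the nearest rest point — the first
#' sample that is a local minimum of `|v|` (ties allowed) or falls below the
#' velocity floor. A window clipped at a signal edge is flagged.
#'
#' @param v Velocity samples (deg/s).
#' @param t Time grid (s).
#' @param peak_i Index of the peak (must satisfy `|v[peak_i]| > threshold`).
#' @param threshold Detection threshold (deg/s), from [compute_threshold()].
#' @param cfg A [segmentation_config()].
#' @return List with `onset_i`, `offset_i`, `boundary` (logical: window
#'   clipped at a signal edge).
#' @export
locate_onset_offset <- function(v, t, peak_i, threshold,
                                cfg = segmentation_config()) {
  s <- abs(v)
  n <- length(s)
  if (peak_i < 1L || peak_i > n) stop("peak_i out of range")
  if (s[peak_i] <= threshold)
    stop("|v| at peak_i does not exceed the threshold")
  floor_v <- cfg$velocity_floor_frac * max(s)
  is_rest <- function(j) {
    if (s[j] <= floor_v) return(TRUE)
    lo <- if (j > 1L) s[j - 1L] else Inf
    hi <- if (j < n) s[j + 1L] else Inf
    s[j] <= lo && s[j] <= hi
  }
  boundary <- FALSE
  # upward threshold crossing
  j <- peak_i
  while (j > 1L && s[j] > threshold) j <- j - 1L
  # walk out to the nearest rest point
  while (j > 1L && !is_rest(j)) j <- j - 1L
  if (j == 1L && !is_rest(1L)) boundary <- TRUE
  onset_i <- j
  # downward crossing, then out to rest
  k <- peak_i
  while (k < n && s[k] > threshold) k <- k + 1L
  while (k < n && !is_rest(k)) k <- k + 1L
  if (k == n && !is_rest(n)) boundary <- TRUE
  offset_i <- k
  list(onset_i = onset_i, offset_i = offset_i, boundary = boundary)
}

# canonical protocol: phase ids per channel in temporal order, and the sign
# of the net displacement of each (outward positive for right/top first)
.protocol_phases <- function() {
  list(horizontal = list(ids = c(1L, 2L, 5L, 6L), dirs = c(1, -1, -1, 1)),
       vertical   = list(ids = c(3L, 4L, 7L, 8L), dirs = c(1, -1, -1, 1)))
}

#' Segment a preprocessed recording into submovement windows
#'
#' Runs threshold computation, peak detection and onset/offset location on
#' each channel's velocity curve, truncates overlapping neighbour windows at
#' the inter-peak valley of `|v|`, and labels the detected windows with the
#' protocol phase ids (horizontal channel: 1, 2, 5, 6; vertical: 3, 4, 7, 8,
#' in temporal order). When a channel does not yield the expected four
#' windows, or the displacement directions do not match the protocol
#' pattern, a warning is raised and labelling falls back to ordinal
#' assignment within the channel.
#'
#' @param traces List with `horizontal` and `vertical` [kinematic_trace()]s
#'   (as returned by [preprocess()]).
#' @param cfg A [segmentation_config()].
#' @param phase_order Optional named list overriding the per-channel phase id
#'   sequence, e.g. `list(horizontal = c(5,6,1,2), vertical = c(7,8,3,4))`
#'   for recordings acquired with the opposite task order.
#' @return A data.frame of class `submovement_windows`, one row per detected
#'   submovement, sorted by onset time, with columns `channel`, `phase_id`,
#'   `onset_i`, `peak_i`, `offset_i`, `onset_t`, `peak_t`, `offset_t`,
#'   `direction`, `boundary`.
#' @export
segment_recording <- function(traces, cfg = segmentation_config(),
                              phase_order = NULL) {
  stopifnot(is.list(traces),
            all(c("horizontal", "vertical") %in% names(traces)))
  proto <- .protocol_phases()
  out <- list()
  for (ch in c("horizontal", "vertical")) {
    tr <- traces[[ch]]
    stopifnot(inherits(tr, "kinematic_trace"))
    s <- abs(tr$v)
    thr <- compute_threshold(tr$v, cfg)
    peaks <- find_velocity_peaks(tr$v, tr$t, cfg)
    if (!length(peaks)) {
      warning(sprintf("%s channel: no submovements detected (expected %d)",
                      ch, length(proto[[ch]]$ids)))
      next
    }
    win <- lapply(peaks, function(p)
      locate_onset_offset(tr$v, tr$t, p, thr, cfg))
    onset <- vapply(win, `[[`, integer(1), "onset_i")
    offset <- vapply(win, `[[`, integer(1), "offset_i")
    boundary <- vapply(win, `[[`, logical(1), "boundary")
    # truncate overlapping neighbours at the inter-peak valley of |v|
    if (length(peaks) > 1L) {
      for (i in seq_len(length(peaks) - 1L)) {
        if (offset[i] > onset[i + 1L]) {
          valley <- peaks[i] + which.min(s[peaks[i]:peaks[i + 1L]]) - 1L
          offset[i] <- valley
          onset[i + 1L] <- valley
        }
      }
    }
    ids <- if (!is.null(phase_order)) phase_order[[ch]] else proto[[ch]]$ids
    expected <- length(ids)
    direction <- sign(tr$x[offset] - tr$x[onset])
    if (length(peaks) != expected) {
      warning(sprintf(
        "%s channel: detected %d submovements, expected %d; using ordinal phase labels",
        ch, length(peaks), expected))
      phase_id <- ids[pmin(seq_along(peaks), expected)]
    } else {
      phase_id <- ids
      if (is.null(phase_order) && !all(direction == proto[[ch]]$dirs))
        warning(sprintf(
          "%s channel: displacement directions do not match the protocol; keeping ordinal phase labels",
          ch))
    }
    out[[ch]] <- data.frame(
      channel = ch, phase_id = phase_id,
      onset_i = onset, peak_i = peaks, offset_i = offset,
      onset_t = tr$t[onset], peak_t = tr$t[peaks], offset_t = tr$t[offset],
      direction = direction, boundary = boundary,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(channel = character(0), phase_id = integer(0),
                      onset_i = integer(0), peak_i = integer(0),
                      offset_i = integer(0), onset_t = numeric(0),
                      peak_t = numeric(0), offset_t = numeric(0),
                      direction = numeric(0), boundary = logical(0))
  res <- res[order(res$onset_t), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("submovement_windows", "data.frame")
  res
}
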