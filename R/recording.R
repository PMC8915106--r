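#' Goniometric recording container
#'
#' A `reach_recording` holds one trial of the two-channel reaching task:
#' horizontal and vertical shoulder angle (degrees) against time (seconds),
#' plus subject metadata. The raw sampling rate is nominally 20 Hz.
#'
#' @param t Numeric vector of time stamps in seconds, strictly increasing.
#' @param horizontal,vertical Numeric vectors of angular position in degrees,
#'   same length as `t`.
#' @param subject_id Subject identifier (coerced to character).
#' @param group Group label, `"healthy"` or `"parkinson"`.
#' @param trial Trial index, integer >= 1.
#' @param fs_raw Nominal sampling rate in Hz. If `NULL`, inferred as the
#'   reciprocal of the median time step.
#'
#' @return An object of class `reach_recording`: a list with fields
#'   `subject_id`, `group`, `trial`, `fs_raw`, `t`, `horizontal`, `vertical`.
#' @export
reach_recording <- function(t, horizontal, vertical,
                            subject_id = "s1",
                            group = c("healthy", "parkinson"),
                            trial = 1L, fs_raw = NULL) {
  group <- match.arg(group)
  t <- as.numeric(t)
  horizontal <- as.numeric(horizontal)
  vertical <- as.numeric(vertical)
  if (is.null(fs_raw)) {
    if (length(t) < 2L) stop("recording must contain at least 2 samples")
    fs_raw <- 1 / stats::median(diff(t))
  }
  rec <- structure(
    list(subject_id = as.character(subject_id), group = group,
         trial = as.integer(trial), fs_raw = fs_raw,
         t = t, horizontal = horizontal, vertical = vertical),
    class = "reach_recording")
  validate_recording(rec)
  rec
}

#' Validate a reach_recording
#'
#' Checks the structural invariants: equal array lengths (>= 2), strictly
#' increasing time, positive sampling rate, and a median time step within 10%
#' of `1/fs_raw` (goniometer clocks jitter; larger deviations indicate a
#' mislabelled rate).
#'
#' @param rec A `reach_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "reach_recording"))
  n <- length(rec$t)
  if (n < 2L) stop("recording must contain at least 2 samples")
  if (length(rec$horizontal) != n || length(rec$vertical) != n)
    stop("time and channel vectors must have equal length")
  if (anyNA(rec$t) || anyNA(rec$horizontal) || anyNA(rec$vertical))
    stop("recording contains missing values")
  if (any(diff(rec$t) <= 0))
    stop("time stamps must be strictly increasing")
  if (!is.finite(rec$fs_raw) || rec$fs_raw <= 0)
    stop("fs_raw must be positive")
  med_dt <- stats::median(diff(rec$t))
  if (abs(med_dt - 1 / rec$fs_raw) > 0.1 / rec$fs_raw)
    stop(sprintf("median time step %.4g s is not within 10%% of 1/fs_raw = %.4g s",
                 med_dt, 1 / rec$fs_raw))
  if (!rec$group %in% c("healthy", "parkinson"))
    stop("group must be 'healthy' or 'parkinson'")
  if (rec$trial < 1L) stop("trial must be >= 1")
  invisible(rec)
}

#' Read a recording from a delimited text file
#'
#' The file must have a header row with columns `time_s`, `horizontal_deg`
#' and `vertical_deg` (any order; extra columns are ignored). The delimiter
#' is chosen from the file extension: comma for `.csv`, tab otherwise.
#'
#' @param path Path to the file.
#' @inheritParams reach_recording
#' @return A [reach_recording()].
#' @export
read_recording <- function(path, subject_id = "s1",
                           group = c("healthy", "parkinson"),
                           trial = 1L, fs_raw = NULL) {
  group <- match.arg(group)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("time_s", "horizontal_deg", "vertical_deg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  reach_recording(t = df$time_s, horizontal = df$horizontal_deg,
                  vertical = df$vertical_deg, subject_id = subject_id,
                  group = group, trial = trial, fs_raw = fs_raw)
}

#' Write a recording to a delimited text file
#'
#' Inverse of [read_recording()]: writes columns `time_s`, `horizontal_deg`,
#' `vertical_deg` with a header row (comma-separated for `.csv`, tab
#' otherwise).
#'
#' @param rec A `reach_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(time_s = rec$t, horizontal_deg = rec$horizontal,
                   vertical_deg = rec$vertical)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.reach_recording <- function(x, ...) {
  cat(sprintf("<reach_recording> subject %s (%s), trial %d\n",
              x$subject_id, x$group, x$trial))
  cat(sprintf("  %d samples, %.2f s at %.3g Hz nominal\n",
              length(x$t), diff(range(x$t)), x$fs_raw))
  cat(sprintf("  horizontal: [%.1f, %.1f] deg; vertical: [%.1f, %.1f] deg\n",
              min(x$horizontal), max(x$horizontal),
              min(x$vertical), max(x$vertical)))
  invisible(x)
}
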