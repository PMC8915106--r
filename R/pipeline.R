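#' Run configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown keys are
#' rejected, so typos in a config file fail loudly rather than silently
#' falling back to defaults.
#'
#' @param fs_target Processed sampling rate in Hz (default 1000).
#' @param filter List: `order` (5), `cutoff_hz` (1.5),
#'   `refilter_derivatives` (`TRUE`).
#' @param segmentation List: `threshold_frac` (0.30),
#'   `min_peak_prominence_frac` (0.10), `min_peak_separation` (0.5 s),
#'   `velocity_floor_frac` (0.05).
#' @param features List: `shape_basis` ("velocity_time"),
#'   `smoothness_metric` ("jerk_integral"), `min_phases` (6).
#' @param stats List: `alpha` (0.05), `heatmap_bins` (`c(0.05, 0.10)`),
#'   `bh_correct` (`FALSE`), `unit` ("recording").
#' @param digits Significant digits used when writing CSV artifacts
#'   (default 6; fixed formatting makes re-runs byte-identical).
#' @return An object of class `run_config`.
#' @export
run_config <- function(fs_target = 1000,
                       filter = list(),
                       segmentation = list(),
                       features = list(),
                       stats = list(),
                       digits = 6L) {
  merge_keys <- function(defaults, given, where) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    fs_target = fs_target,
    filter = merge_keys(list(order = 5L, cutoff_hz = 1.5,
                             refilter_derivatives = TRUE),
                        filter, "filter"),
    segmentation = merge_keys(list(threshold_frac = 0.30,
                                   min_peak_prominence_frac = 0.10,
                                   min_peak_separation = 0.5,
                                   velocity_floor_frac = 0.05),
                              segmentation, "segmentation"),
    features = merge_keys(list(shape_basis = "velocity_time",
                               smoothness_metric = "jerk_integral",
                               min_phases = 6L),
                          features, "features"),
    stats = merge_keys(list(alpha = 0.05, heatmap_bins = c(0.05, 0.10),
                            bh_correct = FALSE, unit = "recording"),
                       stats, "stats"),
    digits = as.integer(digits))
  # materialise the typed sub-configs once, validating values
  cfg$filter_spec <- filter_spec(order = cfg$filter$order,
                                 cutoff_hz = cfg$filter$cutoff_hz)
  cfg$segmentation_config <- do.call(segmentation_config, cfg$segmentation)
  cfg$feature_config <- do.call(feature_config, cfg$features)
  cfg$stat_config <- do.call(stat_config, cfg$stats)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys must be a subset of the arguments of [run_config()];
#' unknown keys (at either level) are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- c("fs_target", "filter", "segmentation", "features", "stats",
               "digits")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Analyze one recording: preprocess, segment, extract
#'
#' @param rec A [reach_recording()].
#' @param config A [run_config()].
#' @return List with `traces`, `windows` and `features` (the feature table
#'   carries `subject`, `group`, `trial` columns).
#' @export
analyze_recording <- function(rec, config = run_config()) {
  traces <- preprocess(rec, spec = config$filter_spec,
                       fs_target = config$fs_target,
                       refilter_derivatives = config$filter$refilter_derivatives)
  windows <- segment_recording(traces, cfg = config$segmentation_config)
  feats <- extract_features(traces, windows, config = config$feature_config)
  feats <- cbind(data.frame(subject = rec$subject_id, group = rec$group,
                            trial = rec$trial, stringsAsFactors = FALSE),
                 feats)
  list(traces = traces, windows = windows, features = feats)
}

# fixed-precision CSV writer: numbers at `digits` significant digits so that
# re-runs with identical inputs are byte-identical
.write_csv_fixed <- function(df, path, digits = 6L) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- trimws(formatC(out[[nm]], digits = digits, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline over a set of recordings
#'
#' For each recording: preprocess, segment, extract features; then pool the
#' feature tables, run the group comparison, and write the artifacts to
#' `out_dir`: `features.csv` (one row per submovement),
#' `features_averaged.csv` (one row per recording), `windows.csv`,
#' `stats.csv`, `pvalue_heatmap.csv` and `run_log.txt` (package version,
#' config echo, skipped recordings). Recordings that fail validation or
#' segmentation are skipped with the reason logged; the run fails only if no
#' recording is usable.
#'
#' @param recordings Either a list of [reach_recording()] objects, or a
#'   manifest data.frame with columns `path`, `subject`, `group`, `trial`
#'   naming delimited text files readable by [read_recording()].
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param dry_run Validate inputs and config, write nothing (default
#'   `FALSE`).
#' @return Invisibly, a list with `features`, `averaged`, `windows`,
#'   `results`, `heatmap`, `skipped`.
#' @export
run_pipeline <- function(recordings, out_dir, config = run_config(),
                         dry_run = FALSE) {
  if (is.data.frame(recordings)) {
    need <- c("path", "subject", "group", "trial")
    if (!all(need %in% names(recordings)))
      stop("manifest needs columns: ", paste(need, collapse = ", "))
    manifest <- recordings
    loaders <- lapply(seq_len(nrow(manifest)), function(i) {
      function() read_recording(manifest$path[i],
                                subject_id = manifest$subject[i],
                                group = manifest$group[i],
                                trial = manifest$trial[i])
    })
    labels <- manifest$path
  } else {
    loaders <- lapply(recordings, function(r) function() r)
    labels <- vapply(recordings, function(r)
      sprintf("%s/trial%d", r$subject_id, r$trial), character(1))
  }
  feats <- list(); avgs <- list(); winds <- list(); skipped <- list()
  for (i in seq_along(loaders)) {
    res <- tryCatch({
      rec <- loaders[[i]]()
      a <- withCallingHandlers(
        analyze_recording(rec, config),
        warning = function(w) invokeRestart("muffleWarning"))
      av <- average_features(a$features, config$feature_config)
      list(rec = rec, a = a, av = av)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(input = labels[i], reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    feats[[length(feats) + 1L]] <- res$a$features
    winds[[length(winds) + 1L]] <-
      cbind(data.frame(subject = res$rec$subject_id, group = res$rec$group,
                       trial = res$rec$trial, stringsAsFactors = FALSE),
            as.data.frame(res$a$windows))
    avgs[[length(avgs) + 1L]] <-
      cbind(data.frame(subject = res$rec$subject_id, group = res$rec$group,
                       trial = res$rec$trial, stringsAsFactors = FALSE),
            res$av)
  }
  if (!length(feats)) stop("no usable recordings")
  features <- do.call(rbind, feats)
  averaged <- do.call(rbind, avgs)
  windows <- do.call(rbind, winds)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(input = character(0), reason = character(0))
  results <- analyze_feature_table(features, cfg = config$stat_config,
                                   feature_cfg = config$feature_config)
  heatmap <- pvalue_heatmap_table(results, cfg = config$stat_config)
  if (!dry_run) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_csv_fixed(features, file.path(out_dir, "features.csv"), config$digits)
    .write_csv_fixed(averaged, file.path(out_dir, "features_averaged.csv"),
                     config$digits)
    .write_csv_fixed(windows, file.path(out_dir, "windows.csv"), config$digits)
    .write_csv_fixed(as.data.frame(results), file.path(out_dir, "stats.csv"),
                     config$digits)
    utils::write.csv(heatmap, file.path(out_dir, "pvalue_heatmap.csv"),
                     row.names = FALSE, quote = FALSE)
    log_lines <- c(
      sprintf("reachkin %s", as.character(utils::packageVersion("reachkin"))),
      sprintf("recordings: %d processed, %d skipped",
              length(feats), nrow(skipped)),
      if (nrow(skipped))
        sprintf("  skipped %s: %s", skipped$input, skipped$reason),
      "config:",
      paste0("  ", strsplit(yaml::as.yaml(
        unclass(config)[c("fs_target", "filter", "segmentation", "features",
                          "stats", "digits")]), "\n")[[1]]))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(list(features = features, averaged = averaged, windows = windows,
                 results = results, heatmap = heatmap, skipped = skipped))
}
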