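#' Statistical-comparison configuration
#'
#' @param alpha Significance level (default 0.05, two-sided).
#' @param heatmap_bins Two thresholds separating strong / weak /
#'   non-significant p-values (default `c(0.05, 0.10)`).
#' @param bh_correct Apply Benjamini-Hochberg correction across results in
#'   [analyze_feature_table()] (default `FALSE`: each parameter-phase cell is
#'   tested at face value).
#' @param unit Unit of analysis: `"recording"` (default; every trial is one
#'   observation) or `"subject"` (trials averaged per subject first).
#' @return An object of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, heatmap_bins = c(0.05, 0.10),
                        bh_correct = FALSE,
                        unit = c("recording", "subject")) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (length(heatmap_bins) != 2L || any(diff(heatmap_bins) <= 0))
    stop("heatmap_bins must be two increasing thresholds")
  structure(list(alpha = alpha, heatmap_bins = heatmap_bins,
                 bh_correct = isTRUE(bh_correct), unit = match.arg(unit)),
            class = "stat_config")
}

.descriptives <- function(x) {
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       median = stats::median(x), iqr = stats::IQR(x))
}

#' Normality-routed two-group comparison
#'
#' Implements the test-selection policy for small unpaired samples:
#' Shapiro-Wilk on each group; if both pass at `alpha`, Levene's test
#' (classic, mean-centred) decides between Student's t (homoscedastic) and
#' Welch's t; if either group fails normality — or is degenerate (zero
#' variance), where Shapiro-Wilk is undefined — the Mann-Whitney U test is
#' used, exact when both groups have at most 20 observations and there are
#' no ties, otherwise the normal approximation with continuity and tie
#' correction. All p-values are two-sided.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3.
#' @param cfg A [stat_config()].
#' @param force_test Optional override of the routing: one of
#'   `"student_t"`, `"welch_t"`, `"mann_whitney"` (used for calibration
#'   checks; routing fields are still reported).
#' @return An object of class `stat_result`: list with per-group
#'   descriptives (`a`, `b`), `normality_p` (length 2), `levene_p` (or `NA`),
#'   `test_used`, `statistic`, `p_value`, `significant`.
#' @export
route_and_test <- function(group_a, group_b, cfg = stat_config(),
                           force_test = NULL) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs at least 3 observations")
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  norm_p <- c(a = shapiro_p(group_a), b = shapiro_p(group_b))
  degenerate <- anyNA(norm_p)
  if (degenerate)
    warning("zero-variance group: normality undefined, using Mann-Whitney U")
  both_normal <- !degenerate && all(norm_p > cfg$alpha)
  levene_p <- NA_real_
  if (both_normal) {
    vals <- c(group_a, group_b)
    grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
    levene_p <- car::leveneTest(vals, grp, center = "mean")[1, "Pr(>F)"]
  }
  test_used <- if (!is.null(force_test)) {
    match.arg(force_test, c("student_t", "welch_t", "mann_whitney"))
  } else if (both_normal) {
    if (levene_p > cfg$alpha) "student_t" else "welch_t"
  } else {
    "mann_whitney"
  }
  res <- switch(test_used,
    student_t = stats::t.test(group_a, group_b, var.equal = TRUE),
    welch_t = stats::t.test(group_a, group_b, var.equal = FALSE),
    mann_whitney = {
      exact <- length(group_a) <= 20L && length(group_b) <= 20L &&
        !any(duplicated(c(group_a, group_b)))
      suppressWarnings(
        stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
    })
  structure(list(a = .descriptives(group_a), b = .descriptives(group_b),
                 normality_p = norm_p, levene_p = levene_p,
                 test_used = test_used,
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 significant = res$p.value < cfg$alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g%s\n",
              x$test_used, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

.stat_result_row <- function(parameter, phase, r) {
  data.frame(parameter = parameter, phase = phase,
             n_a = r$a$n, mean_a = r$a$mean, sd_a = r$a$sd,
             median_a = r$a$median, iqr_a = r$a$iqr,
             n_b = r$b$n, mean_b = r$b$mean, sd_b = r$b$sd,
             median_b = r$b$median, iqr_b = r$b$iqr,
             normality_p_a = unname(r$normality_p["a"]),
             normality_p_b = unname(r$normality_p["b"]),
             levene_p = r$levene_p, test_used = r$test_used,
             statistic = r$statistic, p_value = r$p_value,
             significant = r$significant, stringsAsFactors = FALSE)
}

#' Group comparison of every parameter, per submovement and averaged
#'
#' For each of the thirteen kinematic parameters, compares the two groups on
#' every submovement phase present in the table and on the per-recording
#' averages across phases (the averaged comparison uses recordings with at
#' least `min_phases` phases; see [average_features()]). Group "a" is
#' `"healthy"` and group "b" `"parkinson"` when those labels are present;
#' otherwise the first level in sort order is "a".
#'
#' @param features Tidy feature table: columns `subject`, `group`, `trial`,
#'   `phase_id` and the thirteen parameter columns (one row per submovement;
#'   see [extract_features()] / [run_pipeline()]).
#' @param cfg A [stat_config()].
#' @param feature_cfg A [feature_config()] (for `min_phases`).
#' @return Data.frame of class `stat_results`, one row per parameter x phase
#'   plus one per parameter with `phase = "averaged"`; columns as in
#'   `.stat_result_row` (descriptives, routing p-values, test, p, flag).
#' @export
analyze_feature_table <- function(features, cfg = stat_config(),
                                  feature_cfg = feature_config()) {
  params <- intersect(kinematic_parameters(), names(features))
  skipped <- setdiff(kinematic_parameters(), params)
  if (length(skipped))
    warning("missing parameter column(s) skipped: ",
            paste(skipped, collapse = ", "))
  if (!all(c("subject", "group", "trial", "phase_id") %in% names(features)))
    stop("features table needs subject, group, trial, phase_id columns")
  groups <- sort(unique(as.character(features$group)))
  if (length(groups) != 2L)
    stop("features table must contain exactly two groups, found: ",
         paste(groups, collapse = ", "))
  if (all(c("healthy", "parkinson") %in% groups))
    groups <- c("healthy", "parkinson")

  pull <- function(df, param) {
    # one observation per unit of analysis
    key <- if (cfg$unit == "subject") df$subject
           else interaction(df$subject, df$trial, drop = TRUE)
    as.numeric(tapply(df[[param]], key, mean))
  }
  phases <- sort(unique(features$phase_id))
  out <- list()
  for (param in params) {
    for (ph in phases) {
      sub <- features[features$phase_id == ph, ]
      r <- route_and_test(pull(sub[sub$group == groups[1], ], param),
                          pull(sub[sub$group == groups[2], ], param), cfg)
      out[[length(out) + 1L]] <- .stat_result_row(param, as.character(ph), r)
    }
  }
  # averaged across phases, per recording (Eq.-style mean over submovements)
  rec_key <- interaction(features$subject, features$trial, drop = TRUE)
  avg_rows <- lapply(split(features, rec_key), function(df) {
    if (nrow(df) < feature_cfg$min_phases) return(NULL)
    row <- as.data.frame(lapply(df[params], mean))
    row$subject <- df$subject[1]; row$group <- df$group[1]
    row$trial <- df$trial[1]
    row
  })
  avg <- do.call(rbind, avg_rows)
  for (param in params) {
    r <- route_and_test(pull(avg[avg$group == groups[1], ], param),
                        pull(avg[avg$group == groups[2], ], param), cfg)
    out[[length(out) + 1L]] <- .stat_result_row(param, "averaged", r)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (cfg$bh_correct) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjusted < cfg$alpha
  }
  attr(res, "groups") <- groups
  class(res) <- c("stat_results", "data.frame")
  res
}

#' Bin p-values into a heatmap table
#'
#' Reduces the results of [analyze_feature_table()] to a parameter x phase
#' table of significance bins: `"strong"` for p below the first threshold
#' (default 0.05), `"weak"` between the thresholds (default up to 0.10),
#' `"ns"` otherwise.
#'
#' @param results A `stat_results` data.frame.
#' @param cfg A [stat_config()].
#' @return Data.frame with one row per parameter, one column per phase (plus
#'   `averaged` if present), entries in `c("strong", "weak", "ns")`.
#' @export
pvalue_heatmap_table <- function(results, cfg = stat_config()) {
  bin <- function(p) {
    ifelse(p < cfg$heatmap_bins[1], "strong",
           ifelse(p < cfg$heatmap_bins[2], "weak", "ns"))
  }
  params <- unique(results$parameter)
  phases <- unique(results$phase)
  mat <- matrix(NA_character_, nrow = length(params), ncol = length(phases),
                dimnames = list(params, phases))
  for (i in seq_len(nrow(results)))
    mat[results$parameter[i], results$phase[i]] <- bin(results$p_value[i])
  out <- data.frame(parameter = params, mat, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Plot the p-value heatmap
#'
#' Tile plot of the significance bins (green = strong, yellow = weak,
#' red = non-significant). Requires ggplot2.
#'
#' @param results A `stat_results` data.frame.
#' @param cfg A [stat_config()].
#' @return A ggplot object.
#' @export
plot_pvalue_heatmap <- function(results, cfg = stat_config()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab <- pvalue_heatmap_table(results, cfg)
  long <- do.call(rbind, lapply(setdiff(names(tab), "parameter"), function(ph)
    data.frame(parameter = tab$parameter, phase = ph, bin = tab[[ph]])))
  long$parameter <- factor(long$parameter, levels = rev(kinematic_parameters()))
  long$phase <- factor(long$phase, levels = unique(long$phase))
  ggplot2::ggplot(long, ggplot2::aes(x = phase, y = parameter, fill = bin)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(strong = "#2e7d32",
                                          weak = "#f9a825",
                                          ns = "#c62828"), name = NULL) +
    ggplot2::labs(x = "submovement", y = NULL) +
    ggplot2::theme_minimal()
}
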