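#' Run the full motif rhythm analysis
#'
#' The central entry point: takes a motif annotation table, builds the
#' analysis units (tutor motifs whole; tutee motifs as everything /
#' all-shared / part-shared / not-shared subsets), computes the rhythm
#' metrics for every unit, runs the pairwise Welch comparisons with
#' Bonferroni correction and Cohen's d, the per-nest tutor-tutee beat
#' correlation, and the parameter-vs-length correlations.
#'
#' @param motifs motif table (see [validate_motifs()]) or a path to a motif
#'   CSV file.
#' @param min_intervals minimum IOIs per analysis unit (default 3).
#' @param match_mode shared-run matching relation, see [extract_shared_run()].
#' @param family Bonferroni family, see [welch_comparisons()].
#' @param tutee_subset tutee subset used for the nest-level beat
#'   correlation (default `"EVERYTHING"`).
#' @param adjust_cv apply the small-sample CV correction.
#' @return Object of class `rhythm_analysis` with components `units`,
#'   `metrics`, `comparisons`, `nest_correlation` (`NULL` when fewer than
#'   three nests have both roles), `length_correlations`, `histogram`
#'   (overall binned IOI distribution) and `config`. Has `print()`,
#'   `summary()` and `plot()` methods.
#' @examples
#' corpus <- generate_corpus(generator_config(n_nests = 4, seed = 1))
#' fit <- rhythm_analysis(corpus$motifs)
#' fit
#' @export
rhythm_analysis <- function(motifs, min_intervals = 3,
                            match_mode = c("subsequence", "substring"),
                            family = c("per_parameter", "global"),
                            tutee_subset = "EVERYTHING",
                            adjust_cv = TRUE) {
  match_mode <- match.arg(match_mode)
  family <- match.arg(family)
  if (is.character(motifs) && length(motifs) == 1L) {
    motifs <- read_motifs(motifs)
  }
  motifs <- validate_motifs(motifs)
  units <- build_analysis_units(motifs, min_intervals = min_intervals,
                                match_mode = match_mode)
  metrics <- summarize_units(units, adjust_cv = adjust_cv)
  comparisons <- tryCatch(welch_comparisons(metrics, family = family),
                          mr_insufficient_data = function(e) NULL)
  nest_corr <- tryCatch(
    nest_beat_correlation(metrics, tutee_subset = tutee_subset),
    mr_insufficient_data = function(e) NULL)
  len_corr <- tryCatch(length_correlations(metrics),
                       mr_insufficient_data = function(e) NULL,
                       mr_validation_error = function(e) NULL)
  histogram <- tryCatch(ioi_histogram(units, by = "overall"),
                        mr_insufficient_data = function(e) NULL)
  structure(list(units = units, metrics = metrics,
                 comparisons = comparisons, nest_correlation = nest_corr,
                 length_correlations = len_corr, histogram = histogram,
                 config = list(min_intervals = min_intervals,
                               match_mode = match_mode, family = family,
                               tutee_subset = tutee_subset,
                               adjust_cv = adjust_cv)),
            class = "rhythm_analysis")
}

#' @export
print.rhythm_analysis <- function(x, ...) {
  cat("Motif rhythm analysis\n")
  counts <- table(x$units$subset_kind)
  cat("  analysis units:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  all_iois <- unlist(x$units$iois[x$units$subset_kind %in%
                                    c("TUTOR", "EVERYTHING")])
  cat(sprintf("  intervals (tutor + everything): n = %d, range %.3f-%.3f s, mean %.3f s\n",
              length(all_iois), min(all_iois), max(all_iois), mean(all_iois)))
  beats <- x$metrics$ioi_beat_hz
  cat(sprintf("  IOI beat: mean %.1f Hz (sd %.1f), range %.1f-%.1f Hz\n",
              mean(beats), stats::sd(beats), min(beats), max(beats)))
  cat(sprintf("  adjusted CV: mean %.2f (sd %.2f)\n",
              mean(x$metrics$cv_adj), stats::sd(x$metrics$cv_adj)))
  if (!is.null(x$nest_correlation)) {
    cat(sprintf("  nest-level tutor-tutee beat correlation: r = %.2f (p = %.2g, %d nests)\n",
                x$nest_correlation$r, x$nest_correlation$p,
                x$nest_correlation$n_nests))
  }
  invisible(x)
}

#' @export
summary.rhythm_analysis <- function(object, ...) {
  structure(list(analysis = object), class = "summary.rhythm_analysis")
}

#' @export
print.summary.rhythm_analysis <- function(x, ...) {
  a <- x$analysis
  print(a)
  if (!is.null(a$comparisons)) {
    cat("\nPairwise Welch comparisons (Bonferroni-adjusted):\n")
    cmp <- a$comparisons
    cmp$p_adj <- signif(cmp$p_adj, 3)
    cmp$cohens_d <- round(cmp$cohens_d, 2)
    print(cmp[, c("parameter", "group_a", "group_b", "n_a", "n_b",
                  "t_stat", "p_adj", "cohens_d")], row.names = FALSE,
          digits = 3)
  }
  if (!is.null(a$length_correlations)) {
    cat("\nParameter vs sequence length (Pearson):\n")
    print(a$length_correlations, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot a rhythm analysis
#'
#' Three descriptive panels: the overall IOI distribution by role, the
#' per-nest tutor vs tutee mean beat scatter with the identity line, and
#' per-group boxplots of the chosen parameter.
#'
#' @param x a `rhythm_analysis` object.
#' @param which subset of panels, any of `"histogram"`, `"beats"`,
#'   `"groups"`.
#' @param parameter parameter for the group boxplots.
#' @param ... ignored.
#' @export
plot.rhythm_analysis <- function(x, which = c("histogram", "beats", "groups"),
                                 parameter = "npvi", ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if ("histogram" %in% which && !is.null(x$histogram)) {
    h <- x$histogram
    plot(NA, xlim = range(c(h$bin_left_s, h$bin_right_s)),
         ylim = c(0, max(h$percent)), xlab = "IOI (s)", ylab = "% of IOIs",
         main = "IOI distribution")
    for (r in unique(h$role)) {
      hr <- h[h$role == r, ]
      graphics::lines(hr$bin_left_s + diff(c(hr$bin_left_s[1], hr$bin_right_s[1])) / 2,
                      hr$percent, type = "s",
                      col = if (r == "tutor") "darkred" else "darkgreen")
    }
    graphics::legend("topright", legend = c("tutor", "tutee"),
                     col = c("darkred", "darkgreen"), lty = 1, bty = "n")
  }
  if ("beats" %in% which && !is.null(x$nest_correlation)) {
    p <- x$nest_correlation$points
    lim <- range(c(p$tutor_mean, p$tutee_mean))
    plot(p$tutor_mean, p$tutee_mean, xlim = lim, ylim = lim,
         xlab = "tutor mean IOI beat (Hz)", ylab = "tutee mean IOI beat (Hz)",
         main = sprintf("Per-nest beats (r = %.2f)", x$nest_correlation$r),
         pch = 4)
    graphics::abline(0, 1, lty = 3, col = "grey40")
  }
  if ("groups" %in% which) {
    graphics::boxplot(x$metrics[[parameter]] ~ x$metrics$subset_kind,
                      xlab = "", ylab = parameter,
                      main = paste(parameter, "by group"), las = 2)
  }
  invisible(x)
}

#' Run the end-to-end pipeline and write the report bundle
#'
#' Orchestrates import, unit extraction, metrics, comparisons, correlations
#' and the null simulation, writing `units.csv`, `metrics.csv`,
#' `comparisons.csv`, `correlations.csv`, `nullsim.csv`, `summary.json` and
#' (optionally) `plots.pdf` into `out_dir`. Numeric CSV columns are written
#' with six decimals and deterministic row order, so two runs with the same
#' seed and config produce byte-identical CSVs. The null simulation draws
#' its interval pool from the extracted units and is seeded with `seed`.
#'
#' @param motifs motif table or path to a motif CSV.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the null simulation, recorded in
#'   `summary.json`.
#' @param nullsim_n,nullsim_elements null-simulation size and element
#'   bounds (defaults 1000 sequences of 4–22 elements).
#' @param plots also write `plots.pdf`.
#' @param ... passed to [rhythm_analysis()].
#' @return Invisibly, a list with the `rhythm_analysis` object, the
#'   `null_simulation` object and the written file paths.
#' @export
run_pipeline <- function(motifs, out_dir, seed = 1, nullsim_n = 1000,
                         nullsim_elements = c(4, 22), plots = FALSE, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  analysis <- rhythm_analysis(motifs, ...)
  # interval pool = the dataset's whole motifs (tutor + everything); the
  # shared/not-shared subsets would double-count their intervals
  pool <- unlist(analysis$units$iois[analysis$units$subset_kind %in%
                                       c("TUTOR", "EVERYTHING")])
  nullsim <- run_null_simulation(pool, n_sequences = nullsim_n,
                                 min_elements = nullsim_elements[1],
                                 max_elements = nullsim_elements[2],
                                 seed = seed)
  paths <- c(units = file.path(out_dir, "units.csv"),
             metrics = file.path(out_dir, "metrics.csv"),
             comparisons = file.path(out_dir, "comparisons.csv"),
             correlations = file.path(out_dir, "correlations.csv"),
             nullsim = file.path(out_dir, "nullsim.csv"),
             summary = file.path(out_dir, "summary.json"))

  write_units(analysis$units, paths["units"])
  write_csv6 (analysis$metrics, paths["metrics"])
  if (!is.null(analysis$comparisons)) {
    write_csv6(analysis$comparisons, paths["comparisons"])
  }
  corr <- rbind(
    if (!is.null(analysis$length_correlations))
      cbind(kind = "parameter_vs_length", analysis$length_correlations),
    if (!is.null(nullsim$correlations))
      cbind(kind = "nullsim_vs_length", nullsim$correlations))
  if (!is.null(corr)) write_csv6(corr, paths["correlations"])
  write_csv6(nullsim$metrics, paths["nullsim"])

  counts <- as.list(table(analysis$units$subset_kind))
  beat_points <- if (!is.null(analysis$nest_correlation)) {
    analysis$nest_correlation$points
  } else {
    NULL
  }
  summary_obj <- list(
    seed = seed,
    config = analysis$config,
    unit_counts = counts,
    n_intervals = length(pool),
    per_nest_beats = beat_points,
    nest_beat_correlation = if (!is.null(analysis$nest_correlation)) {
      list(r = analysis$nest_correlation$r, p = analysis$nest_correlation$p,
           n_nests = analysis$nest_correlation$n_nests)
    },
    length_correlations = analysis$length_correlations,
    nullsim_correlations = nullsim$correlations)
  jsonlite::write_json(summary_obj, paths["summary"], auto_unbox = TRUE,
                       digits = NA, null = "null")

  if (plots) {
    pdf_path <- file.path(out_dir, "plots.pdf")
    grDevices::pdf(pdf_path, width = 10, height = 4)
    plot(analysis)
    grDevices::dev.off()
    paths <- c(paths, plots = pdf_path)
  }
  invisible(list(analysis = analysis, nullsim = nullsim, paths = paths))
}

# CSV writer with numeric columns fixed to 6 decimals for bit-stable output.
write_csv6 <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- ifelse(is.finite(out[[nm]]),
                          sprintf("%.6f", out[[nm]]),
                          as.character(out[[nm]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
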