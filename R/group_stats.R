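#' Pairwise group comparisons of rhythm parameters
#'
#' Welch's unequal-variance t test for every unordered pair of subset kinds
#' present in the metrics table, for each rhythm parameter, with Bonferroni
#' correction and Cohen's d (pooled standard deviation). Groups are ordered
#' TUTOR < EVERYTHING < ALL_SHARED < PART_SHARED < NOT_SHARED, and the signs
#' of t and d follow `mean(group_a) - mean(group_b)` with `group_a` the
#' earlier group. Analysis units (sequences), not birds, are the observation
#' unit, matching the descriptive design of the study; use
#' `aggregate_by_bird = TRUE` for a per-bird-mean sensitivity analysis.
#'
#' The Bonferroni family is, by default, the set of pairs tested within one
#' parameter (`family = "per_parameter"`, e.g. 10 pairs for five groups);
#' `family = "global"` corrects across the parameters as well.
#'
#' @param metrics metrics table from [summarize_units()].
#' @param parameters which parameter columns to test.
#' @param family Bonferroni family, `"per_parameter"` or `"global"`.
#' @param aggregate_by_bird average units within each bird first.
#' @return data.frame with one row per (parameter, pair): `parameter`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t_stat`, `df`,
#'   `p_raw`, `p_adj`, `cohens_d`. Pairs where a group has fewer than two
#'   units are skipped and listed in the `"skipped"` attribute.
#' @export
welch_comparisons <- function(metrics,
                              parameters = RHYTHM_PARAMETERS,
                              family = c("per_parameter", "global"),
                              aggregate_by_bird = FALSE) {
  family <- match.arg(family)
  if (aggregate_by_bird) {
    metrics <- aggregate_metrics_by_bird(metrics, parameters)
  }
  groups <- SUBSET_LEVELS[SUBSET_LEVELS %in% unique(as.character(metrics$subset_kind))]
  if (length(groups) < 2L) {
    mr_stop("need at least two groups with data", "mr_insufficient_data")
  }
  pairs <- utils::combn(groups, 2L)
  kind <- as.character(metrics$subset_kind)
  acc <- list(parameter = character(0), group_a = character(0),
              group_b = character(0), n_a = integer(0), n_b = integer(0),
              mean_a = numeric(0), mean_b = numeric(0), t_stat = numeric(0),
              df = numeric(0), p_raw = numeric(0), cohens_d = numeric(0))
  skipped <- list()
  for (param in parameters) {
    vals <- split(metrics[[param]], kind)
    for (j in seq_len(ncol(pairs))) {
      ga <- pairs[1, j]; gb <- pairs[2, j]
      a <- vals[[ga]]; b <- vals[[gb]]
      if (length(a) < 2L || length(b) < 2L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          parameter = param, group_a = ga, group_b = gb,
          reason = "group with fewer than 2 units", stringsAsFactors = FALSE)
        next
      }
      wt <- welch_t(a, b)
      acc$parameter <- c(acc$parameter, param)
      acc$group_a <- c(acc$group_a, ga); acc$group_b <- c(acc$group_b, gb)
      acc$n_a <- c(acc$n_a, length(a)); acc$n_b <- c(acc$n_b, length(b))
      acc$mean_a <- c(acc$mean_a, mean(a)); acc$mean_b <- c(acc$mean_b, mean(b))
      acc$t_stat <- c(acc$t_stat, wt$t); acc$df <- c(acc$df, wt$df)
      acc$p_raw <- c(acc$p_raw, wt$p)
      acc$cohens_d <- c(acc$cohens_d, cohens_d(a, b))
    }
  }
  if (!length(acc$parameter)) {
    mr_stop("no testable group pair", "mr_insufficient_data")
  }
  out <- data.frame(acc, stringsAsFactors = FALSE)
  out$p_adj <- NA_real_
  if (family == "global") {
    out$p_adj <- pmin(1, out$p_raw * nrow(out))
  } else {
    for (param in unique(out$parameter)) {
      sel <- out$parameter == param
      out$p_adj[sel] <- pmin(1, out$p_raw[sel] * sum(sel))
    }
  }
  out <- out[, c("parameter", "group_a", "group_b", "n_a", "n_b",
                 "mean_a", "mean_b", "t_stat", "df", "p_raw", "p_adj",
                 "cohens_d")]
  rownames(out) <- NULL
  if (length(skipped)) attr(out, "skipped") <- do.call(rbind, skipped)
  out
}

# Welch's t with the degenerate zero-variance cases handled explicitly
# (stats::t.test refuses essentially-constant data).
welch_t <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Cohen's d with pooled standard deviation
#'
#' Effect size `(mean(a) - mean(b)) / s_pooled` with
#' `s_pooled^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)`.
#' Zero when both groups are constant with equal means.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return A single number.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    mr_stop("cohens_d needs at least 2 observations per group",
            "mr_insufficient_data")
  }
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 0 else sign(delta) * Inf)
  }
  delta / sqrt(sp2)
}

aggregate_metrics_by_bird <- function(metrics, parameters) {
  agg <- stats::aggregate(metrics[parameters],
                          by = list(nest_id = metrics$nest_id,
                                    bird_id = metrics$bird_id,
                                    subset_kind = metrics$subset_kind),
                          FUN = mean)
  agg$subset_kind <- factor(agg$subset_kind, levels = SUBSET_LEVELS)
  agg
}

#' Per-nest tutor vs tutee beat correlation
#'
#' For every nest, the tutor's mean over its TUTOR units is paired with the
#' mean over the nest's tutee units of the requested subset; Pearson's
#' correlation is computed over the nests (one point per nest, two-sided
#' test).
#'
#' @param metrics metrics table from [summarize_units()].
#' @param tutee_subset which tutee subset supplies the tutee means
#'   (default `"EVERYTHING"`, the whole motif).
#' @param parameter rhythm parameter column (default `"ioi_beat_hz"`).
#' @return An object of class `nest_correlation`: list with `parameter`,
#'   `tutee_subset`, `points` (data.frame `nest_id`, `tutor_mean`,
#'   `tutee_mean`), `r`, `p`, `n_nests`.
#' @export
nest_beat_correlation <- function(metrics, tutee_subset = "EVERYTHING",
                                  parameter = "ioi_beat_hz") {
  stopifnot(parameter %in% names(metrics))
  tut <- metrics[metrics$subset_kind == "TUTOR", , drop = FALSE]
  pup <- metrics[metrics$subset_kind == tutee_subset &
                   metrics$role == "tutee", , drop = FALSE]
  tutor_means <- tapply(tut[[parameter]], tut$nest_id, mean)
  tutee_means <- tapply(pup[[parameter]], pup$nest_id, mean)
  nests <- intersect(names(tutor_means), names(tutee_means))
  if (length(nests) < 3L) {
    mr_stop("need at least 3 nests with both a tutor and tutee units",
            "mr_insufficient_data")
  }
  points <- data.frame(nest_id = nests,
                       tutor_mean = as.numeric(tutor_means[nests]),
                       tutee_mean = as.numeric(tutee_means[nests]),
                       stringsAsFactors = FALSE)
  ct <- stats::cor.test(points$tutor_mean, points$tutee_mean,
                        method = "pearson", alternative = "two.sided")
  structure(list(parameter = parameter, tutee_subset = tutee_subset,
                 points = points, r = unname(ct$estimate), p = ct$p.value,
                 n_nests = length(nests)),
            class = "nest_correlation")
}

#' @export
print.nest_correlation <- function(x, ...) {
  cat("Per-nest tutor-tutee correlation (", x$parameter, ", tutee subset ",
      x$tutee_subset, ")\n", sep = "")
  cat(sprintf("  r = %.3f, p = %.3g over %d nests\n", x$r, x$p, x$n_nests))
  invisible(x)
}

#' Correlation of rhythm parameters with sequence length
#'
#' Pearson correlation (two-sided) of each rhythm parameter against the
#' number of elements in the analysis unit, across all units of the table.
#'
#' @param metrics metrics table (>= 3 rows, non-constant `n_elements`).
#' @param parameters parameter columns to correlate.
#' @return data.frame with `parameter`, `r`, `p`, `n`.
#' @export
length_correlations <- function(metrics, parameters = RHYTHM_PARAMETERS) {
  if (nrow(metrics) < 3L) {
    mr_stop("need at least 3 units", "mr_insufficient_data")
  }
  if (stats::sd(metrics$n_elements) == 0) {
    mr_stop("n_elements is constant; correlation undefined",
            "mr_validation_error")
  }
  rows <- lapply(parameters, function(param) {
    ct <- stats::cor.test(metrics[[param]], metrics$n_elements,
                          method = "pearson")
    data.frame(parameter = param, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(metrics), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
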