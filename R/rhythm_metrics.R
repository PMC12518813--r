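#' Rhythm parameters of an IOI sequence
#'
#' The three parameters of the analysis, computed on a sequence of
#' inter-onset intervals \eqn{d_1, \dots, d_m} (seconds, all positive):
#'
#' * **IOI beat** (Hz): \eqn{1 / \bar d} — the rate of the best-fitting
#'   metronome under the mean-interval model.
#' * **Adjusted CV** (dimensionless): the coefficient of variation
#'   \eqn{s_d / \bar d} (sample standard deviation, denominator \eqn{m-1})
#'   multiplied by the small-sample correction \eqn{1 + 1/(4m)}; set
#'   `adjust = FALSE` for the raw CV.
#' * **nPVI** (dimensionless): the normalized pairwise variability index
#'   \deqn{\frac{100}{m-1} \sum_{k=1}^{m-1}
#'         \frac{|d_k - d_{k+1}|}{(d_k + d_{k+1})/2},}
#'   0 for a perfectly isochronous sequence, larger for locally more
#'   variable timing, always below 200.
#'
#' CV and nPVI are scale invariant; the beat scales as \eqn{1/c} when all
#' intervals are multiplied by \eqn{c}. The beat and CV are invariant under
#' permutation of the intervals, the nPVI in general is not.
#'
#' @param iois numeric vector of intervals in seconds, all > 0; the beat
#'   needs at least one interval, CV and nPVI at least two.
#' @param adjust apply the small-sample correction factor (default TRUE).
#' @return A single number.
#' @examples
#' compute_ioi_beat(c(0.05, 0.06, 0.07))  # 1 / 0.06
#' compute_npvi(c(0.1, 0.2))              # 66.67
#' compute_cv_adj(c(0.1, 0.2))
#' @export
compute_ioi_beat <- function(iois) {
  check_iois(iois, min_m = 1L)
  1 / mean(iois)
}

#' @rdname compute_ioi_beat
#' @export
compute_cv_adj <- function(iois, adjust = TRUE) {
  check_iois(iois, min_m = 2L)
  m <- length(iois)
  cv <- stats::sd(iois) / mean(iois)
  if (adjust) cv <- (1 + 1 / (4 * m)) * cv
  cv
}

#' @rdname compute_ioi_beat
#' @export
compute_npvi <- function(iois) {
  check_iois(iois, min_m = 2L)
  m <- length(iois)
  a <- iois[-m]
  b <- iois[-1]
  100 / (m - 1) * sum(abs(a - b) / ((a + b) / 2))
}

check_iois <- function(iois, min_m) {
  if (!is.numeric(iois) || length(iois) < min_m) {
    mr_stop(sprintf("need at least %d interval(s)", min_m),
            "mr_insufficient_data")
  }
  if (any(!is.finite(iois)) || any(iois <= 0)) {
    mr_stop("intervals must be finite and positive", "mr_validation_error")
  }
  invisible(NULL)
}

#' Rhythm metrics for a table of analysis units
#'
#' Computes IOI beat, adjusted CV and nPVI for every unit. Units with fewer
#' than two intervals cannot carry CV/nPVI and are skipped, with a record in
#' the `"skipped"` attribute (never dropped silently).
#'
#' @param units units table from [build_analysis_units()] or [read_units()].
#' @param adjust_cv apply the small-sample CV correction (default TRUE).
#' @return data.frame with one row per unit: `nest_id`, `bird_id`, `role`,
#'   `motif_id`, `subset_kind`, `n_elements`, `n_iois`, `mean_ioi_s`,
#'   `ioi_beat_hz`, `cv_adj`, `npvi`, in the input's (deterministic) order.
#' @export
summarize_units <- function(units, adjust_cv = TRUE) {
  keep <- units$n_iois >= 2L
  skipped <- units[!keep, setdiff(names(units), "iois"), drop = FALSE]
  u <- units[keep, , drop = FALSE]
  out <- data.frame(
    nest_id = u$nest_id, bird_id = u$bird_id, role = u$role,
    motif_id = u$motif_id, subset_kind = u$subset_kind,
    n_elements = u$n_elements, n_iois = u$n_iois,
    mean_ioi_s = vapply(u$iois, mean, numeric(1)),
    ioi_beat_hz = vapply(u$iois, compute_ioi_beat, numeric(1)),
    cv_adj = vapply(u$iois, compute_cv_adj, numeric(1), adjust = adjust_cv),
    npvi = vapply(u$iois, compute_npvi, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(skipped)) {
    message(nrow(skipped), " unit(s) skipped: fewer than 2 intervals")
    attr(out, "skipped") <- skipped
  }
  out
}

#' Binned IOI distribution
#'
#' Histogram of interval durations, following the two normalisation
#' conventions of the study's distribution figure: for `by = "overall"` the
#' percentages sum to 100 within each role (tutors and tutees each form a
#' full distribution); for `by = "nest"` the percentages of one nest's panel
#' — tutor and tutee bars combined — sum to 100.
#'
#' @param units units table with an `iois` list column.
#' @param by `"overall"` or `"nest"`.
#' @param bin_width_s bin width in seconds (default 0.01, matching the
#'   0.009–0.29 s range of observed intervals).
#' @return data.frame with `role`, `bin_left_s`, `bin_right_s`, `n`,
#'   `percent` (plus `nest_id` for `by = "nest"`).
#' @export
ioi_histogram <- function(units, by = c("overall", "nest"), bin_width_s = 0.01) {
  by <- match.arg(by)
  if (!is.numeric(bin_width_s) || bin_width_s <= 0) {
    mr_stop("bin_width_s must be positive", "mr_validation_error")
  }
  if (!nrow(units) || !length(unlist(units$iois))) {
    mr_stop("no intervals to bin", "mr_insufficient_data")
  }
  role <- ifelse(units$subset_kind == "TUTOR", "tutor", "tutee")
  flat <- data.frame(
    nest_id = rep(units$nest_id, lengths(units$iois)),
    role = rep(role, lengths(units$iois)),
    ioi = unlist(units$iois), stringsAsFactors = FALSE)
  flat$bin <- floor(flat$ioi / bin_width_s)
  tab <- if (by == "overall") {
    stats::aggregate(cbind(n = ioi) ~ role + bin, data = flat, FUN = length)
  } else {
    stats::aggregate(cbind(n = ioi) ~ nest_id + role + bin, data = flat, FUN = length)
  }
  group <- if (by == "overall") tab$role else tab$nest_id
  totals <- tapply(tab$n, group, sum)
  tab$percent <- 100 * tab$n / as.numeric(totals[as.character(group)])
  tab$bin_left_s <- tab$bin * bin_width_s
  tab$bin_right_s <- (tab$bin + 1) * bin_width_s
  tab$bin <- NULL
  ord <- if (by == "overall") order(tab$role, tab$bin_left_s) else
    order(tab$nest_id, tab$role, tab$bin_left_s)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
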