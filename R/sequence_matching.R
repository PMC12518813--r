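#' Mark tutee elements shared with the tutor
#'
#' An element of a tutee motif is *shared* when its label occurs anywhere in
#' the tutor's element-label sequence (set semantics); annotators give tutee
#' elements the same letter as the tutor element they resemble, and new
#' letters to improvised material, so label membership encodes similarity.
#'
#' @param tutee_labels character vector of tutee element labels.
#' @param tutor_labels character vector of tutor element labels (non-empty).
#' @return Logical vector of the same length as `tutee_labels`.
#' @examples
#' mark_shared(c("A", "B", "C", "X", "Y"), c("A", "B", "C", "D", "E"))
#' @export
mark_shared <- function(tutee_labels, tutor_labels) {
  if (!length(tutor_labels)) {
    mr_stop("tutor label sequence is empty", "mr_validation_error")
  }
  tutee_labels %in% tutor_labels
}

#' Extract the beginning-anchored shared run of a tutee motif
#'
#' Finds the maximal run of elements starting at the tutee motif's first
#' element that follows the tutor's label sequence in order, and classifies
#' it as `ALL_SHARED` (the run reproduces the tutor's complete sequence;
#' the tutee may append extra elements afterwards, which are not part of the
#' run) or `PART_SHARED` (an incomplete beginning snippet that follows the
#' tutor's order).
#'
#' Two matching relations are available. `"subsequence"` (default) requires
#' the run's labels to appear in the tutor's sequence in the same relative
#' order, using the leftmost feasible tutor position and advancing
#' monotonically — this tolerates a tutee skipping tutor elements.
#' `"substring"` additionally requires consecutive tutor positions.
#'
#' A run qualifies only if it spans at least `min_intervals` inter-onset
#' intervals (i.e. `min_intervals + 1` elements); otherwise `NULL` is
#' returned. Shared runs of qualifying length that do *not* start at the
#' first element are not classified (the study design only defines
#' beginning-anchored snippets); a warning reports their existence.
#'
#' @param tutee_labels,tutor_labels element label vectors.
#' @param min_intervals minimum number of IOIs a unit must span (default 3,
#'   i.e. four elements).
#' @param match_mode `"subsequence"` or `"substring"`.
#' @return `NULL`, or a list with `kind` (`"ALL_SHARED"` or `"PART_SHARED"`),
#'   `start`, `end` (element indices into the tutee motif) and
#'   `tutor_positions` (matched tutor indices).
#' @examples
#' extract_shared_run(c("A","B","C","D","E","F"), c("A","B","C","D","E"))
#' extract_shared_run(c("A","B","C","X","Y"), c("A","B","C","D","E"),
#'                    min_intervals = 2)
#' @export
extract_shared_run <- function(tutee_labels, tutor_labels,
                               min_intervals = 3,
                               match_mode = c("subsequence", "substring")) {
  match_mode <- match.arg(match_mode)
  run <- shared_run_core(tutee_labels, tutor_labels, match_mode)
  warn_interior_shared_runs(tutee_labels, tutor_labels,
                            if (is.null(run)) 0L else run$end, min_intervals)
  if (is.null(run) || run$end - 1L < min_intervals) return(NULL)
  run
}

# Beginning-anchored shared run without the minimum-length filter; NULL when
# the first tutee element already fails to match.
shared_run_core <- function(tutee_labels, tutor_labels, match_mode) {
  if (!length(tutor_labels)) {
    mr_stop("tutor label sequence is empty", "mr_validation_error")
  }
  n_tutor <- length(tutor_labels)
  matched <- integer(0)
  tpos <- 0L
  for (i in seq_along(tutee_labels)) {
    if (match_mode == "subsequence" || tpos == 0L) {
      cand <- which(tutor_labels == tutee_labels[i])
      cand <- cand[cand > tpos]
      nxt <- if (length(cand)) cand[1] else NA_integer_
    } else {
      nxt <- if (tpos < n_tutor && tutor_labels[tpos + 1L] == tutee_labels[i]) {
        tpos + 1L
      } else {
        NA_integer_
      }
    }
    if (is.na(nxt)) break
    tpos <- nxt
    matched <- c(matched, nxt)
  }
  k <- length(matched)
  if (k == 0L) return(NULL)
  kind <- if (identical(matched, seq_len(n_tutor))) "ALL_SHARED" else "PART_SHARED"
  list(kind = kind, start = 1L, end = k, tutor_positions = matched)
}

# The design only classifies beginning-anchored shared snippets; warn when a
# qualifying run of shared labels exists elsewhere in the motif so the
# exclusion is visible, not silent.
warn_interior_shared_runs <- function(tutee_labels, tutor_labels,
                                      anchored_len, min_intervals) {
  shared <- mark_shared(tutee_labels, tutor_labels)
  if (anchored_len > 0L) shared[seq_len(anchored_len)] <- FALSE
  r <- rle(shared)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- r$values & r$lengths >= min_intervals + 1L & starts > 1L
  if (any(qual)) {
    mr_warn(paste0("shared run(s) of qualifying length not anchored at the ",
                   "motif beginning were left unclassified (element indices ",
                   paste(paste0(starts[qual], "-", ends[qual]), collapse = ", "),
                   ")"),
            "mr_unanchored_run_warning")
  }
  invisible(NULL)
}

#' Extract not-shared runs of a tutee motif
#'
#' Returns all maximal contiguous runs of elements whose labels do not occur
#' in the tutor's sequence and that span at least `min_intervals` IOIs.
#' Several such runs can exist in one motif; they are pairwise disjoint by
#' construction.
#'
#' @inheritParams extract_shared_run
#' @return data.frame with columns `start`, `end` (element indices); zero
#'   rows when no qualifying run exists.
#' @examples
#' extract_not_shared_runs(strsplit("ABCXYZWABCQRS", "")[[1]],
#'                         c("A", "B", "C"), min_intervals = 2)
#' @export
extract_not_shared_runs <- function(tutee_labels, tutor_labels,
                                    min_intervals = 3) {
  runs <- not_shared_runs_core(tutee_labels, tutor_labels)
  runs[runs$end - runs$start >= min_intervals, , drop = FALSE]
}

not_shared_runs_core <- function(tutee_labels, tutor_labels) {
  shared <- mark_shared(tutee_labels, tutor_labels)
  r <- rle(!shared)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Build the analysis units of a corpus
#'
#' Expands every motif into the analysis units of the study design: each
#' tutor motif is one `TUTOR` unit (the whole motif); each tutee motif
#' yields one `EVERYTHING` unit (the whole motif), at most one `ALL_SHARED`
#' or `PART_SHARED` unit (the beginning-anchored shared run, see
#' [extract_shared_run()]), and zero or more `NOT_SHARED` units (see
#' [extract_not_shared_runs()]). A unit's IOIs are the differences between
#' the onsets of its consecutive elements; no interval crosses a run
#' boundary. Units spanning fewer than `min_intervals` IOIs are dropped and
#' recorded in the `"exclusions"` attribute.
#'
#' @param motifs motif table covering one or more nests; every nest must
#'   contain exactly one tutor (with at least one motif).
#' @inheritParams extract_shared_run
#' @return data.frame with one row per unit: provenance columns, `role`,
#'   `subset_kind` (factor with levels TUTOR, EVERYTHING, ALL_SHARED,
#'   PART_SHARED, NOT_SHARED), `start_index`, `end_index`, `n_elements`,
#'   `n_iois`, and a list column `iois` of interval vectors (seconds).
#'   Attribute `"exclusions"`: data.frame of skipped candidate units with a
#'   reason.
#' @export
build_analysis_units <- function(motifs, min_intervals = 3,
                                 match_mode = c("subsequence", "substring")) {
  match_mode <- match.arg(match_mode)
  if (min_intervals < 1) {
    mr_stop("min_intervals must be >= 1", "mr_config_error")
  }
  motifs <- validate_motifs(motifs)
  units <- list()
  excl <- list()
  add_unit <- function(m, kind, start, end) {
    n_el <- end - start + 1L
    if (n_el - 1L < min_intervals) {
      excl[[length(excl) + 1L]] <<- data.frame(
        nest_id = m$nest_id[1], bird_id = m$bird_id[1], motif_id = m$motif_id[1],
        subset_kind = kind, n_elements = n_el,
        reason = sprintf("fewer than %d intervals", min_intervals),
        stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    onsets <- m$onset_s[start:end]
    units[[length(units) + 1L]] <<- data.frame(
      nest_id = m$nest_id[1], bird_id = m$bird_id[1], role = m$role[1],
      motif_id = m$motif_id[1], subset_kind = kind,
      start_index = start, end_index = end,
      n_elements = n_el, n_iois = n_el - 1L,
      iois = I(list(diff(onsets))), stringsAsFactors = FALSE)
    invisible(NULL)
  }

  for (nest in split(motifs, motifs$nest_id)) {
    tutor_rows <- nest[nest$role == "tutor", , drop = FALSE]
    if (!nrow(tutor_rows)) {
      mr_stop(paste0("nest ", nest$nest_id[1], " has no tutor"),
              "mr_config_error")
    }
    if (length(unique(tutor_rows$bird_id)) > 1L) {
      mr_stop(paste0("nest ", nest$nest_id[1], " has more than one tutor"),
              "mr_config_error")
    }
    # crystallised song: the tutor's motifs share one label sequence; the
    # first motif is the reference
    first_motif <- split_motifs(tutor_rows)[[1]]
    tutor_labels <- first_motif$label

    for (m in split_motifs(nest)) {
      if (m$role[1] == "tutor") {
        add_unit(m, "TUTOR", 1L, nrow(m))
        next
      }
      add_unit(m, "EVERYTHING", 1L, nrow(m))
      # unfiltered candidates so that too-short runs are logged, not lost
      run <- shared_run_core(m$label, tutor_labels, match_mode)
      warn_interior_shared_runs(m$label, tutor_labels,
                                if (is.null(run)) 0L else run$end,
                                min_intervals)
      if (!is.null(run)) add_unit(m, run$kind, run$start, run$end)
      ns <- not_shared_runs_core(m$label, tutor_labels)
      for (i in seq_len(nrow(ns))) add_unit(m, "NOT_SHARED", ns$start[i], ns$end[i])
    }
  }

  out <- if (length(units)) do.call(rbind, units) else empty_units()
  out$subset_kind <- factor(out$subset_kind, levels = SUBSET_LEVELS)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}

empty_units <- function() {
  data.frame(nest_id = character(0), bird_id = character(0),
             role = character(0), motif_id = character(0),
             subset_kind = character(0), start_index = integer(0),
             end_index = integer(0), n_elements = integer(0),
             n_iois = integer(0), iois = I(list()),
             stringsAsFactors = FALSE)
}

#' Read and write analysis-unit tables
#'
#' Units are serialised with the interval vector as a semicolon-joined list
#' of seconds (`ioi_list`, six decimals), deterministic row order.
#'
#' @param units units table from [build_analysis_units()].
#' @param path file path.
#' @return `read_units()` returns a units table with the `iois` list column
#'   reconstructed; `write_units()` returns `path` invisibly.
#' @export
write_units <- function(units, path) {
  out <- units[, c("nest_id", "bird_id", "role", "motif_id", "subset_kind",
                   "start_index", "end_index", "n_elements", "n_iois")]
  out$ioi_list <- vapply(units$iois,
                         function(d) paste(sprintf("%.6f", d), collapse = ";"),
                         character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_units
#' @export
read_units <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(nest_id = "character",
                                       bird_id = "character",
                                       motif_id = "character"))
  df$iois <- I(lapply(strsplit(df$ioi_list, ";", fixed = TRUE), as.numeric))
  df$ioi_list <- NULL
  df$subset_kind <- factor(df$subset_kind, levels = SUBSET_LEVELS)
  df
}
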