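#' Motif annotation tables
#'
#' A motif table is a plain `data.frame` in long format, one row per annotated
#' element, with columns `nest_id`, `bird_id`, `role` (`"tutor"` or
#' `"tutee"`), `motif_id`, `element_index`, `label`, `onset_s` and optionally
#' `offset_s`. Element onsets are the start times of the labelled intervals in
#' the source annotation, in seconds from file start. This is the canonical
#' interchange format of the package; TextGrid files are an import/export
#' surface around it.
#'
#' `validate_motifs()` checks the structural invariants: required columns,
#' known roles, non-empty labels (after whitespace trimming), at least one
#' element per motif, unique `element_index` and strictly increasing onsets
#' within each motif, and `offset_s >= onset_s` where offsets are present.
#'
#' @param motifs data.frame in the long annotation format.
#' @return `validate_motifs()` returns the validated data.frame invisibly,
#'   with rows ordered by (nest, bird, motif, element_index) and labels
#'   trimmed; it throws a `mr_validation_error` naming the offending motif
#'   otherwise.
#' @seealso [read_motifs()], [read_textgrid()]
#' @export
validate_motifs <- function(motifs) {
  required <- c("nest_id", "bird_id", "role", "motif_id",
                "element_index", "label", "onset_s")
  if (!is.data.frame(motifs)) {
    mr_stop("`motifs` must be a data.frame", "mr_validation_error")
  }
  missing_cols <- setdiff(required, names(motifs))
  if (length(missing_cols)) {
    mr_stop(paste0("motif table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "mr_validation_error")
  }
  if (nrow(motifs) == 0L) {
    mr_stop("motif table has no rows", "mr_validation_error")
  }
  if (!all(motifs$role %in% c("tutor", "tutee"))) {
    mr_stop("role must be 'tutor' or 'tutee'", "mr_validation_error")
  }
  motifs$label <- trimws(as.character(motifs$label))
  if (any(motifs$label == "" | is.na(motifs$label))) {
    mr_stop("empty element labels are not allowed", "mr_validation_error")
  }
  if (!is.numeric(motifs$onset_s) || any(!is.finite(motifs$onset_s)) ||
      any(motifs$onset_s < 0)) {
    mr_stop("onset_s must be finite, non-negative numbers", "mr_validation_error")
  }
  key <- motif_key(motifs)
  ord <- order(motifs$nest_id, motifs$bird_id, motifs$motif_id, motifs$element_index)
  motifs <- motifs[ord, , drop = FALSE]
  key <- key[ord]
  for (k in unique(key)) {
    rows <- motifs[key == k, , drop = FALSE]
    if (anyDuplicated(rows$element_index)) {
      mr_stop(paste0("duplicate element_index in motif ", k), "mr_validation_error")
    }
    if (nrow(rows) > 1L && any(diff(rows$onset_s) <= 0)) {
      mr_stop(paste0("onsets not strictly increasing in motif ", k),
              "mr_validation_error")
    }
    if ("offset_s" %in% names(rows)) {
      off <- rows$offset_s
      bad <- !is.na(off) & off < rows$onset_s
      if (any(bad)) {
        mr_stop(paste0("offset_s earlier than onset_s in motif ", k),
                "mr_validation_error")
      }
    }
  }
  rownames(motifs) <- NULL
  invisible(motifs)
}

motif_key <- function(motifs) {
  paste(motifs$nest_id, motifs$bird_id, motifs$motif_id, sep = "/")
}

#' Read and write motif annotations as CSV
#'
#' The CSV dialect mirrors the motif table columns: `nest_id, bird_id, role,
#' motif_id, element_index, label, onset_s[, offset_s]`, times in seconds as
#' decimals. `write_motifs()` produces deterministic output: rows ordered by
#' (nest, bird, motif, element index) and times written with six decimals, so
#' that identical inputs give byte-identical files.
#'
#' @param path file path.
#' @param motifs validated motif table (see [validate_motifs()]).
#' @return `read_motifs()` returns a validated motif table;
#'   `write_motifs()` returns `path` invisibly.
#' @examples
#' csv <- system.file("extdata", "example_motifs.csv", package = "motifrhythm")
#' head(read_motifs(csv))
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) {
    mr_stop(paste0("file not found: ", path), "mr_validation_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character",
                                       nest_id = "character",
                                       bird_id = "character",
                                       motif_id = "character"))
  validate_motifs(df)
}

#' @rdname read_motifs
#' @export
write_motifs <- function(motifs, path) {
  motifs <- validate_motifs(motifs)
  out <- motifs
  out$onset_s <- sprintf("%.6f", out$onset_s)
  if ("offset_s" %in% names(out)) {
    out$offset_s <- ifelse(is.na(out$offset_s), "",
                           sprintf("%.6f", out$offset_s))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a motif table into per-motif data.frames (ordered, validated input
# assumed). Returns a named list keyed by nest/bird/motif.
split_motifs <- function(motifs) {
  key <- motif_key(motifs)
  split(motifs, factor(key, levels = unique(key)))
}
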