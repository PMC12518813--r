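#' Read a Praat TextGrid interval tier as an annotated motif
#'
#' Parses a Praat TextGrid file (long or short text dialect, UTF-8 or UTF-16)
#' and turns the named interval tier into one motif: every interval with a
#' non-empty label (after trimming whitespace) becomes an element whose onset
#' is the interval start time. Empty-labelled intervals are silences between
#' elements and are dropped.
#'
#' Motif metadata comes from the explicit arguments when given, otherwise
#' from `filename_pattern`, a Perl regex with named capture groups
#' `nest_id`, `bird_id`, `role` and `motif_id` applied to the file name. The
#' default pattern matches names like `N01_T01_tutor_m03.TextGrid`.
#'
#' @param path path to a TextGrid file.
#' @param tier name of the interval tier holding the element annotations
#'   (default `"elements"`; pass a syllable tier name to analyse syllables).
#' @param nest_id,bird_id,role,motif_id optional metadata overriding the
#'   filename pattern.
#' @param filename_pattern Perl regex with named groups used to pull
#'   metadata out of the file name.
#' @return A validated one-motif annotation table (see [validate_motifs()]).
#' @examples
#' tg <- system.file("extdata", "N01_T01_tutor_m01.TextGrid",
#'                   package = "motifrhythm")
#' read_textgrid(tg)
#' @export
read_textgrid <- function(path, tier = "elements",
                          nest_id = NULL, bird_id = NULL,
                          role = NULL, motif_id = NULL,
                          filename_pattern = default_filename_pattern()) {
  if (!file.exists(path)) {
    mr_stop(paste0("file not found: ", path), "mr_validation_error")
  }
  lines <- read_textgrid_lines(path)
  tiers <- if (any(grepl("\\bitem\\s*\\[", lines))) {
    parse_textgrid_long(lines)
  } else {
    parse_textgrid_short(lines)
  }
  idx <- which(vapply(tiers, function(t) identical(t$name, tier), logical(1)))
  if (!length(idx)) {
    mr_stop(paste0("tier '", tier, "' not found in ", basename(path),
                   " (tiers: ", paste(vapply(tiers, `[[`, "", "name"),
                                      collapse = ", "), ")"),
            "mr_tier_error")
  }
  tg_tier <- tiers[[idx[1]]]
  if (!identical(tg_tier$type, "IntervalTier")) {
    mr_stop(paste0("tier '", tier, "' is a point tier; an interval tier is required"),
            "mr_dialect_error")
  }
  iv <- tg_tier$intervals
  iv$text <- trimws(iv$text)
  iv <- iv[iv$text != "", , drop = FALSE]
  if (!nrow(iv)) {
    mr_stop(paste0("tier '", tier, "' has no labelled intervals"),
            "mr_validation_error")
  }
  iv <- iv[order(iv$xmin), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv$xmin[-1] < iv$xmax[-nrow(iv)] - 1e-9)) {
    mr_stop(paste0("overlapping labelled intervals in tier '", tier, "'"),
            "mr_validation_error")
  }

  meta <- parse_filename_metadata(basename(path), filename_pattern)
  nest_id <- nest_id %||% meta$nest_id
  bird_id <- bird_id %||% meta$bird_id
  role <- role %||% meta$role
  motif_id <- motif_id %||% meta$motif_id
  if (is.null(nest_id) || is.null(bird_id) || is.null(role) || is.null(motif_id)) {
    mr_stop(paste0("cannot determine motif metadata for ", basename(path),
                   ": pass nest_id/bird_id/role/motif_id or adjust filename_pattern"),
            "mr_validation_error")
  }
  motif <- data.frame(nest_id = nest_id, bird_id = bird_id, role = role,
                      motif_id = motif_id,
                      element_index = seq_len(nrow(iv)),
                      label = iv$text,
                      onset_s = iv$xmin, offset_s = iv$xmax,
                      stringsAsFactors = FALSE)
  validate_motifs(motif)
}

#' @rdname read_textgrid
#' @param paths a directory containing `.TextGrid` files, or a character
#'   vector of file paths; `read_textgrids()` reads them all and binds the
#'   motifs into one table.
#' @param ... passed on to [read_textgrid()].
#' @export
read_textgrids <- function(paths, tier = "elements", ...) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.TextGrid$", full.names = TRUE)
  }
  if (!length(paths)) {
    mr_stop("no TextGrid files to read", "mr_validation_error")
  }
  out <- do.call(rbind, lapply(sort(paths), read_textgrid, tier = tier, ...))
  validate_motifs(out)
}

#' Write motifs as Praat TextGrid files
#'
#' Writes one long-dialect TextGrid file per motif into `dir`, named
#' `<nest_id>_<bird_id>_<role>_<motif_id>.TextGrid`, with a single interval
#' tier. Element offsets are taken from `offset_s` where present; a missing
#' offset becomes the next element's onset (contiguous intervals), and the
#' last element gets `default_element_duration`. Gaps between an element's
#' offset and the next onset are written as empty-labelled intervals, so the
#' tier tiles its time range as Praat requires. Times are written with six
#' decimals, making output bit-stable for fixed input.
#'
#' @param motifs motif table (validated).
#' @param dir output directory (created if needed).
#' @param tier tier name to write.
#' @param default_element_duration duration in seconds assumed for the final
#'   element when its offset is absent.
#' @return Invisibly, the written file paths.
#' @export
write_textgrid <- function(motifs, dir, tier = "elements",
                           default_element_duration = 0.05) {
  motifs <- validate_motifs(motifs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in split_motifs(motifs)) {
    n <- nrow(m)
    onset <- m$onset_s
    offset <- if ("offset_s" %in% names(m)) m$offset_s else rep(NA_real_, n)
    next_onset <- c(onset[-1], onset[n] + default_element_duration)
    offset <- ifelse(is.na(offset), next_onset, offset)
    offset <- pmin(offset, next_onset)  # labelled intervals must not overlap

    xmin <- numeric(0); xmax <- numeric(0); text <- character(0)
    cursor <- 0
    for (i in seq_len(n)) {
      if (onset[i] > cursor + 1e-9) {
        xmin <- c(xmin, cursor); xmax <- c(xmax, onset[i]); text <- c(text, "")
      }
      xmin <- c(xmin, onset[i]); xmax <- c(xmax, offset[i]); text <- c(text, m$label[i])
      cursor <- offset[i]
    }
    total <- cursor

    fmt <- function(x) sprintf("%.6f", x)
    lines <- c(
      'File type = "ooTextFile"',
      'Object class = "TextGrid"',
      "",
      paste0("xmin = ", fmt(0)),
      paste0("xmax = ", fmt(total)),
      "tiers? <exists>",
      "size = 1",
      "item []:",
      "    item [1]:",
      '        class = "IntervalTier"',
      paste0('        name = "', tier, '"'),
      paste0("        xmin = ", fmt(0)),
      paste0("        xmax = ", fmt(total)),
      paste0("        intervals: size = ", length(xmin))
    )
    for (i in seq_along(xmin)) {
      lines <- c(lines,
                 paste0("        intervals [", i, "]:"),
                 paste0("            xmin = ", fmt(xmin[i])),
                 paste0("            xmax = ", fmt(xmax[i])),
                 paste0('            text = "', gsub('"', '""', text[i]), '"'))
    }
    fname <- paste0(m$nest_id[1], "_", m$bird_id[1], "_", m$role[1], "_",
                    m$motif_id[1], ".TextGrid")
    path <- file.path(dir, fname)
    writeLines(lines, path, useBytes = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname read_textgrid
#' @export
default_filename_pattern <- function() {
  "^(?<nest_id>[^_]+)_(?<bird_id>[^_]+)_(?<role>tutor|tutee)_(?<motif_id>[^.]+)\\.TextGrid$"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_filename_metadata <- function(fname, pattern) {
  m <- regexpr(pattern, fname, perl = TRUE)
  if (m == -1L) return(list(nest_id = NULL, bird_id = NULL, role = NULL, motif_id = NULL))
  starts <- attr(m, "capture.start")
  lens <- attr(m, "capture.length")
  nms <- attr(m, "capture.names")
  out <- list(nest_id = NULL, bird_id = NULL, role = NULL, motif_id = NULL)
  for (g in nms) {
    if (g == "" || starts[1, g] == -1L) next
    out[[g]] <- substr(fname, starts[1, g], starts[1, g] + lens[1, g] - 1L)
  }
  out
}

# Decode a TextGrid file to character lines, tolerating UTF-8 (with or
# without BOM) and UTF-16 (BOM required, either endianness).
read_textgrid_lines <- function(path) {
  head <- readBin(path, "raw", n = 2L)
  enc <- "UTF-8"
  if (length(head) == 2L &&
      ((head[1] == as.raw(0xfe) && head[2] == as.raw(0xff)) ||
       (head[1] == as.raw(0xff) && head[2] == as.raw(0xfe)))) {
    enc <- "UTF-16"
  }
  con <- file(path, encoding = enc)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  sub("^\\ufeff", "", lines)
}

tg_unquote <- function(s) {
  s <- trimws(s)
  if (nchar(s) >= 2L && startsWith(s, '"') && endsWith(s, '"')) {
    s <- substr(s, 2L, nchar(s) - 1L)
  }
  gsub('""', '"', s)
}

tg_value <- function(line) trimws(sub("^[^=]*=", "", line))

# Long ("verbose") dialect: key = value lines nested under item []/intervals [].
parse_textgrid_long <- function(lines) {
  lines <- trimws(lines)
  tiers <- list()
  cur <- NULL          # current tier under construction
  in_interval <- FALSE # inside an intervals [k] / points [k] block
  iv <- NULL           # current interval record
  flush_iv <- function() {
    if (!is.null(iv) && !is.null(cur)) {
      cur$xmin <<- c(cur$xmin, iv$xmin %||% NA_real_)
      cur$xmax <<- c(cur$xmax, iv$xmax %||% iv$xmin %||% NA_real_)
      cur$text <<- c(cur$text, iv$text %||% "")
    }
    iv <<- NULL
  }
  flush_tier <- function() {
    flush_iv()
    if (!is.null(cur)) {
      tiers[[length(tiers) + 1L]] <<- list(
        type = cur$type, name = cur$name,
        intervals = data.frame(xmin = cur$xmin, xmax = cur$xmax,
                               text = cur$text, stringsAsFactors = FALSE))
    }
    cur <<- NULL
  }
  for (line in lines) {
    if (grepl("^class\\s*=", line)) {
      flush_tier()
      cur <- list(type = tg_unquote(tg_value(line)), name = NA_character_,
                  xmin = numeric(0), xmax = numeric(0), text = character(0))
      in_interval <- FALSE
    } else if (grepl("^name\\s*=", line) && !is.null(cur) && !in_interval) {
      cur$name <- tg_unquote(tg_value(line))
    } else if (grepl("^(intervals|points)\\s*\\[", line)) {
      flush_iv()
      iv <- list()
      in_interval <- TRUE
    } else if (in_interval && grepl("^(xmin|number)\\s*=", line)) {
      iv$xmin <- as.numeric(tg_value(line))
    } else if (in_interval && grepl("^xmax\\s*=", line)) {
      iv$xmax <- as.numeric(tg_value(line))
    } else if (in_interval && grepl("^(text|mark)\\s*=", line)) {
      iv$text <- tg_unquote(tg_value(line))
    }
  }
  flush_tier()
  if (!length(tiers)) {
    mr_stop("no tiers found; not a TextGrid file?", "mr_dialect_error")
  }
  tiers
}

# Short dialect: bare values, one per line, fixed order.
parse_textgrid_short <- function(lines) {
  toks <- trimws(lines)
  toks <- toks[toks != ""]
  if (length(toks) < 7L || !grepl("ooTextFile", toks[1]) ||
      !grepl("TextGrid", toks[2])) {
    mr_stop("not a recognisable TextGrid file", "mr_dialect_error")
  }
  # toks: filetype, objclass, xmin, xmax, <exists>, ntiers, then tier blocks
  i <- 6L
  ntiers <- suppressWarnings(as.integer(toks[i]))
  if (is.na(ntiers)) {
    mr_stop("cannot parse tier count in short TextGrid", "mr_dialect_error")
  }
  tiers <- vector("list", ntiers)
  i <- i + 1L
  for (t in seq_len(ntiers)) {
    type <- tg_unquote(toks[i]); name <- tg_unquote(toks[i + 1L])
    n <- as.integer(toks[i + 4L])
    i <- i + 5L
    if (identical(type, "IntervalTier")) {
      xmin <- as.numeric(toks[i + 3L * (seq_len(n) - 1L)])
      xmax <- as.numeric(toks[i + 3L * (seq_len(n) - 1L) + 1L])
      text <- vapply(toks[i + 3L * (seq_len(n) - 1L) + 2L], tg_unquote, "",
                     USE.NAMES = FALSE)
      i <- i + 3L * n
    } else {
      xmin <- as.numeric(toks[i + 2L * (seq_len(n) - 1L)])
      xmax <- xmin
      text <- vapply(toks[i + 2L * (seq_len(n) - 1L) + 1L], tg_unquote, "",
                     USE.NAMES = FALSE)
      i <- i + 2L * n
    }
    tiers[[t]] <- list(type = type, name = name,
                       intervals = data.frame(xmin = xmin, xmax = xmax,
                                              text = text,
                                              stringsAsFactors = FALSE))
  }
  tiers
}
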