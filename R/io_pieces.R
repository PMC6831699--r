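#' Read a symbolic-music piece into a note-event table
#'
#' Supported formats: plain note lists (one event per line, tab-separated
#' `onset<TAB>pitch[<TAB>note_value]`, onsets in quarter-note units and
#' note values as rational strings such as `"1/2"`), Standard MIDI Files
#' (format 0 or 1), and MusicXML (monophonic pitch/note-value extraction).
#' Events are ordered by onset, ties broken by track index then ascending
#' pitch, so simultaneous notes contribute harmonic intervals in a
#' deterministic order. Percussion-channel (MIDI channel 10) events carry
#' no pitch-class meaning and are excluded.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"notelist"`, `"midi"`, or
#'   `"musicxml"`.
#' @return A data frame of class `note_events` with columns `onset`
#'   (quarter notes), `pitch` (MIDI number 0-127), `note_value` (rational
#'   string or `NA`), `track`; attribute `short` is `TRUE` when the piece
#'   has fewer than 100 notes (the corpus layer applies the filter).
#' @export
read_piece <- function(path, format = c("auto", "notelist", "midi", "musicxml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("read_piece: file not found: '%s'", path), call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
                     txt = , tsv = "notelist",
                     mid = , midi = "midi",
                     xml = , musicxml = "musicxml",
                     stop(sprintf("read_piece: cannot infer format from extension '.%s'", ext),
                          call. = FALSE))
  }
  ev <- switch(format,
               notelist = read_notelist(path),
               midi = read_midi(path),
               musicxml = read_musicxml(path))
  if (nrow(ev) == 0L) {
    stop(sprintf("read_piece: no note events in '%s'", path), call. = FALSE)
  }
  ev <- ev[order(ev$onset, ev$track, ev$pitch), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("note_events", "data.frame"),
            short = nrow(ev) < 100L)
}

read_notelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(data.frame(onset = numeric(0), pitch = integer(0),
                      note_value = character(0), track = integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(parts, length, integer(1))
  if (any(n < 2L)) {
    stop(sprintf("read_piece: note-list line %d has fewer than 2 fields",
                 which(n < 2L)[1L]), call. = FALSE)
  }
  onset <- vapply(parts, function(p) rat_value(rat_parse(p[1L])), numeric(1))
  pitch <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  if (any(is.na(pitch)) || any(pitch < 0) || any(pitch > 127)) {
    stop("read_piece: note-list pitches must be integers in [0, 127]",
         call. = FALSE)
  }
  note_value <- vapply(parts, function(p) {
    if (length(p) >= 3L && nzchar(p[3L])) {
      r <- rat_parse(p[3L])
      if (r[1L] <= 0) stop("read_piece: note values must be positive",
                           call. = FALSE)
      rat_format(r)
    } else NA_character_
  }, character(1))
  data.frame(onset = onset, pitch = pitch, note_value = note_value,
             track = 1L, stringsAsFactors = FALSE)
}

#' Write a note-event table in the note-list format
#'
#' The plain-text counterpart of [read_piece()]'s note-list reader; the
#' writer/reader round trip is exact.
#'
#' @param events data frame with columns `onset`, `pitch`, and optionally
#'   `note_value` (rational strings).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_notelist <- function(events, path) {
  stopifnot(is.data.frame(events), all(c("onset", "pitch") %in% names(events)))
  onset_str <- vapply(events$onset, function(o) {
    rat_format(rat_reduce(round(o * 10080), 10080))
  }, character(1))
  lines <- paste(onset_str, events$pitch, sep = "\t")
  if ("note_value" %in% names(events)) {
    nv <- ifelse(is.na(events$note_value), "", as.character(events$note_value))
    has <- nzchar(nv)
    lines[has] <- paste(lines[has], nv[has], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

read_musicxml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("read_piece: cannot parse MusicXML '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  step_to_pc <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)
  divisions <- 1L
  onset <- 0
  out <- list()
  notes <- xml2::xml_find_all(doc, ".//measure/*[self::note or self::attributes]")
  for (node in notes) {
    if (xml2::xml_name(node) == "attributes") {
      d <- xml2::xml_find_first(node, "./divisions")
      if (!inherits(d, "xml_missing")) {
        divisions <- as.integer(xml2::xml_text(d))
      }
      next
    }
    dur_node <- xml2::xml_find_first(node, "./duration")
    dur <- if (inherits(dur_node, "xml_missing")) 0L
           else as.integer(xml2::xml_text(dur_node))
    is_rest <- !inherits(xml2::xml_find_first(node, "./rest"), "xml_missing")
    pitch_node <- xml2::xml_find_first(node, "./pitch")
    if (!is_rest && !inherits(pitch_node, "xml_missing")) {
      step <- xml2::xml_text(xml2::xml_find_first(pitch_node, "./step"))
      octave <- as.integer(xml2::xml_text(xml2::xml_find_first(pitch_node, "./octave")))
      alter_node <- xml2::xml_find_first(pitch_node, "./alter")
      alter <- if (inherits(alter_node, "xml_missing")) 0L
               else as.integer(xml2::xml_text(alter_node))
      midi <- 12L * (octave + 1L) + step_to_pc[[step]] + alter
      nv <- rat_format(rat_reduce(dur, divisions))
      out[[length(out) + 1L]] <- data.frame(
        onset = onset, pitch = midi, note_value = nv, track = 1L,
        stringsAsFactors = FALSE)
    }
    onset <- onset + dur / divisions
  }
  if (length(out) == 0L) {
    return(data.frame(onset = numeric(0), pitch = integer(0),
                      note_value = character(0), track = integer(0)))
  }
  do.call(rbind, out)
}
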