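# Minimal Standard MIDI File codec (format 0/1). Only what the feature
# extractors need survives the round trip: note onsets (in quarter notes via
# the header division), pitches, and track/channel indices. Meta and sysex
# events are skipped on read; the writer emits a fixed-velocity format-0
# file. Running status is supported on read.

uint_bytes <- function(x, width) {
  out <- raw(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

bytes_uint <- function(bytes) {
  x <- 0
  for (b in bytes) x <- x * 256 + as.integer(b)
  x
}

varlen_encode <- function(x) {
  stopifnot(x >= 0)
  groups <- integer(0)
  repeat {
    groups <- c(x %% 128, groups)
    x <- x %/% 128
    if (x == 0) break
  }
  n <- length(groups)
  if (n > 1L) groups[seq_len(n - 1L)] <- groups[seq_len(n - 1L)] + 128
  as.raw(groups)
}

#' Write note events as a Standard MIDI File
#'
#' Emits a format-0 file with one track, fixed velocity and no tempo map;
#' only onsets and pitches matter to the downstream extractors. Each note
#' sounds for `duration` quarter notes (or per-event durations when the
#' events table has a numeric `duration` column).
#'
#' @param events data frame with columns `onset` (quarter notes) and
#'   `pitch`; optional `duration`.
#' @param path output file path.
#' @param division ticks per quarter note (default 480).
#' @param duration default note duration in quarter notes (default 0.5).
#' @return `path`, invisibly.
#' @export
write_midi <- function(events, path, division = 480L, duration = 0.5) {
  stopifnot(is.data.frame(events), all(c("onset", "pitch") %in% names(events)))
  if (any(events$pitch < 0 | events$pitch > 127)) {
    stop("write_midi: pitches must be in [0, 127]", call. = FALSE)
  }
  dur <- if ("duration" %in% names(events)) events$duration else
    rep(duration, nrow(events))
  on_ticks <- round(events$onset * division)
  off_ticks <- round((events$onset + dur) * division)
  ev <- rbind(
    data.frame(tick = on_ticks, pitch = events$pitch, on = TRUE),
    data.frame(tick = off_ticks, pitch = events$pitch, on = FALSE))
  # note-offs precede note-ons at equal ticks so repeated pitches retrigger
  ev <- ev[order(ev$tick, ev$on, ev$pitch), ]
  body <- raw(0)
  last <- 0
  chunks <- vector("list", nrow(ev) + 1L)
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last
    last <- ev$tick[i]
    status <- if (ev$on[i]) as.raw(0x90) else as.raw(0x80)
    chunks[[i]] <- c(varlen_encode(delta), status,
                     as.raw(ev$pitch[i]), as.raw(if (ev$on[i]) 64 else 0))
  }
  chunks[[nrow(ev) + 1L]] <- c(varlen_encode(0), as.raw(c(0xFF, 0x2F, 0x00)))
  body <- do.call(c, chunks)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), uint_bytes(6, 4), uint_bytes(0, 2),
             uint_bytes(1, 2), uint_bytes(division, 2),
             charToRaw("MTrk"), uint_bytes(length(body), 4), body), con)
  invisible(path)
}

read_midi <- function(path, note_values = c("ioi", "none"), grid_den = 12L) {
  note_values <- match.arg(note_values)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 14L || rawToChar(bytes[1:4]) != "MThd") {
    stop(sprintf("read_piece: '%s' is not a Standard MIDI File (missing MThd)",
                 path), call. = FALSE)
  }
  header_len <- bytes_uint(bytes[5:8])
  fmt <- bytes_uint(bytes[9:10])
  ntrks <- bytes_uint(bytes[11:12])
  division <- bytes_uint(bytes[13:14])
  if (!fmt %in% c(0, 1)) {
    stop(sprintf("read_piece: unsupported MIDI format %d in '%s'", fmt, path),
         call. = FALSE)
  }
  if (bitwAnd(division, 0x8000L) != 0L) {
    stop(sprintf("read_piece: SMPTE time division unsupported in '%s'", path),
         call. = FALSE)
  }
  pos <- 9L + header_len
  notes <- list()
  for (trk in seq_len(ntrks)) {
    if (pos + 7L > length(bytes) || rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") {
      stop(sprintf("read_piece: malformed MIDI track %d at byte %d in '%s'",
                   trk, pos, path), call. = FALSE)
    }
    trk_len <- bytes_uint(bytes[(pos + 4L):(pos + 7L)])
    p <- pos + 8L
    end <- p + trk_len
    tick <- 0
    status <- NULL
    while (p < end) {
      # delta time (variable length)
      delta <- 0
      repeat {
        b <- as.integer(bytes[p]); p <- p + 1L
        delta <- delta * 128 + (b %% 128)
        if (b < 128) break
      }
      tick <- tick + delta
      b <- as.integer(bytes[p])
      if (b >= 128) {
        status <- b
        p <- p + 1L
      } else if (is.null(status)) {
        stop(sprintf("read_piece: running status without prior status at byte %d in '%s'",
                     p, path), call. = FALSE)
      }
      hi <- status %/% 16
      if (status == 0xFF) {
        p <- p + 1L  # meta type
        len <- 0
        repeat {
          b2 <- as.integer(bytes[p]); p <- p + 1L
          len <- len * 128 + (b2 %% 128)
          if (b2 < 128) break
        }
        p <- p + len
        status <- NULL
      } else if (status %in% c(0xF0, 0xF7)) {
        len <- 0
        repeat {
          b2 <- as.integer(bytes[p]); p <- p + 1L
          len <- len * 128 + (b2 %% 128)
          if (b2 < 128) break
        }
        p <- p + len
        status <- NULL
      } else if (hi %in% c(0x8, 0x9, 0xA, 0xB, 0xE)) {
        d1 <- as.integer(bytes[p]); d2 <- as.integer(bytes[p + 1L])
        p <- p + 2L
        channel <- status %% 16
        if (hi == 0x9 && d2 > 0 && channel != 9L) {  # channel 10 = percussion
          notes[[length(notes) + 1L]] <- c(tick = tick, pitch = d1, track = trk)
        }
      } else if (hi %in% c(0xC, 0xD)) {
        p <- p + 1L
      } else {
        stop(sprintf("read_piece: unexpected status byte 0x%X at byte %d in '%s'",
                     status, p, path), call. = FALSE)
      }
    }
    pos <- end
  }
  if (length(notes) == 0L) {
    return(data.frame(onset = numeric(0), pitch = integer(0),
                      note_value = character(0), track = integer(0)))
  }
  m <- do.call(rbind, notes)
  df <- data.frame(onset = m[, "tick"] / division,
                   pitch = as.integer(m[, "pitch"]),
                   note_value = NA_character_,
                   track = as.integer(m[, "track"]),
                   stringsAsFactors = FALSE)
  if (note_values == "ioi") {
    # no notated durations in MIDI: approximate by the inter-onset interval
    # within each track, quantized to the rational grid
    for (trk in unique(df$track)) {
      idx <- which(df$track == trk)
      idx <- idx[order(df$onset[idx])]
      if (length(idx) >= 2L) {
        ioi <- diff(df$onset[idx])
        keep <- ioi > 0
        df$note_value[idx[-length(idx)][keep]] <-
          vapply(ioi[keep], function(x) rat_format(rat_quantize(x, grid_den)),
                 character(1))
      }
    }
  }
  df
}
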