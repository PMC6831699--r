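#' Pitch-class-interval sequence of a pitch stream
#'
#' Converts MIDI pitches to pitch classes (mod 12), takes successive
#' differences mod 12, then deletes zero intervals (repeated pitches and
#' octave transitions), which would otherwise dilute the informative
#' features. Note the order: differencing is applied to the full pitch-class
#' stream first, zeros are removed afterwards.
#'
#' @param pitches integer vector of MIDI pitch numbers (0-127), in order of
#'   appearance.
#' @return Integer vector with values in 1..11 (class `interval_sequence`);
#'   empty when fewer than 2 pitches are given or all intervals are zero.
#' @export
#' @examples
#' interval_sequence(c(60, 64, 67, 67, 72, 66, 60))  # 4 3 5 6 6
interval_sequence <- function(pitches) {
  if (length(pitches) > 0 &&
      (!is.numeric(pitches) || any(!is.finite(pitches)) ||
       any(pitches != round(pitches)) || any(pitches < 0) || any(pitches > 127))) {
    stop("interval_sequence: pitches must be integers in [0, 127]", call. = FALSE)
  }
  if (length(pitches) < 2L) {
    return(structure(integer(0), class = "interval_sequence"))
  }
  pc <- as.integer(pitches) %% 12L
  iv <- diff(pc) %% 12L
  structure(iv[iv != 0L], class = "interval_sequence")
}

check_interval_seq <- function(x, min_len, what) {
  if (!is.numeric(x) ||
      (length(x) > 0 && (any(x != round(x)) || any(x < 1) || any(x > 11)))) {
    stop(sprintf("%s: intervals must be integers in 1..11", what), call. = FALSE)
  }
  if (length(x) < min_len) {
    stop(sprintf("%s: frequency undefined for fewer than %d intervals",
                 what, min_len), call. = FALSE)
  }
  as.integer(x)
}

#' Tritone frequency of an interval sequence
#'
#' The fraction of pitch-class intervals equal to 6 semitones,
#' \eqn{\#\{n : x_n = 6\}/|x|}.
#'
#' @param seq an [interval_sequence()] (integers in 1..11), length >= 1.
#' @return A frequency in \[0, 1\].
#' @export
#' @examples
#' tritone_frequency(c(4, 3, 5, 6, 6))  # 0.4
tritone_frequency <- function(seq) {
  x <- check_interval_seq(seq, 1L, "tritone_frequency")
  sum(x == 6L) / length(x)
}

# the 20 interval bigrams unrealizable on a diatonic scale (Methods list)
NONDIATONIC_SET <- matrix(c(
  1, 1,  1, 3,  1, 8,  1, 10,  2, 11,
  3, 1,  3, 8,  4, 4,  4, 9,   4, 11,
  8, 1,  8, 3,  8, 8,  9, 4,   9, 11,
  10, 1, 11, 2, 11, 4, 11, 9,  11, 11),
  ncol = 2L, byrow = TRUE)

#' The set of non-diatonic interval bigrams
#'
#' An ordered pair of successive pitch-class intervals is a *non-diatonic
#' motion* when no three notes of a single diatonic scale can produce it.
#' By transposition invariance one scale suffices, so the brute-force
#' derivation enumerates all three-note walks `p -> q -> r` on the white-key
#' pitch-class set \{0, 2, 4, 5, 7, 9, 11\} with nonzero mod-12 steps,
#' collects the realizable interval bigrams, and returns the complement
#' within the 11 x 11 alphabet — 20 pairs.
#'
#' @param method `"reference"` for the hard-coded 20-pair constant,
#'   `"brute_force"` for the independent enumeration (the two agree; a unit
#'   test holds them together).
#' @return A two-column integer matrix of ordered pairs `(first, second)`,
#'   sorted lexicographically.
#' @export
#' @examples
#' nrow(nondiatonic_set())  # 20
nondiatonic_set <- function(method = c("reference", "brute_force")) {
  method <- match.arg(method)
  if (method == "reference") {
    m <- NONDIATONIC_SET
    storage.mode(m) <- "integer"
    colnames(m) <- c("first", "second")
    return(m)
  }
  scale <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
  realizable <- matrix(FALSE, 11L, 11L)
  for (p in scale) for (q in scale) for (r in scale) {
    i <- (q - p) %% 12L
    j <- (r - q) %% 12L
    if (i != 0L && j != 0L) realizable[i, j] <- TRUE
  }
  idx <- which(!realizable, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  m <- matrix(as.integer(idx), ncol = 2L)
  colnames(m) <- c("first", "second")
  m
}

#' Non-diatonic-motion frequency of an interval sequence
#'
#' \eqn{\#\{n : (x_n, x_{n+1}) \in C\}/|x|}, where C is the 20-element
#' [nondiatonic_set()]. The denominator is the sequence length `|x|`, not
#' the number of bigrams `|x| - 1`.
#'
#' @param seq an [interval_sequence()], length >= 2.
#' @return A frequency in \[0, 1\].
#' @export
#' @examples
#' nondiatonic_frequency(c(1, 1, 1))  # 2/3
nondiatonic_frequency <- function(seq) {
  x <- check_interval_seq(seq, 2L, "nondiatonic_frequency")
  inC <- matrix(FALSE, 11L, 11L)
  inC[NONDIATONIC_SET] <- TRUE
  n <- length(x)
  sum(inC[cbind(x[-n], x[-1L])]) / n
}

#' Bigram frequencies of an interval sequence
#'
#' Frequencies of all `121 = 11^2` ordered pairs of successive pitch-class
#' intervals, each normalized by the sequence length `|x|` (the same
#' convention as [nondiatonic_frequency()]), so the entries sum to
#' `(|x| - 1)/|x|`.
#'
#' @param seq an [interval_sequence()], length >= 2.
#' @return An 11 x 11 numeric matrix; rows index the first interval,
#'   columns the second.
#' @export
bigram_frequencies <- function(seq) {
  x <- check_interval_seq(seq, 2L, "bigram_frequencies")
  n <- length(x)
  counts <- matrix(0, 11L, 11L, dimnames = list(first = 1:11, second = 1:11))
  pairs <- cbind(x[-n], x[-1L])
  for (k in seq_len(nrow(pairs))) {
    counts[pairs[k, 1L], pairs[k, 2L]] <- counts[pairs[k, 1L], pairs[k, 2L]] + 1
  }
  counts / n
}

# the 11 duration ratios regarded as common; everything else is "rare"
ALLOWED_RHYTHM_RATIOS <- list(
  c(1, 1), c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1),
  c(1, 4), c(4, 1), c(1, 6), c(6, 1))

#' Rare-rhythm frequency of a note-value sequence
#'
#' For each adjacent pair of note values the exact rational ratio
#' `value[n+1]/value[n]` is computed; the pair is *rare* when the ratio is
#' not one of the 11 common ratios \{1, 1/2, 2, 2/3, 3/2, 1/3, 3, 1/4, 4,
#' 1/6, 6\}. Membership is decided in exact rational arithmetic. The
#' frequency is the rare count divided by the number of bigrams `|v| - 1`
#' by default (`denominator = "bigrams"`); `denominator = "values"` divides
#' by `|v|` instead, matching the normalization used for interval bigrams.
#'
#' @param values note values as rational strings (`"1/2"`), integers, or a
#'   list of `c(num, den)` pairs; at least 2 positive values.
#' @param denominator `"bigrams"` (default) or `"values"`.
#' @return A frequency in \[0, 1\].
#' @export
#' @examples
#' rare_rhythm_frequency(c("1", "1/5", "1/5"))  # 0.5
rare_rhythm_frequency <- function(values, denominator = c("bigrams", "values")) {
  denominator <- match.arg(denominator)
  rats <- lapply(values, function(v) {
    r <- if (is.numeric(v) && length(v) == 2L) rat_reduce(v[1L], v[2L])
         else rat_parse(v)
    if (r[1L] <= 0) stop("rare_rhythm_frequency: note values must be positive",
                         call. = FALSE)
    r
  })
  n <- length(rats)
  if (n < 2L) {
    stop("rare_rhythm_frequency: need at least 2 note values", call. = FALSE)
  }
  allowed <- vapply(ALLOWED_RHYTHM_RATIOS, rat_format, character(1))
  rare <- 0L
  for (k in seq_len(n - 1L)) {
    ratio <- rat_div(rats[[k + 1L]], rats[[k]])
    if (!(rat_format(ratio) %in% allowed)) rare <- rare + 1L
  }
  rare / if (denominator == "bigrams") n - 1L else n
}

#' Extract all features of one piece
#'
#' Runs the full extractor set on a note-event table: interval sequence,
#' tritone and non-diatonic frequencies, the 121 bigram frequencies, and —
#' when note values are available — the rare-rhythm frequency.
#'
#' @param events a note-event data frame from [read_piece()].
#' @param piece_id,composer,year optional metadata carried into the result.
#' @return A list of class `piece_features` with fields `piece_id`,
#'   `composer`, `year`, `n_notes`, `n_intervals`, `short` (fewer than 100
#'   notes), `tritone_freq`, `nondiatonic_freq`, `bigram_freqs` (11 x 11
#'   matrix), `rare_rhythm_freq` (`NA` without note values). Frequencies
#'   needing a longer sequence than available are `NA`.
#' @export
piece_features <- function(events, piece_id = NA_character_,
                           composer = NA_character_, year = NA_real_) {
  stopifnot(is.data.frame(events), all(c("onset", "pitch") %in% names(events)))
  iv <- interval_sequence(events$pitch)
  n_iv <- length(iv)
  tri <- if (n_iv >= 1L) tritone_frequency(iv) else NA_real_
  ndia <- if (n_iv >= 2L) nondiatonic_frequency(iv) else NA_real_
  big <- if (n_iv >= 2L) bigram_frequencies(iv) else matrix(NA_real_, 11L, 11L)
  rare <- NA_real_
  if ("note_value" %in% names(events)) {
    vals <- events$note_value[!is.na(events$note_value)]
    if (length(vals) >= 2L) rare <- rare_rhythm_frequency(vals)
  }
  structure(list(piece_id = piece_id, composer = composer, year = year,
                 n_notes = nrow(events), n_intervals = n_iv,
                 short = nrow(events) < 100L,
                 tritone_freq = tri, nondiatonic_freq = ndia,
                 bigram_freqs = big, rare_rhythm_freq = rare),
            class = "piece_features")
}

#' Extract features for a corpus directory
#'
#' Reads every piece file in a directory, applies [piece_features()], joins
#' per-piece metadata, and applies the corpus-level filter: pieces with
#' fewer than `min_notes` notes (default 100) are dropped.
#'
#' @param dir directory containing piece files (`.txt`/`.tsv` note lists,
#'   `.mid`/`.midi` Standard MIDI Files, `.xml`/`.musicxml` MusicXML).
#' @param metadata optional data frame with columns `piece_id`, `composer`,
#'   `year` (or a path to such a CSV); matched on file name without
#'   extension.
#' @param min_notes minimum note count for inclusion (default 100).
#' @param drop_duplicates if `TRUE`, keep only the first file among those
#'   whose normalized names (lower case, non-alphanumerics stripped)
#'   coincide. Off by default.
#' @return A features data frame as produced by [features_table()].
#' @export
extract_corpus <- function(dir, metadata = NULL, min_notes = 100L,
                           drop_duplicates = FALSE) {
  files <- list.files(dir, pattern = "\\.(txt|tsv|mid|midi|xml|musicxml)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("extract_corpus: no piece files found in '%s'", dir),
         call. = FALSE)
  }
  files <- sort(files)
  if (drop_duplicates) {
    key <- tolower(gsub("[^a-z0-9]", "", tolower(basename(files))))
    files <- files[!duplicated(key)]
  }
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  }
  feats <- list()
  for (f in files) {
    id <- sub("\\.[^.]+$", "", basename(f))
    ev <- read_piece(f)
    composer <- NA_character_
    year <- NA_real_
    if (!is.null(metadata)) {
      row <- match(id, metadata$piece_id)
      if (!is.na(row)) {
        composer <- as.character(metadata$composer[row])
        year <- as.numeric(metadata$year[row])
      }
    }
    pf <- piece_features(ev, piece_id = id, composer = composer, year = year)
    if (pf$n_notes >= min_notes) feats[[length(feats) + 1L]] <- pf
  }
  if (length(feats) == 0L) {
    stop("extract_corpus: all pieces were shorter than the minimum note count",
         call. = FALSE)
  }
  features_table(feats)
}

#' Flatten piece features into a table
#'
#' @param features a list of [piece_features()] objects.
#' @param include_bigrams if `TRUE`, append 121 columns `bigram_i_j`.
#' @return A data frame with one row per piece: `piece_id`, `composer`,
#'   `year`, `n_notes`, `n_intervals`, `short`, `tritone_freq`,
#'   `nondiatonic_freq`, `rare_rhythm_freq` (and optionally the bigrams).
#' @export
features_table <- function(features, include_bigrams = FALSE) {
  stopifnot(length(features) > 0)
  base <- do.call(rbind, lapply(features, function(p) {
    data.frame(piece_id = p$piece_id, composer = p$composer, year = p$year,
               n_notes = p$n_notes, n_intervals = p$n_intervals,
               short = p$short, tritone_freq = p$tritone_freq,
               nondiatonic_freq = p$nondiatonic_freq,
               rare_rhythm_freq = p$rare_rhythm_freq,
               stringsAsFactors = FALSE)
  }))
  if (include_bigrams) {
    bg <- do.call(rbind, lapply(features, function(p) {
      v <- as.vector(t(p$bigram_freqs))
      names(v) <- paste0("bigram_", rep(1:11, each = 11), "_", rep(1:11, 11))
      v
    }))
    base <- cbind(base, as.data.frame(bg))
  }
  rownames(base) <- NULL
  base
}
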