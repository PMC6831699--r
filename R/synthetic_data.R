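#' Simulate a synthetic corpus along a model trajectory
#'
#' Implements the generative assumption behind the dynamical models: per
#' piece, a frequency \eqn{\theta} is drawn from the generation's beta
#' model, then each note carries the rare event independently with
#' probability \eqn{\theta}, so event counts are binomial. Piece lengths
#' are uniform over `note_count_range` — the 10^2 to 10^3 notes of a
#' typical musical piece. The output uses the same features/metadata
#' schemas consumed by [window_series()].
#'
#' @param trajectory a `trajectory` data frame (from [sce_iterate()]), or
#'   any data frame with columns `a` and `b`, one row per generation.
#' @param pieces_per_generation number of pieces per generation.
#' @param note_count_range integer interval of notes per piece (default
#'   `c(100, 1000)`).
#' @param seed integer seed; identical seeds give identical corpora.
#' @param start_year,years_per_generation calendar mapping of generations
#'   (defaults 1500 and 25).
#' @return A data frame with one row per piece: `piece_id`, `composer`
#'   (synthetic label), `year`, `generation`, `n_notes`, `theta` (latent),
#'   `freq` (observed event frequency), and `tritone_freq` set equal to
#'   `freq` so the table is drop-in for the corpus-statistics layer.
#' @export
#' @examples
#' tr <- sce_iterate(moment_pair(0.05, 0.03), selection_params(0, 1), 4)
#' corp <- simulate_corpus(tr, pieces_per_generation = 50, seed = 1)
#' head(corp)
simulate_corpus <- function(trajectory, pieces_per_generation,
                            note_count_range = c(100L, 1000L), seed = 1L,
                            start_year = 1500, years_per_generation = 25) {
  stopifnot(is.data.frame(trajectory), all(c("a", "b") %in% names(trajectory)),
            nrow(trajectory) >= 1L)
  if (!is.numeric(pieces_per_generation) || pieces_per_generation < 1 ||
      pieces_per_generation != round(pieces_per_generation)) {
    stop("simulate_corpus: 'pieces_per_generation' must be a positive integer",
         call. = FALSE)
  }
  note_count_range <- as.integer(note_count_range)
  if (length(note_count_range) != 2L || any(note_count_range < 2L) ||
      any(note_count_range > 1e5L) ||
      note_count_range[1L] > note_count_range[2L]) {
    stop("simulate_corpus: 'note_count_range' must be an increasing integer pair within [2, 1e5]",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- pieces_per_generation
  rows <- lapply(seq_len(nrow(trajectory)), function(i) {
    t <- i - 1L
    theta <- stats::rbeta(m, trajectory$a[i], trajectory$b[i])
    n_notes <- sample.int(note_count_range[2L] - note_count_range[1L] + 1L,
                          m, replace = TRUE) + note_count_range[1L] - 1L
    counts <- stats::rbinom(m, n_notes, theta)
    data.frame(piece_id = sprintf("gen%03d_piece%04d", t, seq_len(m)),
               composer = sprintf("synthetic_gen%03d", t),
               year = start_year + t * years_per_generation,
               generation = t, n_notes = n_notes, theta = theta,
               freq = counts / n_notes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$tritone_freq <- out$freq
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write note-list fixtures with planted features
#'
#' Builds pieces whose extracted features are known by construction, for
#' testing the extractors: an interval plan is realized as a monotone
#' pitch walk (each pitch is the previous plus the planned interval, kept
#' inside the MIDI range by octave folding that never creates zero
#' pitch-class intervals), and note values are written verbatim.
#'
#' @param plans a list; each element is a list with fields `id`,
#'   `intervals` (integers 1..11), optional `note_values` (rational
#'   strings, same length as the note count), optional `start_pitch`
#'   (default 60).
#' @param dir output directory (created if missing).
#' @param midi also emit a `.mid` file per piece (default `FALSE`).
#' @return Character vector of the note-list paths written, invisibly.
#' @export
make_note_fixtures <- function(plans, dir, midi = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (plan in plans) {
    stopifnot(is.list(plan), !is.null(plan$id), !is.null(plan$intervals))
    iv <- as.integer(plan$intervals)
    if (length(iv) > 0 && (any(iv < 1L) || any(iv > 11L))) {
      stop("make_note_fixtures: planned intervals must lie in 1..11",
           call. = FALSE)
    }
    start <- if (is.null(plan$start_pitch)) 60L else as.integer(plan$start_pitch)
    pitches <- Reduce(function(p, d) {
      nxt <- p + d
      # octave folding preserves the pitch class, hence the planned interval
      while (nxt > 115L) nxt <- nxt - 12L
      while (nxt < 12L) nxt <- nxt + 12L
      nxt
    }, iv, accumulate = TRUE, init = start)
    n <- length(pitches)
    ev <- data.frame(onset = seq_len(n) - 1, pitch = pitches,
                     stringsAsFactors = FALSE)
    if (!is.null(plan$note_values)) {
      stopifnot(length(plan$note_values) == n)
      ev$note_value <- vapply(plan$note_values,
                              function(v) rat_format(rat_parse(v)),
                              character(1))
    }
    path <- file.path(dir, paste0(plan$id, ".txt"))
    write_notelist(ev, path)
    if (midi) write_midi(ev, file.path(dir, paste0(plan$id, ".mid")))
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' End-to-end parameter-recovery experiment
#'
#' The validation harness for the whole pipeline: simulate a model
#' trajectory, optionally sample a synthetic corpus from it, aggregate the
#' corpus into a window series, fit the model back, and report true versus
#' recovered coefficients. With `pieces_per_generation = NULL` the fit sees
#' the noiseless model moments (closed-loop self-consistency); otherwise
#' binomial/beta sampling noise and the zero-frequency exclusion enter, as
#' they would for a real corpus.
#'
#' @param true_params a [selection_params()] (SCE) or a scalar `beta`
#'   (log-potential).
#' @param init a [moment_pair()] initial state (for the log-potential model
#'   it is converted through [lognormal_from_moments()]).
#' @param generations number of generations simulated (>= 1).
#' @param pieces_per_generation corpus size per generation, or `NULL` for
#'   noiseless moments.
#' @param note_count_range notes per piece (default `c(100, 1000)`).
#' @param seed integer seed for corpus sampling.
#' @param grid_points optimizer grid density passed to [fit_model()].
#' @return A list of class `recovery_report`: `model`, `true`, `recovered`,
#'   `relative_error` (per coefficient, `NA` where the true value is 0),
#'   `fit` (the full [fit_model()] result), and `series`.
#' @export
recovery_experiment <- function(true_params, init, generations,
                                pieces_per_generation = NULL,
                                note_count_range = c(100L, 1000L), seed = 1L,
                                grid_points = 21L) {
  if (!is.numeric(generations) || generations < 1 ||
      generations != round(generations)) {
    stop("recovery_experiment: 'generations' must be a positive integer",
         call. = FALSE)
  }
  is_sce <- inherits(true_params, "selection_params")
  init <- as_moment_pair(init)
  if (is_sce) {
    tr <- sce_iterate(init, true_params, generations)
    model <- "sce"
  } else {
    beta <- as.numeric(true_params)[1L]
    tr <- logpotential_iterate(lognormal_from_moments(init), beta, generations)
    model <- "logpotential"
  }
  if (is.null(pieces_per_generation)) {
    series <- data.frame(mean = tr$mu, sd = tr$sigma)
  } else {
    corp <- simulate_corpus(tr, pieces_per_generation,
                            note_count_range = note_count_range, seed = seed)
    # One window per generation so model steps align with data steps.
    # The model describes the latent per-piece frequency theta, while the
    # observed frequency adds binomial noise: var(f) = sigma_t^2 +
    # E[theta(1-theta)/N]. The recovery estimator therefore subtracts the
    # unbiased within-piece term mean(f(1-f)/(N-1)) from the sample
    # variance and keeps zero-frequency pieces (zero-exclusion is the
    # descriptive corpus convention, not a latent-moment estimator).
    series <- do.call(rbind, lapply(split(corp, corp$generation), function(g) {
      v <- stats::var(g$freq) -
        mean(g$freq * (1 - g$freq) / (g$n_notes - 1L))
      data.frame(mean = mean(g$freq), sd = sqrt(max(v, 1e-12)))
    }))
    rownames(series) <- NULL
  }
  fit <- fit_model(series, model = model, grid_points = grid_points)
  if (is_sce) {
    true_vec <- c(beta_T = true_params$beta_T, beta_N = true_params$beta_N)
    rec_vec <- c(beta_T = fit$params$beta_T, beta_N = fit$params$beta_N)
  } else {
    true_vec <- c(beta = beta)
    rec_vec <- c(beta = fit$params)
  }
  rel <- ifelse(true_vec == 0, NA_real_, abs(rec_vec - true_vec) / abs(true_vec))
  structure(list(model = model, true = true_vec, recovered = rec_vec,
                 relative_error = rel, fit = fit, series = series),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report: %s model>\n", x$model))
  print(data.frame(true = x$true, recovered = x$recovered,
                   relative_error = x$relative_error))
  invisible(x)
}
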