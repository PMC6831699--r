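#' Sliding-window statistics of a feature frequency
#'
#' Aggregates per-piece frequencies into time windows `[y, y + width)`
#' stepped by `step` years across the span of the data — by default
#' 100-year windows shifted in 25-year steps. Pieces with frequency exactly
#' zero are excluded before computing statistics (rare-event frequencies of
#' zero carry no distributional information and would distort the mean/SD
#' of the observed distribution); the sample (n-1) standard deviation is
#' used. Windows with fewer than 2 surviving pieces have `sd = NA`.
#'
#' @param features a features data frame (see [features_table()]) with a
#'   `year` column.
#' @param feature name of the frequency column (e.g. `"tritone_freq"`).
#' @param width,step window width and shift in years (defaults 100 and 25).
#' @param exclude_zero drop exact-zero frequencies (default `TRUE`).
#' @return A data frame of class `window_stats` with columns
#'   `window_start`, `window_end`, `n_pieces`, `mean`, `sd`, `ratio`
#'   (`sd/mean`).
#' @export
window_series <- function(features, feature, width = 100, step = 25,
                          exclude_zero = TRUE) {
  stopifnot(is.data.frame(features), width > 0, step > 0)
  if (!feature %in% names(features)) {
    stop(sprintf("window_series: unknown feature '%s'", feature), call. = FALSE)
  }
  if (!"year" %in% names(features) || any(is.na(features$year))) {
    stop("window_series: every piece needs a 'year'", call. = FALSE)
  }
  x <- features[[feature]]
  yr <- features$year
  keep <- !is.na(x)
  x <- x[keep]; yr <- yr[keep]
  starts <- seq(floor(min(yr) / step) * step, max(yr), by = step)
  rows <- lapply(starts, function(s) {
    inw <- yr >= s & yr < s + width
    v <- x[inw]
    if (exclude_zero) v <- v[v != 0]
    n <- length(v)
    data.frame(window_start = s, window_end = s + width, n_pieces = n,
               mean = if (n >= 1L) mean(v) else NA_real_,
               sd = if (n >= 2L) stats::sd(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$ratio <- out$sd / out$mean
  structure(out, class = c("window_stats", "data.frame"),
            feature = feature, width = width, step = step)
}

#' Per-composer statistics of a feature frequency
#'
#' Mean, sample SD, and piece count per composer, with the same
#' zero-frequency exclusion as [window_series()]. Composers whose pieces
#' are all zero-frequency appear with `n_pieces = 0` and `NA` statistics.
#'
#' @inheritParams window_series
#' @return A data frame with columns `composer`, `n_pieces`, `mean`, `sd`.
#' @export
composer_stats <- function(features, feature, exclude_zero = TRUE) {
  stopifnot(is.data.frame(features))
  if (!feature %in% names(features)) {
    stop(sprintf("composer_stats: unknown feature '%s'", feature), call. = FALSE)
  }
  split_rows <- split(features[[feature]], features$composer)
  out <- do.call(rbind, lapply(names(split_rows), function(comp) {
    v <- split_rows[[comp]]
    v <- v[!is.na(v)]
    if (exclude_zero) v <- v[v != 0]
    n <- length(v)
    data.frame(composer = comp, n_pieces = n,
               mean = if (n >= 1L) mean(v) else NA_real_,
               sd = if (n >= 2L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-era beta fits of a feature frequency
#'
#' Splits pieces into eras (century bins by default), drops zero
#' frequencies, and fits a beta distribution to each era by [fit_beta()].
#' Eras that cannot be fitted (fewer than 3 nonzero values, zero variance)
#' are flagged rather than aborting the others.
#'
#' @inheritParams window_series
#' @param edges era boundaries in years; defaults to century edges spanning
#'   the data.
#' @return A data frame with columns `era_start`, `era_end`, `n_pieces`,
#'   `a`, `b`, `logLik`, `ok`, `note`.
#' @export
era_beta_fit <- function(features, feature, edges = NULL) {
  stopifnot(is.data.frame(features))
  if (!feature %in% names(features)) {
    stop(sprintf("era_beta_fit: unknown feature '%s'", feature), call. = FALSE)
  }
  yr <- features$year
  x <- features[[feature]]
  if (is.null(edges)) {
    edges <- seq(floor(min(yr) / 100) * 100, ceiling(max(yr) / 100) * 100,
                 by = 100)
  }
  out <- lapply(seq_len(length(edges) - 1L), function(i) {
    ine <- yr >= edges[i] & yr < edges[i + 1L]
    v <- x[ine & !is.na(x)]
    v <- v[v > 0 & v < 1]  # both endpoints are uninformative for a beta fit
    row <- data.frame(era_start = edges[i], era_end = edges[i + 1L],
                      n_pieces = length(v), a = NA_real_, b = NA_real_,
                      logLik = NA_real_, ok = FALSE, note = "",
                      stringsAsFactors = FALSE)
    fit <- tryCatch(fit_beta(v), error = function(e) e, warning = function(w) w)
    if (inherits(fit, "beta_params")) {
      row$a <- fit$a; row$b <- fit$b
      row$logLik <- attr(fit, "logLik")
      row$ok <- TRUE
    } else {
      row$note <- conditionMessage(fit)
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a window series to CSV
#'
#' Schema `window_start, window_end, n_pieces, mean, sd, ratio` — also the
#' input schema of the model-fitting layer.
#'
#' @param ws a [window_series()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_series_csv <- function(ws, path) {
  utils::write.csv(as.data.frame(ws), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a window-series CSV
#'
#' @param path file path (schema of [write_window_series_csv()]).
#' @return A `window_stats` data frame.
#' @export
read_window_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_start", "window_end", "n_pieces", "mean", "sd")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_window_series_csv: missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  if (!"ratio" %in% names(df)) df$ratio <- df$sd / df$mean
  structure(df, class = c("window_stats", "data.frame"))
}
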