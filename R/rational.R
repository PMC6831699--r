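# Exact rational arithmetic for note values. Note values are carried as
# "num/den" strings (quarter-note units) so rhythm-ratio membership can be
# decided exactly, never through floating point.

rat_gcd <- function(x, y) {
  while (y != 0) {
    tmp <- x %% y
    x <- y
    y <- tmp
  }
  abs(x)
}

# parse "3/4" or "2" to a reduced c(num, den) integer pair
rat_parse <- function(s) {
  s <- trimws(as.character(s))
  if (!grepl("^[0-9]+(/[0-9]+)?$", s)) {
    stop(sprintf("invalid rational '%s' (expected 'p' or 'p/q')", s),
         call. = FALSE)
  }
  parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
  num <- as.numeric(parts[1L])
  den <- if (length(parts) == 2L) as.numeric(parts[2L]) else 1
  if (den == 0) stop("invalid rational: zero denominator", call. = FALSE)
  rat_reduce(num, den)
}

rat_reduce <- function(num, den) {
  g <- rat_gcd(num, den)
  if (g == 0) return(c(0, 1))
  c(num / g, den / g)
}

rat_div <- function(x, y) {
  # x / y for reduced pairs; y must be nonzero
  rat_reduce(x[1L] * y[2L], x[2L] * y[1L])
}

rat_format <- function(r) {
  if (r[2L] == 1) as.character(r[1L]) else paste0(r[1L], "/", r[2L])
}

rat_value <- function(r) r[1L] / r[2L]

# quantize a positive numeric duration to the nearest rational on a grid of
# multiples of 1/grid_den quarter notes (used only for the MIDI path, where
# notated values are unavailable and inter-onset intervals stand in)
rat_quantize <- function(x, grid_den = 12L) {
  num <- round(x * grid_den)
  if (num < 1) num <- 1
  rat_reduce(num, grid_den)
}
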