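test_that("interval extraction follows the hand-traced procedure", {
  # pitch classes (0,4,7,7,0,6,0) -> diffs (4,3,0,5,6,6) -> zeros dropped
  iv <- interval_sequence(c(60, 64, 67, 67, 72, 66, 60))
  expect_equal(as.integer(iv), c(4L, 3L, 5L, 6L, 6L))
  expect_length(interval_sequence(c(64, 64, 64)), 0)
  expect_length(interval_sequence(c(60, 72)), 0)  # octave drops
  expect_length(interval_sequence(60), 0)
  expect_error(interval_sequence(c(60, 300)), "0, 127")
})

test_that("interval sequences are transposition and octave invariant", {
  set.seed(7)
  for (rep in 1:5) {
    base <- cumsum(c(60, sample(c(1:5, 7:11), 30, replace = TRUE))) %% 40 + 40
    iv <- interval_sequence(base)
    for (shift in c(-7, 3, 12)) {
      expect_equal(as.integer(interval_sequence(base + shift)),
                   as.integer(iv))
    }
    # octave displacement of interior notes (intervals here are never 0 or
    # displaced onto 0, so the sequence is unchanged)
    disp <- base
    disp[10] <- disp[10] + 12
    expect_equal(as.integer(interval_sequence(disp)), as.integer(iv))
  }
})

test_that("tritone frequency counts interval-6 elements over |x|", {
  expect_equal(tritone_frequency(c(4, 3, 5, 6, 6)), 0.4)
  expect_equal(tritone_frequency(c(1, 2, 3)), 0)
  expect_equal(tritone_frequency(c(6, 6, 6)), 1)
  expect_error(tritone_frequency(integer(0)), "undefined")
  # unigram frequencies over the 11-letter alphabet partition to one
  set.seed(11)
  x <- sample(1:11, 200, replace = TRUE)
  freqs <- vapply(1:11, function(i) sum(x == i) / length(x), numeric(1))
  expect_equal(sum(freqs), 1)
  expect_equal(freqs[6], tritone_frequency(x))
})

test_that("the non-diatonic set matches its brute-force derivation", {
  ref <- nondiatonic_set("reference")
  bf <- nondiatonic_set("brute_force")
  expect_equal(nrow(ref), 20L)
  expect_identical(ref, bf)
  expect_equal(121L - nrow(bf), 101L)  # realizable complement
  # spot checks: (1,1) unrealizable, (2,2) realizable (C-D-E)
  expect_true(any(ref[, 1] == 1 & ref[, 2] == 1))
  expect_false(any(ref[, 1] == 2 & ref[, 2] == 2))
})

test_that("non-diatonic frequency uses |x| as denominator", {
  expect_equal(nondiatonic_frequency(c(4, 3, 5, 6, 6)), 0)
  expect_equal(nondiatonic_frequency(c(1, 1, 1)), 2 / 3)
  expect_error(nondiatonic_frequency(6), "undefined")
})

test_that("bigram frequencies cover the 121 alphabet and sum correctly", {
  bg <- bigram_frequencies(c(4, 3, 5, 6, 6))
  expect_equal(dim(bg), c(11L, 11L))
  expect_equal(bg[6, 6], 0.2)
  expect_equal(bg[4, 3], 0.2)
  expect_equal(sum(bg > 0), 4L)  # (4,3), (3,5), (5,6), (6,6)
  expect_equal(sum(bg), 4 / 5)
  set.seed(3)
  x <- sample(1:11, 57, replace = TRUE)
  expect_equal(sum(bigram_frequencies(x)), (length(x) - 1) / length(x))
})

test_that("rare-rhythm frequency uses exact rational ratio membership", {
  expect_equal(rare_rhythm_frequency(c("1", "1", "1/2", "1/2", "3/4")), 0)
  expect_equal(rare_rhythm_frequency(c("1", "1/5", "1/5")), 0.5)
  expect_equal(rare_rhythm_frequency(c("1", "1")), 0)
  # 2/3 and 3/2 allowed; 5/3 rare, exactly
  expect_equal(rare_rhythm_frequency(c("2/3", "1", "5/3")), 0.5)
  # the 'values' normalization divides by |v| instead
  expect_equal(rare_rhythm_frequency(c("1", "1/5", "1/5"),
                                     denominator = "values"), 1 / 3)
  expect_error(rare_rhythm_frequency("1"), "at least 2")
  expect_error(rare_rhythm_frequency(c("1", "0")), "positive")
})

test_that("piece feature extraction bundles all features", {
  ev <- data.frame(onset = 0:6, pitch = c(60, 64, 67, 67, 72, 66, 60),
                   note_value = c("1", "1", "1/2", "1/2", "3/4", "1", "1"))
  pf <- piece_features(ev, piece_id = "trace", composer = "x", year = 1700)
  expect_equal(pf$n_intervals, 5L)
  expect_equal(pf$tritone_freq, 0.4)
  expect_equal(pf$nondiatonic_freq, 0)
  expect_true(pf$short)
  expect_equal(sum(pf$bigram_freqs), 4 / 5)
  tab <- features_table(list(pf), include_bigrams = TRUE)
  expect_equal(ncol(tab), 9L + 121L)
  expect_equal(tab$tritone_freq, 0.4)
})

test_that("planted-rate corpora are recovered within binomial error", {
  # plant tritones at known per-piece rates; extraction must recover each
  # rate exactly (the plan fixes the count, so recovery is exact)
  dir <- withr::local_tempdir()
  plans <- list(planted_tritone_plan("p1", 400, 80, seed = 1),
                planted_tritone_plan("p2", 900, 45, seed = 2))
  make_note_fixtures(plans, dir)
  f1 <- piece_features(read_piece(file.path(dir, "p1.txt")))
  f2 <- piece_features(read_piece(file.path(dir, "p2.txt")))
  expect_equal(f1$tritone_freq, 80 / 400)
  expect_equal(f2$tritone_freq, 45 / 900)
  # and a sampled-rate corpus lands within 3 binomial SDs
  set.seed(9)
  theta <- 0.1
  n <- 600
  iv <- ifelse(runif(n) < theta, 6L, sample(setdiff(1:11, 6L), n, TRUE))
  make_note_fixtures(list(list(id = "samp", intervals = iv)), dir)
  fs <- piece_features(read_piece(file.path(dir, "samp.txt")))
  expect_lt(abs(fs$tritone_freq - theta), 3 * sqrt(theta * (1 - theta) / n))
})
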