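test_that("reweighted density reduces to known closed forms", {
  p <- beta_params(2, 2)
  expect_equal(reweighted_density(p, selection_params(0, 0), 0.5), 1.5)
  expect_equal(reweighted_density(p, selection_params(0, 1), 0.5),
               1.5 * exp(-1.5), tolerance = 1e-12)
  expect_equal(reweighted_density(p, selection_params(1, 0), 0.5), 2.25)
  expect_error(selection_params(-1.5, 0), "ill-defined")
  # integrability guard: (1+beta_T)(a-1) must exceed -1
  expect_error(reweighted_density(beta_params(0.2, 2),
                                  selection_params(0.5, 0), 0.5),
               "ill-defined")
})

test_that("the SCE update is the identity without selection", {
  for (m in list(moment_pair(0.2, 0.1), moment_pair(0.02, 0.012),
                 moment_pair(0.5, 0.2))) {
    out <- sce_update(m, selection_params(0, 0))
    expect_lt(abs(out$mu - m$mu), 1e-8)
    expect_lt(abs(out$sigma - m$sigma), 1e-8)
  }
})

test_that("typicality-only closed form matches direct substitution", {
  out <- typicality_closed_form(beta_params(2, 3), 1)
  expect_equal(c(out$a, out$b), c(3, 5))
  id <- typicality_closed_form(beta_params(2, 3), 0)
  expect_equal(c(id$a, id$b), c(2, 3))
  half <- typicality_closed_form(beta_params(3, 12), 0.5)
  expect_equal(c(half$a, half$b), c(4, 17.5))
  # the mode is invariant under the closed-form map
  expect_equal(beta_mode(half), 2 / 13, tolerance = 1e-14)
  p <- beta_params(2.7, 9.3)
  for (bT in c(0.1, 0.5, 2)) {
    expect_lt(abs(beta_mode(typicality_closed_form(p, bT)) - beta_mode(p)),
              1e-10)
  }
})

test_that("quadrature update agrees with the typicality closed form", {
  # dual-route check: numerical moment matching vs exact shape recursion
  for (bT in c(0.1, 0.5, 1)) {
    m <- moments_from_beta(beta_params(2, 3))
    p <- beta_params(2, 3)
    for (t in 1:20) {
      m <- sce_update(m, selection_params(bT, 0))
      p <- typicality_closed_form(p, bT)
      back <- beta_from_moments(m)
      expect_lt(abs(back$a / p$a - 1), 1e-6)
      expect_lt(abs(back$b / p$b - 1), 1e-6)
    }
  }
  # the spec's worked one-step case: (3,12) under beta_T = 1 -> (5,23)
  one <- sce_update(moment_pair(0.2, 0.1), selection_params(1, 0))
  target <- moments_from_beta(beta_params(5, 23))
  expect_lt(abs(one$mu - target$mu), 1e-6)
  expect_lt(abs(one$sigma - target$sigma), 1e-6)
})

test_that("novelty-only updates agree with a dense Riemann oracle", {
  cases <- list(c(0.02, 0.012, 0, 1), c(0.02, 0.01, 0, 1),
                c(0.05, 0.03, 0, 0.5), c(0.02, 0.01, 0.2, 1))
  for (cs in cases) {
    oracle <- riemann_reweighted_moments(cs[1], cs[2], cs[3], cs[4], n = 4e5)
    got <- sce_update(moment_pair(cs[1], cs[2]),
                      selection_params(cs[3], cs[4]))
    expect_lt(abs(got$mu / oracle$mu - 1), 1e-4)
    expect_lt(abs(got$sigma / oracle$sigma - 1), 1e-3)
  }
  # novelty raises both mean and SD from a rare-feature state
  nov <- sce_update(moment_pair(0.02, 0.012), selection_params(0, 1))
  expect_gt(nov$mu, 0.02)
  expect_gt(nov$sigma, 0.012)
})

test_that("selection peaks solve phi = 1/beta_N with equal heights", {
  p <- beta_params(2, 2)
  pk <- selection_peaks(p, 1)
  # analytic oracle: 6 theta (1 - theta) = 1
  expect_equal(pk[1], (1 - sqrt(1 / 3)) / 2, tolerance = 1e-10)
  expect_equal(pk[2], (1 + sqrt(1 / 3)) / 2, tolerance = 1e-10)
  heights <- reweighted_density(p, selection_params(0, 1), pk)
  expect_equal(heights, rep(exp(-1), 2), tolerance = 1e-8)
  # equal heights 1/(e beta_N) across shapes and strengths
  for (bN in c(0.8, 2, 5)) {
    for (shapes in list(c(2, 5), c(3, 12))) {
      q <- beta_params(shapes[1], shapes[2])
      pk2 <- selection_peaks(q, bN)
      if (length(pk2) == 2L) {
        h <- reweighted_density(q, selection_params(0, bN), pk2)
        expect_equal(h, rep(1 / (exp(1) * bN), 2), tolerance = 1e-8)
      }
    }
  }
  expect_length(selection_peaks(p, 0.1), 0)
  expect_error(selection_peaks(beta_params(1, 5), 1), "a > 1")
})

test_that("orbits reproduce the three selection regimes", {
  # no selection: fixed map
  fixed <- sce_iterate(moment_pair(0.11, 0.07), selection_params(0, 0), 10)
  expect_true(all(abs(fixed$mu - 0.11) < 1e-6))
  expect_true(all(abs(fixed$sigma - 0.07) < 1e-6))

  # typicality only: SD to zero, mean to the (invariant) mode
  typ <- sce_iterate(moment_pair(0.2, 0.1), selection_params(0.5, 0), 200)
  expect_false(attr(typ, "terminated"))
  s <- typ$sigma
  expect_true(all(diff(s[s > 1e-8]) < 0))
  expect_lt(s[length(s)], 1e-6)
  expect_true(all(diff(typ$mu) < 1e-12))
  expect_lt(abs(typ$mu[nrow(typ)] - 2 / 13), 1e-4)

  # novelty only: mean increases and converges to 1/2
  nov <- sce_iterate(moment_pair(0.05, 0.03), selection_params(0, 0.5), 80)
  expect_false(attr(nov, "terminated"))
  expect_gt(min(diff(nov$mu)), -1e-9)
  expect_lt(abs(nov$mu[nrow(nov)] - nov$mu[nrow(nov) - 1L]), 1e-6)
  expect_equal(nov$mu[nrow(nov)], 0.5, tolerance = 1e-3)
})

test_that("ratio diagnostics flag plateaus and growth factors", {
  fixed <- sce_iterate(moment_pair(0.2, 0.1), selection_params(0, 0), 5)
  d <- ratio_diagnostics(fixed)
  expect_true(all(abs(d$ratio - 0.5) < 1e-6))
  expect_true(all(abs(d$growth_factor[1:5] - 1) < 1e-6))

  typ <- sce_iterate(moment_pair(0.2, 0.1), selection_params(0.5, 0), 30)
  dt <- ratio_diagnostics(typ)
  expect_true(all(diff(dt$ratio) < 0))
  expect_true(all(dt$growth_factor[1:30] <= 1 + 1e-12))

  nov <- sce_iterate(moment_pair(0.02, 0.01), selection_params(0, 1), 40)
  dn <- ratio_diagnostics(nov)
  plateau <- attr(dn, "plateau")
  expect_false(is.null(plateau))
  expect_gt(plateau$mean_ratio, 0)
  expect_lt(plateau$mean_ratio, 1)

  expect_error(ratio_diagnostics(fixed[1, , drop = FALSE]), "at least 2")
})

test_that("the novelty slow manifold behaves as the theory predicts", {
  # plateau ratio below one, non-increasing in beta_N; read at a tolerance
  # matching the small 2-cycle that forms around the fixed state for
  # stronger novelty
  plateaus <- vapply(c(0.5, 1, 2), function(bN) {
    tr <- sce_iterate(moment_pair(0.02, 0.01), selection_params(0, bN), 60)
    attr(ratio_diagnostics(tr, ratio_tol = 0.02), "plateau")$mean_ratio
  }, numeric(1))
  expect_true(all(plateaus > 0 & plateaus < 1))
  expect_true(all(diff(plateaus) <= 1e-3))

  # near-exponential growth: one-step growth factors at fixed ratio 0.6 stay
  # within the same order of magnitude across a decade of mu
  for (bN in c(0.5, 1)) {
    gf <- vapply(c(0.002, 0.005, 0.01, 0.02), function(mu) {
      sce_update(moment_pair(mu, 0.6 * mu), selection_params(0, bN))$mu / mu
    }, numeric(1))
    expect_lt(max(gf) / min(gf), 2)
    expect_true(all(gf > 1))
  }

  # growth-rate insensitivity: doubling beta_N changes the one-step growth
  # factor by well under 50%
  g1 <- sce_update(moment_pair(0.02, 0.012), selection_params(0, 0.5))$mu / 0.02
  g2 <- sce_update(moment_pair(0.02, 0.012), selection_params(0, 1))$mu / 0.02
  expect_lt(abs(g2 - g1) / g1, 0.5)
})

test_that("mixed selection balances the SD at a fixed value", {
  tr <- sce_iterate(moment_pair(0.02, 0.01), selection_params(0.2, 1), 80)
  n <- nrow(tr)
  expect_lt(abs(tr$sigma[n] - tr$sigma[n - 1L]), 1e-8)
  sig_star <- tr$sigma[n]
  above <- sce_update(moment_pair(0.3, min(sig_star * 1.5, 0.28)),
                      selection_params(0.2, 1))
  below <- sce_update(moment_pair(0.3, sig_star * 0.5),
                      selection_params(0.2, 1))
  expect_lt(above$sigma, min(sig_star * 1.5, 0.28))
  expect_gt(below$sigma, sig_star * 0.5)
})

test_that("trajectories carry years and survive a CSV round trip", {
  tr <- sce_iterate(moment_pair(0.2, 0.1), selection_params(0.3, 0), 4,
                    time_map = list(start_year = 1500,
                                    years_per_generation = 25))
  expect_equal(tr$year, seq(1500, 1600, by = 25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$mu, tr$mu, tolerance = 1e-12)
  expect_equal(back$year, tr$year)
  expect_identical(attr(back, "model"), "sce")
})
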