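sce_series <- function(mu, sigma, beta_T, beta_N, T) {
  tr <- sce_iterate(moment_pair(mu, sigma),
                    selection_params(beta_T, beta_N), T - 1L)
  data.frame(mean = tr$mu, sd = tr$sigma)
}

test_that("the objective is zero at the generating parameters and additive", {
  s <- sce_series(0.02, 0.012, 0.2, 1, 12)
  expect_lt(fit_objective(c(0.2, 1), "sce", s), 1e-10)
  expect_gt(fit_objective(c(0.2, 1.2), "sce", s), 1e-6)
  s2 <- sce_series(0.05, 0.03, 0.2, 1, 12)
  expect_equal(fit_objective(c(0.2, 1), "sce", list(s, s2)),
               fit_objective(c(0.2, 1), "sce", s) +
                 fit_objective(c(0.2, 1), "sce", s2), tolerance = 1e-12)
  # missing sd at the earliest point cannot initialize
  s_bad <- s
  s_bad$sd[1] <- NA
  expect_error(fit_objective(c(0.2, 1), "sce", s_bad), "initialize")
})

test_that("noiseless parameter recovery is near-exact for both models", {
  # SCE: three parameter draws, fixed seed
  set.seed(17)
  draws <- cbind(beta_T = runif(3, 0.05, 0.6), beta_N = runif(3, 0.3, 2))
  for (i in seq_len(nrow(draws))) {
    s <- sce_series(0.02, 0.012, draws[i, 1], draws[i, 2], 10)
    f <- fit_model(s, model = "sce", grid_points = 8)
    expect_lt(abs(f$params$beta_T - draws[i, 1]), 1e-3)
    expect_lt(abs(f$params$beta_N - draws[i, 2]), 1e-3)
    expect_lt(f$objective, 1e-8)
  }
  # log-potential: three draws including a negative coefficient
  set.seed(18)
  betas <- c(runif(2, 0.1, 2), -0.4)
  for (beta in betas) {
    tr <- logpotential_iterate(lognormal_params(-3, 0.5), beta, 12)
    s <- data.frame(mean = tr$mu, sd = tr$sigma)
    f <- fit_model(s, model = "logpotential")
    expect_lt(abs(f$params - beta), 1e-3)
    expect_lt(f$objective, 1e-8)
  }
  # a flat series is explained by beta = 0
  flat <- data.frame(mean = rep(0.1, 6), sd = rep(0.05, 6))
  f0 <- fit_model(flat, model = "logpotential")
  expect_lt(abs(f0$params), 1e-6)
})

test_that("recovery survives 5% observation noise on the moments", {
  # a slow-growth configuration, as in empirical series: the uniform
  # distribution is a fixed point of the map for every parameter value, so
  # once an orbit saturates its points carry no parameter information and
  # no estimator could identify the coefficients under noise
  tr <- sce_iterate(moment_pair(0.02, 0.012), selection_params(0.2, 0.15), 15)
  set.seed(42)
  s <- data.frame(mean = tr$mu * (1 + rnorm(16, 0, 0.05)),
                  sd = tr$sigma * (1 + rnorm(16, 0, 0.05)))
  f <- fit_model(s, model = "sce", grid_points = 8)
  expect_lt(abs(f$params$beta_T - 0.2) / 0.2, 0.25)
  expect_lt(abs(f$params$beta_N - 0.15) / 0.15, 0.25)
})

test_that("one SCE parameter pair fits two series where one beta cannot", {
  # two series from different initial conditions, same selection regime
  s1 <- sce_series(0.02, 0.012, 0.2, 1, 12)
  s2 <- sce_series(0.06, 0.03, 0.2, 1, 12)
  sce_joint <- fit_model(list(s1, s2), model = "sce", grid_points = 8)
  expect_lt(sce_joint$objective, 1e-8)
  log_joint <- fit_model(list(s1, s2), model = "logpotential")
  expect_gt(log_joint$objective, 10 * max(sce_joint$objective, 1e-8))
})

test_that("the SCE model cannot hold a ratio the log-potential conserves", {
  # data generated by the log-potential with sigma/mu pinned away from the
  # SCE attractor: the log-potential fit is exact, the SCE fit is not
  tr <- logpotential_iterate(lognormal_from_moments(list(mu = 0.05,
                                                         sigma = 0.015)),
                             0.5, 11)
  s <- data.frame(mean = tr$mu, sd = tr$sigma)
  f_log <- fit_model(s, model = "logpotential")
  expect_lt(abs(f_log$params - 0.5), 1e-3)
  f_sce <- fit_model(s, model = "sce", grid_points = 8)
  expect_gt(f_sce$objective, 10 * max(f_log$objective, 1e-10))
})

test_that("forecasts continue the fitted map", {
  s <- sce_series(0.2, 0.1, 0.5, 0, 10)  # typicality-dominated, decreasing
  f <- fit_model(s, model = "sce", grid_points = 8)
  fc <- forecast_model(f, horizon = 20)
  expect_equal(nrow(fc), 21L)
  dmu <- abs(diff(fc$mu))
  expect_true(all(diff(dmu) < 1e-12))  # convergence: shrinking steps
  h0 <- forecast_model(f, horizon = 0)
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$mu, tail(f$trajectories[[1]]$mu, 1), tolerance = 1e-12)
  # negative-beta log-potential forecast decays geometrically
  trl <- logpotential_iterate(lognormal_from_moments(list(mu = 0.3,
                                                          sigma = 0.1)),
                              -0.5, 8)
  sl <- data.frame(mean = trl$mu, sd = trl$sigma)
  fl <- fit_model(sl, model = "logpotential")
  fcl <- forecast_model(fl, horizon = 5)
  g <- fcl$mu[-1] / fcl$mu[-6]
  expect_lt(max(abs(g - g[1])), 1e-10)
  expect_lt(g[1], 1)
})

test_that("fit results serialize to JSON", {
  s <- sce_series(0.2, 0.1, 0.5, 0, 6)
  f <- fit_model(s, model = "sce", grid_points = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$model, "sce")
  expect_equal(parsed$params$beta_T, f$params$beta_T, tolerance = 1e-9)
  expect_equal(parsed$objective, f$objective, tolerance = 1e-9)
})
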