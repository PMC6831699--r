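#' Squared-error objective of a dynamical model against window series
#'
#' For each series the model is initialized at the mean and SD of the
#' earliest time point and iterated one generation per data time step
#' (`generations_per_step` allows finer model time). The objective is the
#' sum over series and time points of the squared residuals of both the
#' mean and the SD,
#' \eqn{\sum_s \sum_t [(\mu^{model}_t - \mu^{data}_t)^2 +
#' (\sigma^{model}_t - \sigma^{data}_t)^2]}. Time points with missing SD
#' contribute only the mean residual. Parameter values whose orbit leaves
#' the representable region score `Inf`.
#'
#' @param params for `model = "sce"` a [selection_params()] (or
#'   `c(beta_T, beta_N)`); for `model = "logpotential"` a scalar `beta`.
#' @param model `"sce"` or `"logpotential"`.
#' @param series a `window_stats` data frame or a list of them; each needs
#'   a defined mean and SD at its earliest point and >= 2 time points.
#' @param generations_per_step model generations per data step (default 1).
#' @return The scalar objective (nonnegative, possibly `Inf`).
#' @export
fit_objective <- function(params, model = c("sce", "logpotential"), series,
                          generations_per_step = 1L) {
  model <- match.arg(model)
  series <- as_series_list(series)
  total <- 0
  for (s in series) {
    pred <- tryCatch(
      predict_series(params, model, s, generations_per_step),
      error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    res_mu <- pred$mu - s$mean
    res_sd <- pred$sigma - s$sd
    res_sd[is.na(res_sd)] <- 0
    total <- total + sum(res_mu^2) + sum(res_sd^2)
  }
  total
}

as_series_list <- function(series) {
  if (is.data.frame(series)) series <- list(series)
  stopifnot(is.list(series), length(series) >= 1L)
  for (s in series) {
    if (!is.data.frame(s) || !all(c("mean", "sd") %in% names(s)) ||
        nrow(s) < 2L) {
      stop("fit: each series needs columns 'mean' and 'sd' and >= 2 time points",
           call. = FALSE)
    }
    if (is.na(s$mean[1L]) || is.na(s$sd[1L])) {
      stop("fit: cannot initialize the model: mean/sd undefined at the earliest time point",
           call. = FALSE)
    }
  }
  series
}

# model means/SDs at the data time points, starting from the earliest point
predict_series <- function(params, model, s, gps = 1L) {
  n_pts <- nrow(s)
  n_gen <- (n_pts - 1L) * gps
  if (model == "sce") {
    sel <- if (inherits(params, "selection_params")) params
           else selection_params(params[[1L]], params[[2L]])
    init <- moment_pair(s$mean[1L], s$sd[1L])
    tr <- sce_iterate(init, sel, n_gen, rel_tol = 1e-9)
    if (isTRUE(attr(tr, "terminated"))) {
      stop("orbit left the representable region", call. = FALSE)
    }
  } else {
    beta <- if (is.list(params)) params$beta else as.numeric(params)[1L]
    init <- lognormal_from_moments(list(mu = s$mean[1L], sigma = s$sd[1L]))
    tr <- logpotential_iterate(init, beta, n_gen)
  }
  idx <- 1L + gps * (seq_len(n_pts) - 1L)
  list(mu = tr$mu[idx], sigma = tr$sigma[idx])
}

#' Fit selection coefficients to window series
#'
#' Least-squares fitting of the SCE coefficients \eqn{(\beta_T, \beta_N)}
#' or the log-potential coefficient \eqn{\beta} to one or more empirical
#' mean/SD series, jointly: a single parameter set must fit all series,
#' each from its own initial condition. The optimizer is a deterministic
#' coarse grid (log-spaced above 0.1) followed by derivative-free local
#' refinement from the best grid point, so results are reproducible and
#' robust to the non-smoothness of the objective near the
#' representable-region boundary.
#'
#' @param series a `window_stats` data frame or list of them.
#' @param model `"sce"` or `"logpotential"`.
#' @param beta_max box bound on the coefficients (default 20); the SCE box
#'   is `[0, beta_max]^2`, the log-potential box `[-beta_max, beta_max]`.
#' @param grid_points grid density per dimension (default 21).
#' @param generations_per_step model generations per data step (default 1).
#' @return A list of class `fit_result`: `model`, `params` (a
#'   [selection_params()] or scalar `beta`), `objective`,
#'   `per_series_rmse` (RMSE over the concatenated mean and SD residuals,
#'   divisor `2T`), `trajectories` (fitted model states per series), and
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' tr <- sce_iterate(moment_pair(0.02, 0.012), selection_params(0.2, 1), 10)
#' s <- data.frame(mean = tr$mu, sd = tr$sigma)
#' fit_model(s, model = "sce")$params
#' }
fit_model <- function(series, model = c("sce", "logpotential"),
                      beta_max = 20, grid_points = 21L,
                      generations_per_step = 1L) {
  model <- match.arg(model)
  series <- as_series_list(series)
  obj <- function(p) fit_objective(p, model, series, generations_per_step)
  pos_grid <- c(0, exp(seq(log(0.1), log(beta_max),
                           length.out = grid_points - 1L)))
  if (model == "sce") {
    grid <- as.matrix(expand.grid(beta_T = pos_grid, beta_N = pos_grid))
    vals <- apply(grid, 1L, function(p) obj(c(p[1L], p[2L])))
    if (all(!is.finite(vals))) {
      stop("fit_model: objective infinite at every grid point", call. = FALSE)
    }
    best <- grid[which.min(vals), ]
    pen <- function(p) {
      if (any(p < 0) || any(p > beta_max)) return(1e12)
      v <- obj(p)
      if (!is.finite(v)) 1e12 else v
    }
    opt <- stats::optim(best, pen, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 1500))
    # polish: restart once from the first optimum (Nelder-Mead can stall)
    opt2 <- stats::optim(opt$par, pen, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 1500))
    if (opt2$value < opt$value) opt <- opt2
    params <- selection_params(opt$par[[1L]], opt$par[[2L]])
    objective <- opt$value
  } else {
    grid <- seq(-beta_max, beta_max, length.out = 2L * grid_points - 1L)
    vals <- vapply(grid, obj, numeric(1))
    if (all(!is.finite(vals))) {
      stop("fit_model: objective infinite at every grid point", call. = FALSE)
    }
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    o <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-12)
    params <- o$minimum
    objective <- o$objective
  }
  trajectories <- lapply(series, function(s) {
    pred <- predict_series(params, model, s, generations_per_step)
    data.frame(step = seq_len(nrow(s)), mu = pred$mu, sigma = pred$sigma,
               data_mean = s$mean, data_sd = s$sd)
  })
  per_series_rmse <- vapply(seq_along(series), function(i) {
    s <- series[[i]]
    p <- trajectories[[i]]
    res_sd <- p$sigma - s$sd
    res_sd[is.na(res_sd)] <- 0
    sqrt((sum((p$mu - s$mean)^2) + sum(res_sd^2)) / (2 * nrow(s)))
  }, numeric(1))
  structure(list(model = model, params = params, objective = objective,
                 per_series_rmse = per_series_rmse,
                 trajectories = trajectories,
                 config = list(beta_max = beta_max, grid_points = grid_points,
                               generations_per_step = generations_per_step,
                               series = series)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s model>\n", x$model))
  if (x$model == "sce") {
    cat(sprintf("  beta_T = %.6g, beta_N = %.6g\n",
                x$params$beta_T, x$params$beta_N))
  } else {
    cat(sprintf("  beta = %.6g\n", x$params))
  }
  cat(sprintf("  objective = %.6g; per-series RMSE: %s\n", x$objective,
              paste(signif(x$per_series_rmse, 4), collapse = ", ")))
  invisible(x)
}

#' Forecast a fitted model beyond the data
#'
#' Continues the fitted map from the final fitted state of one series for
#' `horizon` further generations. With a typicality-dominated SCE fit the
#' forecast mean converges (toward the invariant mode) as the SD shrinks;
#' a log-potential fit with negative `beta` decays geometrically.
#'
#' @param fit a [fit_model()] result.
#' @param horizon number of generations past the last data point (>= 0).
#' @param series_index which fitted series to continue (default 1).
#' @return A `trajectory` data frame whose generation 0 is the last fitted
#'   state.
#' @export
forecast_model <- function(fit, horizon, series_index = 1L) {
  stopifnot(inherits(fit, "fit_result"), horizon >= 0,
            horizon == round(horizon))
  tr <- fit$trajectories[[series_index]]
  last <- tr[nrow(tr), ]
  if (fit$model == "sce") {
    init <- moment_pair(last$mu, last$sigma)
    if (horizon == 0L) {
      return(build_trajectory(list(init), model = "sce", sel = fit$params))
    }
    sce_iterate(init, fit$params, horizon)
  } else {
    init <- lognormal_from_moments(list(mu = last$mu, sigma = last$sigma))
    if (horizon == 0L) {
      return(build_trajectory(list(lognormal_moments(init)),
                              model = "logpotential", sel = fit$params))
    }
    logpotential_iterate(init, fit$params, horizon)
  }
}

#' Serialize a fit result as JSON
#'
#' @param fit a [fit_model()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  params <- if (fit$model == "sce") {
    list(beta_T = fit$params$beta_T, beta_N = fit$params$beta_N)
  } else {
    list(beta = fit$params)
  }
  jsonlite::write_json(
    list(model = fit$model, params = params, objective = fit$objective,
         per_series_rmse = fit$per_series_rmse),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
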