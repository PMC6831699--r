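#' Selection coefficients of the statistical creator-evaluator model
#'
#' The evaluator weights a data chunk with frequency \eqn{\theta} by
#' \eqn{\varphi(\theta)^{\beta_T} \exp[-\beta_N \varphi(\theta)]}: the first
#' factor rewards typicality (chunks probable under the evaluator's model),
#' the second penalizes lack of novelty (chunks similar to abundant existing
#' data). `beta_T < -1` puts infinite weight on zero-probability chunks and
#' is rejected as ill-defined. Negative `beta_N` and `beta_T` in (-1, 0) are
#' accepted but outside the analyzed regime.
#'
#' @param beta_T typicality coefficient, `> -1`.
#' @param beta_N novelty coefficient, any real.
#' @return An object of class `selection_params`.
#' @export
#' @examples
#' selection_params(beta_T = 0.2, beta_N = 1)
selection_params <- function(beta_T = 0, beta_N = 0) {
  if (!is.numeric(beta_T) || !is.numeric(beta_N) || length(beta_T) != 1L ||
      length(beta_N) != 1L || !is.finite(beta_T) || !is.finite(beta_N)) {
    stop("selection_params: coefficients must be finite scalars", call. = FALSE)
  }
  if (beta_T <= -1) {
    stop("selection_params: beta_T <= -1 is ill-defined (infinite weight on zero-probability chunks)",
         call. = FALSE)
  }
  structure(list(beta_T = as.numeric(beta_T), beta_N = as.numeric(beta_N)),
            class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat(sprintf("Selection: beta_T = %g (typicality), beta_N = %g (novelty)\n",
              x$beta_T, x$beta_N))
  invisible(x)
}

as_selection_params <- function(x) {
  if (inherits(x, "selection_params")) return(x)
  if (is.list(x) && all(c("beta_T", "beta_N") %in% names(x))) {
    return(selection_params(x$beta_T, x$beta_N))
  }
  stop("expected a 'selection_params' object", call. = FALSE)
}

.musevol_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; memoized per order
gl_rule <- function(n) {
  key <- as.character(n)
  if (!is.null(.musevol_cache[[key]])) return(.musevol_cache[[key]])
  k <- seq_len(n - 1L)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- off
  J[cbind(k + 1L, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  rule <- list(x = e$values, w = 2 * e$vectors[1L, ]^2)
  .musevol_cache[[key]] <- rule
  rule
}

# fixed-order Gauss-Legendre integral of g on [lo, hi]
gauss_legendre_01 <- function(g, lo, hi, n = 128L) {
  r <- gl_rule(n)
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  sum(r$w * g(mid + half * r$x)) * half
}

# log of the unnormalized reweighted density; vectorized over theta
log_reweighted <- function(a, b, beta_T, beta_N, theta) {
  lphi <- stats::dbeta(theta, a, b, log = TRUE)
  (1 + beta_T) * lphi - beta_N * exp(lphi)
}

check_integrable <- function(params, sel) {
  a_eff <- 1 + (1 + sel$beta_T) * (params$a - 1)
  b_eff <- 1 + (1 + sel$beta_T) * (params$b - 1)
  if (a_eff <= 0 || b_eff <= 0) {
    stop(sprintf(
      "selection is ill-defined: effective exponents (1+beta_T)(a-1) = %g, (1+beta_T)(b-1) = %g must both exceed -1",
      a_eff - 1, b_eff - 1), call. = FALSE)
  }
  invisible(TRUE)
}

#' Selection-reweighted (unnormalized) density
#'
#' Evaluates \eqn{\tilde\varphi(\theta) = \varphi(\theta)^{1+\beta_T}
#' \exp[-\beta_N\,\varphi(\theta)]}, the distribution of the selected data in
#' the infinite-data limit, up to normalization. With
#' `beta_T = beta_N = 0` this is exactly the beta density.
#'
#' @param params a [beta_params()] object.
#' @param sel a [selection_params()] object.
#' @param theta frequency values strictly in (0, 1) (vectorized).
#' @return Nonnegative density values (unnormalized).
#' @export
reweighted_density <- function(params, sel, theta) {
  params <- as_beta_params(params)
  sel <- as_selection_params(sel)
  check_integrable(params, sel)
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta <= 0) || any(theta >= 1)) {
    stop("reweighted_density: 'theta' must lie strictly in (0, 1)", call. = FALSE)
  }
  exp(log_reweighted(params$a, params$b, sel$beta_T, sel$beta_N, theta))
}

# Moments of the normalized reweighted density by adaptive quadrature.
#
# The typicality factor phi^(1+beta_T) is itself (proportional to) a beta
# density with shapes a_eff = 1 + (1+beta_T)(a-1), b_eff likewise, so the
# integration variable is substituted as theta = qbeta(u, a_eff, b_eff):
# moments become integrals over u of theta(u)^k times the bounded novelty
# weight exp(-beta_N * phi(theta(u))) (shifted so its maximum is 1). This
# keeps the integrand tame even for the extremely peaked shapes reached
# late in typicality-only orbits. The normalization constant cancels in the
# moment ratios, and the variance is computed as a central moment in a
# second pass to avoid catastrophic cancellation when sigma is tiny.
reweighted_moments <- function(params, sel, rel_tol = 1e-10) {
  a <- params$a
  b <- params$b
  a_eff <- 1 + (1 + sel$beta_T) * (a - 1)
  b_eff <- 1 + (1 + sel$beta_T) * (b - 1)
  if (max(a_eff, b_eff) <= 1e12) {
    # qbeta can emit NaN warnings at extreme shape/probability pairs; the
    # NaNs are detected and routed to the adaptive fallback below
    theta_of_u <- function(u) suppressWarnings(stats::qbeta(u, a_eff, b_eff))
  } else {
    # beyond qbeta's reach the effective beta is normal to ~1e-6 relative
    # (skewness ~ 1/sqrt(a_eff)); only reached by near-degenerate states
    s_eff <- a_eff + b_eff
    mu_eff <- a_eff / s_eff
    sd_eff <- sqrt(a_eff * b_eff / (s_eff + 1)) / s_eff
    theta_of_u <- function(u) {
      pmin(pmax(mu_eff + sd_eff * stats::qnorm(u), 1e-12), 1 - 1e-12)
    }
  }
  # shift the novelty exponent so the weight's maximum is exactly 1
  probe <- theta_of_u(seq(1e-9, 1 - 1e-9, length.out = 513))
  probe <- probe[probe > 0 & probe < 1]
  shift <- max(-sel$beta_N * stats::dbeta(probe, a, b), 0)
  weight <- function(theta) exp(-sel$beta_N * stats::dbeta(theta, a, b) - shift)
  # split u along the transition layers of the novelty weight: where a
  # sharply peaked phi crosses levels 2^j / beta_N the weight falls from
  # ~1 to e^-32 over a sliver of u that a blind adaptive rule can miss
  splits <- 0.5
  if (sel$beta_N > 0 && a > 1 && b > 1) {
    mode <- (a - 1) / (a + b - 2)
    phimax <- stats::dbeta(mode, a, b)
    eps <- .Machine$double.eps
    th_splits <- numeric(0)
    for (level in (2^(0:5)) / sel$beta_N) {
      if (phimax <= level) break
      g <- function(theta) stats::dbeta(theta, a, b) - level
      # a crossing may sit below double resolution of the boundary (e.g.
      # a barely above 1 with the density still over the level at eps);
      # skip the side rather than fail, the dyadic panels cover it
      for (side in list(c(eps, mode), c(mode, 1 - eps))) {
        if (g(side[1L]) * g(side[2L]) < 0) {
          th_splits <- c(th_splits,
                         stats::uniroot(g, lower = side[1L], upper = side[2L],
                                        tol = 1e-13)$root)
        }
      }
    }
    if (length(th_splits)) {
      splits <- sort(unique(c(stats::pbeta(th_splits, a_eff, b_eff), 0.5)))
    }
  }
  bounds <- sort(unique(pmin(pmax(c(0, splits, 1), 0), 1)))
  # Fast path: a fixed-order composite Gauss-Legendre rule over the split
  # u-grid, dyadically refined toward u = 0 and u = 1 where theta(u) has
  # algebraic singularities in its derivatives. One vectorized qbeta sweep
  # then serves all three moments. Negative beta_N (weight peaked, splits
  # unavailable) takes the adaptive path below.
  if (sel$beta_N >= 0) {
    dyadic <- 2^-(1:45)
    bounds <- sort(unique(c(bounds, dyadic, 1 - dyadic)))
    r <- gl_rule(20L)
    half <- diff(bounds) / 2
    mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
    u_all <- as.vector(outer(r$x, half) + rep(mids, each = length(r$x)))
    w_all <- as.vector(outer(r$w, half))
    theta <- theta_of_u(u_all)
    wt <- w_all * weight(theta)
    m0 <- sum(wt)
    if (is.finite(m0) && m0 > 0) {
      m1 <- sum(theta * wt) / m0
      v <- sum((theta - m1)^2 * wt) / m0
      if (is.finite(v) && v > 0) {
        return(list(mu = m1, sigma = sqrt(v)))
      }
    }
    # degenerate sweep (all weight below double precision): fall through
  }
  quad <- function(g) {
    total <- 0
    for (i in seq_len(length(bounds) - 1L)) {
      piece <- NULL
      # late typicality-only states contract below the precision of qbeta,
      # leaving noise the adaptive rule cannot resolve; relax, then fall
      # back to a fixed high-order rule
      for (tol in c(rel_tol, 1e-8, 1e-6)) {
        piece <- tryCatch(
          stats::integrate(g, bounds[i], bounds[i + 1L], rel.tol = tol,
                           abs.tol = 0, subdivisions = 500L)$value,
          error = function(e) NULL)
        if (!is.null(piece)) break
      }
      if (is.null(piece)) piece <- gauss_legendre_01(g, bounds[i], bounds[i + 1L])
      total <- total + piece
    }
    total
  }
  m0 <- quad(function(u) weight(theta_of_u(u)))
  if (!is.finite(m0) || m0 <= 0) {
    stop("sce_update: quadrature failed to normalize the reweighted density",
         call. = FALSE)
  }
  m1 <- quad(function(u) {
    theta <- theta_of_u(u)
    theta * weight(theta)
  }) / m0
  v <- quad(function(u) {
    theta <- theta_of_u(u)
    (theta - m1)^2 * weight(theta)
  }) / m0
  if (!is.finite(v) || v <= 0) {
    stop("sce_update: quadrature produced a non-positive variance", call. = FALSE)
  }
  list(mu = m1, sigma = sqrt(v))
}

#' One generation of the SCE map
#'
#' Applies selection reweighting to the current beta model and learns the
#' next-generation model by moment matching: the returned \eqn{(\mu, \sigma)}
#' are the exact mean and SD of the normalized reweighted density, computed
#' by adaptive quadrature, and determine the next beta shapes through
#' [beta_from_moments()].
#'
#' @param moments a [moment_pair()] — the current state.
#' @param sel a [selection_params()] object.
#' @param rel_tol quadrature relative tolerance (default `1e-10`).
#' @return A [moment_pair()] for the next generation. If the updated moments
#'   leave the beta-representable region an error of class
#'   `musevol_state_error` is signalled (never silently clipped).
#' @export
#' @examples
#' sce_update(moment_pair(0.2, 0.1), selection_params(beta_T = 1, beta_N = 0))
sce_update <- function(moments, sel, rel_tol = 1e-10) {
  moments <- as_moment_pair(moments)
  sel <- as_selection_params(sel)
  params <- beta_from_moments(moments)
  check_integrable(params, sel)
  m <- reweighted_moments(params, sel, rel_tol = rel_tol)
  if (m$mu <= 0 || m$mu >= 1 || !is_beta_representable(m$mu, m$sigma)) {
    stop(structure(class = c("musevol_state_error", "error", "condition"),
                   list(message = sprintf(
                     "sce_update: updated moments (mu = %g, sigma = %g) left the beta-representable region",
                     m$mu, m$sigma), call = NULL)))
  }
  moment_pair(m$mu, m$sigma)
}

#' Closed-form typicality-only update
#'
#' With no novelty term the reweighted density is itself a beta density and
#' the map is exact on the shapes: \eqn{a' - 1 = (1+\beta_T)(a-1)},
#' \eqn{b' - 1 = (1+\beta_T)(b-1)}. The mode is invariant under this map,
#' which is why typicality-only orbits contract onto it.
#'
#' @param params a [beta_params()] object.
#' @param beta_T typicality coefficient, `> -1`.
#' @return A [beta_params()] for the next generation.
#' @export
typicality_closed_form <- function(params, beta_T) {
  params <- as_beta_params(params)
  if (!is.numeric(beta_T) || length(beta_T) != 1L || !is.finite(beta_T) ||
      beta_T <= -1) {
    stop("typicality_closed_form: beta_T must be a finite scalar > -1",
         call. = FALSE)
  }
  beta_params(1 + (1 + beta_T) * (params$a - 1),
              1 + (1 + beta_T) * (params$b - 1))
}

#' Peaks of the novelty-reweighted density
#'
#' Under novelty-only selection the reweighted density
#' \eqn{\varphi e^{-\beta_N \varphi}} is bimodal when the beta peak exceeds
#' \eqn{1/\beta_N}: its stationary points away from the beta mode solve
#' \eqn{\varphi(\theta) = 1/\beta_N}, and at both solutions the reweighted
#' density equals \eqn{1/(e\,\beta_N)} — the two peaks have equal height.
#'
#' @param params a [beta_params()] with `a, b > 1`.
#' @param beta_N positive novelty coefficient.
#' @param tol root-finding tolerance (default `1e-12`).
#' @return Numeric vector of peak positions: `c(theta_minus, theta_plus)`
#'   bracketing the beta mode, or `numeric(0)` when the density never
#'   reaches `1/beta_N`.
#' @export
selection_peaks <- function(params, beta_N, tol = 1e-12) {
  params <- as_beta_params(params)
  if (params$a <= 1 || params$b <= 1) {
    stop("selection_peaks: need a > 1 and b > 1", call. = FALSE)
  }
  if (!is.numeric(beta_N) || length(beta_N) != 1L || !is.finite(beta_N) ||
      beta_N <= 0) {
    stop("selection_peaks: beta_N must be a positive scalar", call. = FALSE)
  }
  k <- beta_mode(params)
  target <- 1 / beta_N
  if (stats::dbeta(k, params$a, params$b) <= target) return(numeric(0))
  g <- function(theta) stats::dbeta(theta, params$a, params$b) - target
  eps <- .Machine$double.eps
  left <- stats::uniroot(g, lower = eps, upper = k, tol = tol)$root
  right <- stats::uniroot(g, lower = k, upper = 1 - eps, tol = tol)$root
  c(left, right)
}

#' Iterate the SCE map
#'
#' Applies [sce_update()] for a given number of generations, recording both
#' the \eqn{(\mu, \sigma)} state and the equivalent beta shapes at every
#' generation. If an update leaves the beta-representable region the orbit
#' halts early and the returned trajectory is flagged `terminated`.
#'
#' @param init a [moment_pair()] — the generation-0 state.
#' @param sel a [selection_params()] object.
#' @param generations number of updates to apply (>= 1).
#' @param time_map optional list with `start_year` and `years_per_generation`
#'   to attach calendar years to generations.
#' @param rel_tol quadrature tolerance passed to [sce_update()].
#' @return A `trajectory` data frame with columns `generation`, `a`, `b`,
#'   `mu`, `sigma`, `ratio` (and `year` when `time_map` is given), plus
#'   attributes `model = "sce"`, `sel`, and `terminated` (logical).
#' @export
#' @examples
#' tr <- sce_iterate(moment_pair(0.05, 0.03), selection_params(0, 0.5), 20)
#' head(tr)
sce_iterate <- function(init, sel, generations, time_map = NULL,
                        rel_tol = 1e-10) {
  init <- as_moment_pair(init)
  sel <- as_selection_params(sel)
  if (!is.numeric(generations) || length(generations) != 1L ||
      generations < 1 || generations != round(generations)) {
    stop("sce_iterate: 'generations' must be a positive integer", call. = FALSE)
  }
  states <- vector("list", generations + 1L)
  states[[1L]] <- init
  terminated <- FALSE
  n_done <- generations
  for (t in seq_len(generations)) {
    nxt <- tryCatch(sce_update(states[[t]], sel, rel_tol = rel_tol),
                    musevol_state_error = function(e) e,
                    error = function(e) {
                      stop(sprintf("sce_iterate: update failed at generation %d: %s",
                                   t, conditionMessage(e)), call. = FALSE)
                    })
    if (inherits(nxt, "musevol_state_error")) {
      terminated <- TRUE
      n_done <- t - 1L
      break
    }
    states[[t + 1L]] <- nxt
  }
  states <- states[seq_len(n_done + 1L)]
  build_trajectory(states, model = "sce", sel = sel, time_map = time_map,
                   terminated = terminated)
}

build_trajectory <- function(states, model, sel, time_map = NULL,
                             terminated = FALSE) {
  gens <- seq_along(states) - 1L
  mu <- vapply(states, function(s) s$mu, numeric(1))
  sigma <- vapply(states, function(s) s$sigma, numeric(1))
  ab <- t(vapply(states, function(s) {
    # log-potential states need not be beta-representable; shapes are NA there
    tryCatch({
      p <- beta_from_moments(s)
      c(p$a, p$b)
    }, error = function(e) c(NA_real_, NA_real_))
  }, numeric(2)))
  df <- data.frame(generation = gens, a = ab[, 1], b = ab[, 2],
                   mu = mu, sigma = sigma, ratio = sigma / mu)
  if (!is.null(time_map)) {
    stopifnot(is.list(time_map),
              all(c("start_year", "years_per_generation") %in% names(time_map)),
              time_map$years_per_generation > 0)
    df$year <- time_map$start_year + gens * time_map$years_per_generation
  }
  structure(df, class = c("trajectory", "data.frame"),
            model = model, sel = sel, time_map = time_map,
            terminated = terminated)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<%s trajectory: %d generations%s>\n", attr(x, "model"),
              nrow(x) - 1L,
              if (isTRUE(attr(x, "terminated"))) ", terminated early" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Ratio and growth diagnostics of a trajectory
#'
#' Reports per generation the ratio \eqn{\sigma_t/\mu_t} and the mean growth
#' factor \eqn{\mu_{t+1}/\mu_t}, and flags the slow-manifold plateau: the
#' longest run of generations over which the ratio changes by less than
#' `ratio_tol` per generation. On the plateau, mean and SD grow together at
#' a nearly constant ratio — the scale-invariant phase of the dynamics.
#'
#' @param traj a trajectory from [sce_iterate()] or
#'   [logpotential_iterate()] with at least 2 states.
#' @param ratio_tol per-generation tolerance on the ratio change used to
#'   detect the plateau (default `1e-3`).
#' @return A data frame with columns `generation`, `ratio`, `growth_factor`
#'   (`NA` at the final generation), and logical `on_plateau`; attribute
#'   `plateau` holds the plateau's generation range and mean ratio (or NULL
#'   when no two consecutive generations qualify).
#' @export
ratio_diagnostics <- function(traj, ratio_tol = 1e-3) {
  if (!is.data.frame(traj) || nrow(traj) < 2L) {
    stop("ratio_diagnostics: need a trajectory with at least 2 states",
         call. = FALSE)
  }
  ratio <- traj$sigma / traj$mu
  growth <- c(traj$mu[-1L] / traj$mu[-nrow(traj)], NA_real_)
  dr <- abs(diff(ratio))
  ok <- dr < ratio_tol
  # longest run of consecutive small ratio changes
  plateau <- NULL
  on_plateau <- rep(FALSE, nrow(traj))
  if (any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    i0 <- starts[best]
    i1 <- ends[best] + 1L   # ok[i] links states i and i+1
    on_plateau[i0:i1] <- TRUE
    plateau <- list(from = traj$generation[i0], to = traj$generation[i1],
                    mean_ratio = mean(ratio[i0:i1]))
  }
  structure(data.frame(generation = traj$generation, ratio = ratio,
                       growth_factor = growth, on_plateau = on_plateau),
            plateau = plateau)
}

#' Write a trajectory to CSV
#'
#' Columns `model, generation, a, b, mu, sigma, ratio` and `year` when the
#' trajectory carries a time map.
#'
#' @param traj a trajectory data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  df <- cbind(model = attr(traj, "model"), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return A `trajectory` data frame (model restored from the CSV).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  model <- if ("model" %in% names(df)) df$model[1L] else "unknown"
  df$model <- NULL
  structure(df, class = c("trajectory", "data.frame"), model = model,
            terminated = FALSE)
}
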