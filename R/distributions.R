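#' Beta-distribution parameters
#'
#' Constructs the `(a, b)` parameterization of the creator model
#' \eqn{\varphi(\theta) = \theta^{a-1}(1-\theta)^{b-1}/B(a,b)} over a feature
#' frequency \eqn{\theta \in (0, 1)}. The shape `a` governs the density near
#' \eqn{\theta = 0} and `b` the density near \eqn{\theta = 1}.
#'
#' @param a,b positive shape parameters.
#' @return An object of class `beta_params` with fields `a` and `b`.
#' @seealso [moment_pair()], [moments_from_beta()], [beta_from_moments()]
#' @export
#' @examples
#' beta_params(3, 12)
beta_params <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("beta_params: 'a' and 'b' must be finite positive scalars",
         call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  m <- moments_from_beta(x)
  cat(sprintf("Beta model: a = %g, b = %g  (mu = %g, sigma = %g)\n",
              x$a, x$b, m$mu, m$sigma))
  invisible(x)
}

#' Mean/SD parameterization of a frequency model
#'
#' The pair \eqn{(\mu, \sigma)} is in one-to-one correspondence with the beta
#' shapes `(a, b)` on the representable region \eqn{\sigma^2 < \mu(1-\mu)};
#' the dynamical maps in this package use it as the state space.
#'
#' @param mu mean frequency, strictly in (0, 1).
#' @param sigma standard deviation, strictly positive.
#' @param require_beta if `TRUE` (default), additionally require
#'   \eqn{\sigma^2 < \mu(1-\mu)} so that the pair is beta-representable.
#' @return An object of class `moment_pair` with fields `mu` and `sigma`.
#' @export
#' @examples
#' moment_pair(0.2, 0.1)
moment_pair <- function(mu, sigma, require_beta = TRUE) {
  if (!is.numeric(mu) || !is.numeric(sigma) || length(mu) != 1L ||
      length(sigma) != 1L || !is.finite(mu) || !is.finite(sigma)) {
    stop("moment_pair: 'mu' and 'sigma' must be finite scalars", call. = FALSE)
  }
  if (mu <= 0 || mu >= 1) {
    stop("moment_pair: 'mu' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (sigma <= 0) stop("moment_pair: 'sigma' must be positive", call. = FALSE)
  if (require_beta && !is_beta_representable(mu, sigma)) {
    stop(sprintf(
      "moment_pair: sigma^2 = %g is not below mu*(1-mu) = %g; not beta-representable",
      sigma^2, mu * (1 - mu)), call. = FALSE)
  }
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "moment_pair")
}

#' @export
print.moment_pair <- function(x, ...) {
  cat(sprintf("Moment pair: mu = %g, sigma = %g  (sigma/mu = %g)\n",
              x$mu, x$sigma, x$sigma / x$mu))
  invisible(x)
}

# Guard for the moment-matching map: a small margin keeps numerically
# degenerate states out of beta_from_moments.
is_beta_representable <- function(mu, sigma, tol = 1e-12) {
  sigma^2 < mu * (1 - mu) - tol
}

#' Convert beta shapes to mean and standard deviation
#'
#' \eqn{\mu = a/(a+b)} and \eqn{\sigma = \sqrt{ab/(a+b+1)}/(a+b)}; the ratio
#' satisfies the identity \eqn{\sigma/\mu = \sqrt{(1-\mu)/(a+\mu)}}.
#'
#' @param params a [beta_params()] object.
#' @return A [moment_pair()].
#' @export
#' @examples
#' moments_from_beta(beta_params(3, 12))  # mu = 0.2, sigma = 0.1
moments_from_beta <- function(params) {
  params <- as_beta_params(params)
  a <- params$a
  b <- params$b
  s <- a + b
  mu <- a / s
  sigma <- sqrt(a * b / (s + 1)) / s
  structure(list(mu = mu, sigma = sigma), class = "moment_pair")
}

#' Convert mean and standard deviation to beta shapes
#'
#' The unique inverse of [moments_from_beta()] on the representable region:
#' with \eqn{\nu = \mu(1-\mu)/\sigma^2 - 1}, \eqn{a = \mu\nu} and
#' \eqn{b = (1-\mu)\nu}. This closed form is the moment-matching learning
#' step of the iterated-learning models.
#'
#' @param moments a [moment_pair()] object.
#' @return A [beta_params()].
#' @export
#' @examples
#' beta_from_moments(moment_pair(0.2, 0.1))  # a = 3, b = 12
beta_from_moments <- function(moments) {
  moments <- as_moment_pair(moments)
  mu <- moments$mu
  sigma <- moments$sigma
  if (!is_beta_representable(mu, sigma)) {
    stop(sprintf(
      "beta_from_moments: (mu = %g, sigma = %g) lies outside the beta-representable region sigma^2 < mu*(1-mu)",
      mu, sigma), call. = FALSE)
  }
  nu <- mu * (1 - mu) / sigma^2 - 1
  beta_params(mu * nu, (1 - mu) * nu)
}

#' Beta density of the creator model
#'
#' @param params a [beta_params()] object.
#' @param theta frequency values, strictly in (0, 1) (vectorized).
#' @return Density values \eqn{\theta^{a-1}(1-\theta)^{b-1}/B(a,b)}.
#' @export
beta_density <- function(params, theta) {
  params <- as_beta_params(params)
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta <= 0) || any(theta >= 1)) {
    stop("beta_density: 'theta' must lie strictly in (0, 1)", call. = FALSE)
  }
  stats::dbeta(theta, params$a, params$b)
}

#' Mode (peak position) of a beta model
#'
#' \eqn{k = (a-1)/(a+b-2)}, defined for an interior peak (`a, b > 1`). Under
#' typicality-only selection the mode is invariant, so it is the limit the
#' mean converges to as the SD shrinks; for `a < b` it lies strictly below
#' the mean.
#'
#' @param params a [beta_params()] object with `a > 1` and `b > 1`.
#' @return The peak position in (0, 1).
#' @export
beta_mode <- function(params) {
  params <- as_beta_params(params)
  if (params$a <= 1 || params$b <= 1) {
    stop("beta_mode: no interior mode unless a > 1 and b > 1", call. = FALSE)
  }
  (params$a - 1) / (params$a + params$b - 2)
}

#' Maximum-likelihood beta fit to observed frequencies
#'
#' Fits `(a, b)` by maximizing the beta log-likelihood, initialized at the
#' moment-matched estimate. Values of exactly 0 or 1 are rejected rather than
#' clipped: zero-frequency observations are excluded upstream by the corpus
#' layer, mirroring the exclusion applied throughout the corpus analysis.
#' If the optimizer fails, the moment-matched estimate is returned with a
#' warning.
#'
#' @param frequencies numeric vector, at least 3 values strictly in (0, 1)
#'   with positive sample variance.
#' @return A [beta_params()] with attributes `logLik` (at the returned
#'   parameters) and `method` (`"mle"` or `"moments"`).
#' @export
#' @examples
#' set.seed(1)
#' fit_beta(rbeta(2000, 3, 12))
fit_beta <- function(frequencies) {
  x <- frequencies
  if (!is.numeric(x) || length(x) < 3L) {
    stop("fit_beta: need at least 3 frequencies", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop("fit_beta: all frequencies must lie strictly in (0, 1); pre-filter zeros",
         call. = FALSE)
  }
  if (stats::var(x) <= 0) {
    stop("fit_beta: zero sample variance", call. = FALSE)
  }
  m <- mean(x)
  v <- stats::var(x)
  if (v >= m * (1 - m)) {
    # moment estimate outside the representable region; fall back to a mild
    # shrinkage of the variance so an initial point exists
    v <- 0.9 * m * (1 - m)
  }
  init <- beta_from_moments(moment_pair(m, sqrt(v)))
  negll <- function(p) {
    -sum(stats::dbeta(x, exp(p[1]), exp(p[2]), log = TRUE))
  }
  opt <- tryCatch(
    stats::optim(log(c(init$a, init$b)), negll, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000)),
    error = function(e) NULL)
  ll_init <- -negll(log(c(init$a, init$b)))
  if (is.null(opt) || !is.finite(opt$value) || -opt$value < ll_init) {
    warning("fit_beta: MLE optimization failed; returning moment-matched fit")
    out <- init
    attr(out, "logLik") <- ll_init
    attr(out, "method") <- "moments"
    return(out)
  }
  out <- beta_params(exp(opt$par[1]), exp(opt$par[2]))
  attr(out, "logLik") <- -opt$value
  attr(out, "method") <- "mle"
  out
}

#' Log-normal parameters of the log-potential creator model
#'
#' @param mu_tilde log-scale mean (any real).
#' @param sigma_tilde log-scale standard deviation, positive.
#' @return An object of class `lognormal_params`.
#' @export
lognormal_params <- function(mu_tilde, sigma_tilde) {
  if (!is.numeric(mu_tilde) || !is.numeric(sigma_tilde) ||
      length(mu_tilde) != 1L || length(sigma_tilde) != 1L ||
      !is.finite(mu_tilde) || !is.finite(sigma_tilde) || sigma_tilde <= 0) {
    stop("lognormal_params: need finite 'mu_tilde' and positive 'sigma_tilde'",
         call. = FALSE)
  }
  structure(list(mu_tilde = as.numeric(mu_tilde),
                 sigma_tilde = as.numeric(sigma_tilde)),
            class = "lognormal_params")
}

#' @export
print.lognormal_params <- function(x, ...) {
  m <- lognormal_moments(x)
  cat(sprintf(
    "Log-normal model: mu_tilde = %g, sigma_tilde = %g  (mu = %g, sigma/mu = %g)\n",
    x$mu_tilde, x$sigma_tilde, m$mu, m$sigma / m$mu))
  invisible(x)
}

#' Moments of a log-normal frequency model
#'
#' \eqn{\mu = \exp(\tilde\mu + \tilde\sigma^2/2)} and
#' \eqn{\sigma/\mu = \sqrt{\exp(\tilde\sigma^2) - 1}}. Unlike the beta case,
#' \eqn{\mu} is not bounded above by 1: the log-normal is only approximately
#' a frequency model.
#'
#' @param params a [lognormal_params()] object.
#' @return A list with fields `mu` and `sigma` (class `moment_pair`).
#' @seealso [lognormal_from_moments()] for the inverse conversion.
#' @export
lognormal_moments <- function(params) {
  if (!inherits(params, "lognormal_params")) {
    stop("lognormal_moments: expected a 'lognormal_params' object", call. = FALSE)
  }
  mu <- exp(params$mu_tilde + params$sigma_tilde^2 / 2)
  ratio <- sqrt(exp(params$sigma_tilde^2) - 1)
  structure(list(mu = mu, sigma = ratio * mu), class = "moment_pair")
}

#' Log-normal parameters matching a given mean and SD
#'
#' Inverse of [lognormal_moments()]:
#' \eqn{\tilde\sigma^2 = \log(1 + (\sigma/\mu)^2)},
#' \eqn{\tilde\mu = \log\mu - \tilde\sigma^2/2}.
#'
#' @param moments a [moment_pair()] (or list with `mu > 0`, `sigma > 0`;
#'   `mu` may exceed 1 here).
#' @return A [lognormal_params()].
#' @export
lognormal_from_moments <- function(moments) {
  mu <- moments$mu
  sigma <- moments$sigma
  if (!is.finite(mu) || !is.finite(sigma) || mu <= 0 || sigma <= 0) {
    stop("lognormal_from_moments: need positive finite 'mu' and 'sigma'",
         call. = FALSE)
  }
  s2 <- log(1 + (sigma / mu)^2)
  lognormal_params(log(mu) - s2 / 2, sqrt(s2))
}

as_beta_params <- function(x) {
  if (inherits(x, "beta_params")) return(x)
  if (is.list(x) && all(c("a", "b") %in% names(x))) return(beta_params(x$a, x$b))
  stop("expected a 'beta_params' object (or list with fields 'a' and 'b')",
       call. = FALSE)
}

as_moment_pair <- function(x, require_beta = TRUE) {
  if (inherits(x, "moment_pair")) return(x)
  if (is.list(x) && all(c("mu", "sigma") %in% names(x))) {
    return(moment_pair(x$mu, x$sigma, require_beta = require_beta))
  }
  stop("expected a 'moment_pair' object (or list with fields 'mu' and 'sigma')",
       call. = FALSE)
}
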