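#' One generation of the log-potential model
#'
#' The comparison model: a log-normal creator model under the evaluation
#' function \eqn{R(\theta) = \ln\theta} with selection coefficient
#' \eqn{\beta}. Reweighting a log-normal by \eqn{\theta^{\beta}} is again
#' log-normal, so the update is exact and closed-form: the log-scale SD is
#' unchanged and the log-scale mean shifts by \eqn{\beta\tilde\sigma^2}.
#'
#' @param params a [lognormal_params()] object.
#' @param beta selection coefficient (any real).
#' @return A [lognormal_params()] for the next generation.
#' @export
#' @examples
#' logpotential_update(lognormal_params(-3, 0.5), beta = 1)  # mu_tilde -2.75
logpotential_update <- function(params, beta) {
  if (!inherits(params, "lognormal_params")) {
    stop("logpotential_update: expected a 'lognormal_params' object",
         call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stop("logpotential_update: 'beta' must be a finite scalar", call. = FALSE)
  }
  lognormal_params(params$mu_tilde + beta * params$sigma_tilde^2,
                   params$sigma_tilde)
}

#' Iterate the log-potential model
#'
#' The closed-form solution makes the trajectory exactly geometric in the
#' mean, \eqn{\mu_{t+1} = \mu_t e^{\beta\tilde\sigma^2}}, with the ratio
#' \eqn{\sigma_t/\mu_t} conserved at machine precision. Because the
#' log-normal is untruncated, \eqn{\mu_t} can exceed 1 for large enough
#' \eqn{\beta t}: the model treats the frequency scale only approximately.
#'
#' @param init a [lognormal_params()] — the generation-0 model.
#' @param beta selection coefficient.
#' @param generations number of updates (>= 1).
#' @param time_map optional list with `start_year` and
#'   `years_per_generation`.
#' @return A `trajectory` data frame (columns as in [sce_iterate()]; the
#'   beta-shape columns are `NA` where the state is not beta-representable)
#'   with attribute `model = "logpotential"`.
#' @export
logpotential_iterate <- function(init, beta, generations, time_map = NULL) {
  if (!inherits(init, "lognormal_params")) {
    stop("logpotential_iterate: expected a 'lognormal_params' object",
         call. = FALSE)
  }
  if (!is.numeric(generations) || length(generations) != 1L ||
      generations < 1 || generations != round(generations)) {
    stop("logpotential_iterate: 'generations' must be a positive integer",
         call. = FALSE)
  }
  pars <- init
  states <- vector("list", generations + 1L)
  states[[1L]] <- lognormal_moments(pars)
  for (t in seq_len(generations)) {
    pars <- logpotential_update(pars, beta)
    states[[t + 1L]] <- lognormal_moments(pars)
  }
  tr <- build_trajectory(states, model = "logpotential", sel = beta,
                         time_map = time_map)
  attr(tr, "log_params") <- list(init = init, beta = beta)
  tr
}
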