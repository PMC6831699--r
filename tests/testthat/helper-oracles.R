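# Independent brute-force oracles used across the suite. These never call
# the quadrature path they check.

# dense Riemann-sum moments of the selection-reweighted beta density,
# computed in theta space on a uniform grid
riemann_reweighted_moments <- function(mu, sigma, beta_T, beta_N, n = 2e5) {
  p <- beta_from_moments(moment_pair(mu, sigma))
  theta <- (seq_len(n) - 0.5) / n
  lw <- (1 + beta_T) * stats::dbeta(theta, p$a, p$b, log = TRUE) -
    beta_N * stats::dbeta(theta, p$a, p$b)
  w <- exp(lw - max(lw))
  m0 <- sum(w)
  m1 <- sum(theta * w) / m0
  v <- sum((theta - m1)^2 * w) / m0
  list(mu = m1, sigma = sqrt(v))
}

# truncated-normal log-likelihood on (0, 1), MLE by direct optimization;
# the comparator for the beta-likeness law
truncnorm_loglik <- function(x) {
  nll <- function(p) {
    m <- p[1L]
    s <- exp(p[2L])
    z <- stats::pnorm(1, m, s) - stats::pnorm(0, m, s)
    -sum(stats::dnorm(x, m, s, log = TRUE) - log(z))
  }
  opt <- stats::optim(c(mean(x), log(stats::sd(x))), nll,
                      control = list(reltol = 1e-10, maxit = 1000))
  -opt$value
}

# a planted-rate interval plan: n intervals with exactly k tritones, the
# rest drawn from the non-tritone alphabet; positions shuffled by seed
planted_tritone_plan <- function(id, n, k, seed) {
  set.seed(seed)
  iv <- c(rep(6L, k), sample(setdiff(1:11, 6L), n - k, replace = TRUE))
  list(id = id, intervals = sample(iv))
}
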