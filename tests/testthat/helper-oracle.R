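# Independent oracles, kept deliberately separate from the closed forms they
# check.

# Brute-force discretized Bayes rule for the posterior over a stream mean:
# fine grid over the mean, normal prior x normal likelihood, normalized by
# the trapezoid rule.
grid_bayes_posterior <- function(pr, sigma, obs, n_grid = 40001) {
  half <- 12 * sqrt(pr$s2) + if (length(obs)) diff(range(obs)) + 1 else 1
  g <- seq(pr$m - half, pr$m + half, length.out = n_grid)
  log_post <- stats::dnorm(g, pr$m, sqrt(pr$s2), log = TRUE)
  for (x in obs) log_post <- log_post + stats::dnorm(x, g, sigma, log = TRUE)
  p <- exp(log_post - max(log_post))
  p <- p / sum(p)
  m <- sum(g * p)
  list(mean = m, var = sum((g - m)^2 * p))
}

# Truncated-normal mean on [0, 1] by numerical integration.
trunc01_mean_numeric <- function(mu, sigma2) {
  s <- sqrt(sigma2)
  z <- stats::integrate(function(t) stats::dnorm(t, mu, s), 0, 1)$value
  stats::integrate(function(t) t * stats::dnorm(t, mu, s), 0, 1)$value / z
}

fig3_streams <- function() list(stream_spec(0.7, 0.25), stream_spec(0.2, 0.25))

small_fig3 <- function(n_runs = 10L, n_steps = 1000L, seed = 7L, record = "log") {
  cfg <- make_fixture("fig3")
  cfg$n_runs <- as.integer(n_runs)
  cfg$n_steps <- as.integer(n_steps)
  cfg$seed <- as.integer(seed)
  cfg$record <- record
  cfg
}
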