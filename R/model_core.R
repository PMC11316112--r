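# Conjugate Gaussian belief updating and the weighted support posterior.
#
# Each stream has known observation SD sigma and unknown mean. With a
# N(m, s2) prior over the mean and n observations with sum S, the posterior
# over the mean is
#   precision = 1/s2 + n/sigma^2
#   mean      = (m/s2 + S/sigma^2) / precision
#   var       = 1 / precision
# The agent's posterior over policy support is the linear pool of her two
# stream posteriors: mu = w*mean_x + (1-w)*mean_y, and (streams independent)
# sigma2 = w^2*var_x + (1-w)^2*var_y.

#' Update a Gaussian belief with observations from one stream
#'
#' Conjugate normal-normal updating with known observation variance. With no
#' observations the prior is returned unchanged.
#'
#' @param pr Prior over the stream mean, built with [prior()].
#' @param sigma Known observation standard deviation (> 0).
#' @param observations Numeric vector of observations (possibly empty).
#' @return A [gaussian_belief()]: the posterior over the stream's mean.
#' @examples
#' update_belief(prior(0.5, 1), 0.25, 0.7) # mean 11.7/17, var 1/17
#' @export
update_belief <- function(pr, sigma, observations = numeric()) {
  if (!inherits(pr, "ebpm_prior")) pr <- do.call(prior, as.list(pr))
  if (!is_number(sigma) || sigma <= 0) stop_invalid("sigma must be > 0, got %s", format(sigma))
  if (length(observations) && !is.numeric(observations)) {
    stop_invalid("observations must be numeric")
  }
  n <- length(observations)
  if (n == 0L) return(gaussian_belief(pr$m, pr$s2, 0L))
  precision <- 1 / pr$s2 + n / sigma^2
  post_mean <- (pr$m / pr$s2 + sum(observations) / sigma^2) / precision
  gaussian_belief(post_mean, 1 / precision, n)
}

# Posterior mean/variance at a vector of observation counts, given the running
# sums of the (bias-shifted) draws. Count 0 maps to the prior. Used by the
# simulation harness so trajectories match update_belief exactly.
posterior_path <- function(pr, sigma, cum_sums, counts) {
  precision <- 1 / pr$s2 + counts / sigma^2
  sums <- c(0, cum_sums)[counts + 1L]
  list(mean = (pr$m / pr$s2 + sums / sigma^2) / precision,
       var = 1 / precision)
}

# Truncated-normal moments on [0, 1]; used only when support truncation is
# switched on (off by default: the limit formulas of the model are linear).
truncate_moments <- function(mu, sigma2) {
  s <- sqrt(sigma2)
  a <- (0 - mu) / s
  b <- (1 - mu) / s
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m_t <- mu + s * (da - db) / z
  v_t <- sigma2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mu = m_t, sigma2 = pmax(v_t, .Machine$double.xmin))
}

#' Combine two stream beliefs into a policy-support posterior
#'
#' Linearly pools the agent's posteriors over the two stream means using her
#' weight `w` on stream X, and applies the threshold rule: recommend FOR iff
#' the pooled mean strictly exceeds `threshold` (a tie recommends AGAINST).
#'
#' @param agent An [agent_spec()] (only `w` is used here; biases act on the
#'   observations, upstream of the beliefs).
#' @param belief_x,belief_y [gaussian_belief()]s over the stream means.
#' @param threshold Decision threshold for the recommendation.
#' @param truncate If `TRUE`, renormalise the support posterior to \[0, 1\]
#'   (truncated normal) before summarising. Off by default.
#' @return A [belief_summary()].
#' @examples
#' a <- agent_spec(w = 0.5)
#' combine_streams(a, gaussian_belief(0.7, 1e-4), gaussian_belief(0.2, 1e-4), 0.5)
#' @export
combine_streams <- function(agent, belief_x, belief_y, threshold = 0.5,
                            truncate = FALSE) {
  stopifnot(inherits(agent, "agent_spec"),
            inherits(belief_x, "gaussian_belief"),
            inherits(belief_y, "gaussian_belief"))
  if (!is_number(threshold)) stop_invalid("threshold must be a finite number")
  w <- agent$w
  mu <- w * belief_x$mean + (1 - w) * belief_y$mean
  sigma2 <- w^2 * belief_x$var + (1 - w)^2 * belief_y$var
  if (truncate) {
    tm <- truncate_moments(mu, sigma2)
    mu <- tm$mu
    sigma2 <- tm$sigma2
  }
  belief_summary(mu, sigma2, if (mu > threshold) "FOR" else "AGAINST")
}

#' Large-sample limit of an agent's support mean
#'
#' In the limit of accumulated evidence the agent's posterior mean for stream
#' X converges to `mu_x + bias_x` (and analogously for Y), so her support
#' mean converges to the deterministic value
#' `w * (mu_x + bias_x) + (1 - w) * (mu_y + bias_y)`.
#'
#' @param agent An [agent_spec()].
#' @param streams List of two [stream_spec()]s, X first.
#' @return The limiting support mean (a number).
#' @examples
#' limit_support(agent_spec(0.5), list(stream_spec(0.7, 0.25), stream_spec(0.2, 0.25)))
#' @export
limit_support <- function(agent, streams) {
  stopifnot(inherits(agent, "agent_spec"), length(streams) == 2L,
            inherits(streams[[1]], "stream_spec"),
            inherits(streams[[2]], "stream_spec"))
  agent$w * (streams[[1]]$mu_true + agent$bias_x) +
    (1 - agent$w) * (streams[[2]]$mu_true + agent$bias_y)
}
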