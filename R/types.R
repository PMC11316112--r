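# Domain types: evidence streams, priors, agents, beliefs.
# All are plain S3 lists with validating constructors; invalid parameters
# raise conditions of class "ebpm_invalid_parameter".

stop_invalid <- function(msg, ...) {
  stop(structure(
    class = c("ebpm_invalid_parameter", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Specify an evidence stream
#'
#' An evidence stream emits i.i.d. Gaussian observations with an unknown mean
#' `mu_true` and a known standard deviation `sigma`. Agents never see
#' `mu_true`; they learn it from the draws. `rate` is the stream's emission
#' speed relative to stream Y's clock: when stream Y has delivered `n`
#' observations, a stream with rate `r` has delivered `floor(r * n)`.
#'
#' @param mu_true True stream mean (unknown to the agents).
#' @param sigma Known observation standard deviation, strictly positive.
#' @param rate Relative emission rate in (0, 1]; 1 means one observation per
#'   step of the reference clock.
#' @return An object of class `stream_spec`.
#' @examples
#' stream_spec(0.7, 0.25)
#' stream_spec(0.8, 0.25, rate = 0.1) # slow stream
#' @export
stream_spec <- function(mu_true, sigma, rate = 1) {
  if (!is_number(mu_true)) stop_invalid("mu_true must be a finite number")
  if (!is_number(sigma) || sigma <= 0) stop_invalid("sigma must be > 0, got %s", format(sigma))
  if (!is_number(rate) || rate <= 0 || rate > 1) {
    stop_invalid("rate must be in (0, 1], got %s", format(rate))
  }
  structure(list(mu_true = mu_true, sigma = sigma, rate = rate),
            class = "stream_spec")
}

#' Gaussian prior over a stream's unknown mean
#'
#' @param m Prior mean.
#' @param s2 Prior variance, strictly positive.
#' @return An object of class `ebpm_prior`.
#' @export
prior <- function(m = 0.5, s2 = 1) {
  if (!is_number(m)) stop_invalid("prior mean m must be a finite number")
  if (!is_number(s2) || s2 <= 0) stop_invalid("prior variance s2 must be > 0, got %s", format(s2))
  structure(list(m = m, s2 = s2), class = "ebpm_prior")
}

#' Specify an agent
#'
#' An agent is characterised by the weight `w` she puts on stream X (stream Y
#' gets `1 - w`), an optional systematic additive observation bias per stream
#' (`bias_x`, `bias_y`; both zero in the pristine case), a prior per stream,
#' and an inertia coefficient for the assessment she reports (0 = she reports
#' her posterior mean immediately; close to 1 = her reported assessment lags
#' far behind her posterior).
#'
#' @param w Weight on stream X, in \[0, 1\].
#' @param bias_x,bias_y Additive offset applied to every observation the agent
#'   receives from the corresponding stream. A biased agent's posterior mean
#'   for stream X converges to `mu_x + bias_x`.
#' @param prior_x,prior_y Per-stream priors (see [prior()]); both agents share
#'   `prior(0.5, 1)` by default.
#' @param inertia Exponential-smoothing coefficient in \[0, 1) for the
#'   reported assessment.
#' @return An object of class `agent_spec`.
#' @examples
#' agent_spec(w = 0.9)                 # pristine, leans on stream X
#' agent_spec(w = 0.5, bias_x = 0.2)   # faulty reader of stream X
#' @export
agent_spec <- function(w, bias_x = 0, bias_y = 0,
                       prior_x = prior(), prior_y = prior_x,
                       inertia = 0) {
  if (!is_number(w) || w < 0 || w > 1) stop_invalid("w must be in [0, 1], got %s", format(w))
  if (!is_number(bias_x) || !is_number(bias_y)) stop_invalid("biases must be finite numbers")
  if (!inherits(prior_x, "ebpm_prior") || !inherits(prior_y, "ebpm_prior")) {
    stop_invalid("prior_x and prior_y must be built with prior()")
  }
  if (!is_number(inertia) || inertia < 0 || inertia >= 1) {
    stop_invalid("inertia must be in [0, 1), got %s", format(inertia))
  }
  structure(list(w = w, bias_x = bias_x, bias_y = bias_y,
                 prior_x = prior_x, prior_y = prior_y, inertia = inertia),
            class = "agent_spec")
}

#' Posterior belief about one stream's unknown mean
#'
#' @param mean Posterior mean.
#' @param var Posterior variance, strictly positive.
#' @param n_obs Number of observations absorbed.
#' @return An object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, var, n_obs = 0L) {
  if (!is_number(mean)) stop_invalid("belief mean must be a finite number")
  if (!is_number(var) || var <= 0) stop_invalid("belief var must be > 0, got %s", format(var))
  if (!is_number(n_obs) || n_obs < 0 || n_obs != trunc(n_obs)) {
    stop_invalid("n_obs must be a non-negative integer")
  }
  structure(list(mean = mean, var = var, n_obs = as.integer(n_obs)),
            class = "gaussian_belief")
}

#' Posterior belief about policy support, with a recommendation
#'
#' The agent's posterior over the evidential support for the policy: a
#' Gaussian with mean `mu` and variance `sigma2`, plus the threshold rule's
#' recommendation ("FOR" iff `mu` strictly exceeds the threshold, ties go
#' "AGAINST").
#'
#' @param mu Posterior mean of policy support.
#' @param sigma2 Posterior variance, strictly positive.
#' @param recommendation Either "FOR" or "AGAINST".
#' @return An object of class `belief_summary`.
#' @export
belief_summary <- function(mu, sigma2, recommendation) {
  if (!is_number(mu)) stop_invalid("mu must be a finite number")
  if (!is_number(sigma2) || sigma2 <= 0) stop_invalid("sigma2 must be > 0, got %s", format(sigma2))
  recommendation <- match.arg(recommendation, c("FOR", "AGAINST"))
  structure(list(mu = mu, sigma2 = sigma2, recommendation = recommendation),
            class = "belief_summary")
}

#' @export
print.stream_spec <- function(x, ...) {
  cat(sprintf("<stream_spec> mu_true = %g, sigma = %g, rate = %g\n",
              x$mu_true, x$sigma, x$rate))
  invisible(x)
}

#' @export
print.agent_spec <- function(x, ...) {
  cat(sprintf(
    "<agent_spec> w = %g, bias = (%g, %g), prior = N(%g, %g)/N(%g, %g), inertia = %g\n",
    x$w, x$bias_x, x$bias_y, x$prior_x$m, x$prior_x$s2,
    x$prior_y$m, x$prior_y$s2, x$inertia))
  invisible(x)
}

#' @export
print.belief_summary <- function(x, ...) {
  cat(sprintf("<belief_summary> mu = %.4f, sigma2 = %.3g, %s\n",
              x$mu, x$sigma2, x$recommendation))
  invisible(x)
}
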