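# Seeded paired-run Monte Carlo harness. Both agents see the same stream
# draws in each run (common random numbers); each agent shifts the draws by
# her own bias before updating. Stream Y is the clock: step t means the agent
# has seen n_y = t observations from Y and floor(rate_x * t) from X.

#' Simulation configuration
#'
#' @param stream_x,stream_y [stream_spec()]s. Stream Y is the reference
#'   clock; `stream_x$rate` is interpreted relative to it.
#' @param agents List of two [agent_spec()]s, conventionally D then R.
#' @param threshold Decision threshold shared by both agents.
#' @param n_steps Observations from stream Y per run.
#' @param n_runs Number of paired runs.
#' @param seed Root seed; every run and stream derives its own substream
#'   from it, so adding runs never perturbs earlier runs.
#' @param record Either `"log"` (default: a log-spaced grid of about 25
#'   recorded steps per decade, matching log-scaled trajectory plots),
#'   `"final"` (record the last step only), or a positive integer k
#'   (record every k-th step).
#' @param truncate If `TRUE`, truncate support posteriors to \[0, 1\].
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- make_fixture("fig3")
#' cfg$n_runs
#' @export
sim_config <- function(stream_x, stream_y, agents, threshold = 0.5,
                       n_steps = 10000L, n_runs = 100L, seed = 0L,
                       record = "log", truncate = FALSE) {
  stopifnot(inherits(stream_x, "stream_spec"), inherits(stream_y, "stream_spec"))
  if (!is.list(agents) || length(agents) != 2L ||
      !all(vapply(agents, inherits, logical(1), "agent_spec"))) {
    stop_invalid("agents must be a list of two agent_spec objects")
  }
  if (!is_number(threshold)) stop_invalid("threshold must be a finite number")
  if (!is_number(n_steps) || n_steps < 1 || n_steps != trunc(n_steps)) {
    stop_invalid("n_steps must be a positive integer")
  }
  if (!is_number(n_runs) || n_runs < 1 || n_runs != trunc(n_runs)) {
    stop_invalid("n_runs must be a positive integer")
  }
  if (!is_number(seed) || seed != trunc(seed)) stop_invalid("seed must be an integer")
  if (is.character(record)) {
    record <- match.arg(record, c("log", "final"))
  } else if (!is_number(record) || record < 1 || record != trunc(record)) {
    stop_invalid("record must be \"log\", \"final\" or a positive integer")
  }
  if (!isTRUE(truncate) && !isFALSE(truncate)) stop_invalid("truncate must be TRUE or FALSE")
  if (is.null(names(agents))) names(agents) <- c("D", "R")
  structure(list(stream_x = stream_x, stream_y = stream_y, agents = agents,
                 threshold = threshold, n_steps = as.integer(n_steps),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 record = record, truncate = truncate),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d runs x %d steps, threshold %g, seed %d\n",
              x$n_runs, x$n_steps, x$threshold, x$seed))
  cat(sprintf("  X: mu %g sd %g rate %g | Y: mu %g sd %g\n",
              x$stream_x$mu_true, x$stream_x$sigma, x$stream_x$rate,
              x$stream_y$mu_true, x$stream_y$sigma))
  for (nm in names(x$agents)) {
    a <- x$agents[[nm]]
    cat(sprintf("  %s: w %g bias (%g, %g) inertia %g\n",
                nm, a$w, a$bias_x, a$bias_y, a$inertia))
  }
  invisible(x)
}

# Deterministic substream seed per (root seed, run, stream). Distinct for
# every (run, stream) pair and kept well below 2^31.
substream_seed <- function(seed, run_index, stream) {
  (abs(seed) %% 10007L) * 104729L + run_index * 2L + stream
}

# Recorded steps for a run: always includes the final step.
record_grid <- function(n_steps, record) {
  if (identical(record, "final")) return(n_steps)
  if (is.numeric(record)) {
    return(unique(c(seq(as.integer(record), n_steps, by = as.integer(record)), n_steps)))
  }
  pts <- max(2, ceiling(25 * log10(n_steps)) + 1L)
  g <- unique(round(10^seq(0, log10(n_steps), length.out = pts)))
  g[g >= 1 & g <= n_steps]
}

#' Draw one run's shared evidence
#'
#' Generates the raw (unbiased) draws both agents consume in run
#' `run_index`: `floor(rate_x * n_steps)` from stream X and `n_steps` from
#' stream Y. Each (seed, run, stream) triple has its own RNG substream, so
#' the same pair always reproduces bit-identically and runs are mutually
#' independent.
#'
#' @param config A [sim_config()].
#' @param run_index Run number, 1-based.
#' @return List with numeric vectors `x` and `y`.
#' @export
draw_shared_data <- function(config, run_index) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_number(run_index) || run_index < 1) stop_invalid("run_index must be >= 1")
  n_y <- config$n_steps
  n_x <- floor(config$stream_x$rate * n_y)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(config$seed, run_index, 0L))
  x <- stats::rnorm(n_x, config$stream_x$mu_true, config$stream_x$sigma)
  set.seed(substream_seed(config$seed, run_index, 1L))
  y <- stats::rnorm(n_y, config$stream_y$mu_true, config$stream_y$sigma)
  list(x = x, y = y)
}

#' Smooth a sequence of assessments with exponential inertia
#'
#' The reported assessment lags the raw one:
#' `reported[t] = lambda * reported[t-1] + (1 - lambda) * raw[t]`, started at
#' `init` (by default the first raw value, so a constant input is a fixed
#' point and `lambda = 0` is the identity). In [run_paired()] `init` is the
#' agent's prior-based support mean.
#'
#' @param raw Numeric vector of raw assessments.
#' @param lambda Inertia coefficient in \[0, 1).
#' @param init Value the smoother starts from.
#' @return Numeric vector, same length as `raw`.
#' @examples
#' apply_inertia(c(0, rep(1, 9)), 0.9) # crosses 0.5 at the 7th post-step point
#' @export
apply_inertia <- function(raw, lambda, init = raw[1]) {
  if (!is_number(lambda) || lambda < 0 || lambda >= 1) {
    stop_invalid("lambda must be in [0, 1), got %s", format(lambda))
  }
  if (!length(raw)) return(raw)
  if (lambda == 0) return(raw)
  as.numeric(stats::filter((1 - lambda) * raw, lambda,
                           method = "recursive", init = init))
}

# One agent's trajectory for one run, on the recorded grid.
agent_trajectory <- function(agent, draws, config, grid) {
  n_steps <- config$n_steps
  rate_x <- config$stream_x$rate
  sx <- config$stream_x$sigma
  sy <- config$stream_y$sigma
  # steps at which beliefs are needed: every step if the agent has inertia
  # (the smoother is defined on the full per-step sequence), else just grid
  steps <- if (agent$inertia > 0) seq_len(n_steps) else grid
  nx <- floor(rate_x * steps)
  ny <- steps
  px <- posterior_path(agent$prior_x, sx, cumsum(draws$x + agent$bias_x), nx)
  py <- posterior_path(agent$prior_y, sy, cumsum(draws$y + agent$bias_y), ny)
  w <- agent$w
  mu <- w * px$mean + (1 - w) * py$mean
  sigma2 <- w^2 * px$var + (1 - w)^2 * py$var
  if (config$truncate) {
    tm <- truncate_moments(mu, sigma2)
    mu <- tm$mu
    sigma2 <- tm$sigma2
  }
  mu_prior <- w * agent$prior_x$m + (1 - w) * agent$prior_y$m
  reported <- apply_inertia(mu, agent$inertia, init = mu_prior)
  keep <- match(grid, steps)
  data.frame(
    step = grid,
    n_x = floor(rate_x * grid),
    support_mean = mu[keep],
    support_sd = sqrt(sigma2[keep]),
    recommendation = ifelse(mu[keep] > config$threshold, "FOR", "AGAINST"),
    reported_assessment = reported[keep]
  )
}

#' Run paired simulations
#'
#' Runs `n_runs` paired simulations. In each run both agents consume the same
#' stream draws (after adding their own biases), update their per-stream
#' beliefs by conjugate normal-normal updating, pool them with their weights,
#' and report an assessment after inertia smoothing. Beliefs are recorded on
#' the configured step grid.
#'
#' @param config A [sim_config()].
#' @return An object of class `ebpm_sims`: a list with `records` (a tidy
#'   data frame with one row per run/step/agent: `run_id`, `step` (= number
#'   of Y observations seen), `n_x`, `agent`, `support_mean`, `support_sd`,
#'   `recommendation`, `reported_assessment`) and `config`.
#' @examples
#' cfg <- make_fixture("fig3")
#' cfg$n_runs <- 5L; cfg$n_steps <- 500L
#' sims <- run_paired(cfg)
#' head(sims$records)
#' @export
run_paired <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- record_grid(config$n_steps, config$record)
  agent_names <- names(config$agents)
  out <- vector("list", config$n_runs * 2L)
  k <- 0L
  for (run in seq_len(config$n_runs)) {
    draws <- draw_shared_data(config, run)
    for (i in seq_along(config$agents)) {
      tr <- agent_trajectory(config$agents[[i]], draws, config, grid)
      tr <- cbind(run_id = run, tr)
      tr$agent <- agent_names[i]
      k <- k + 1L
      out[[k]] <- tr
    }
  }
  records <- do.call(rbind, out)
  records <- records[order(records$run_id, records$step, records$agent),
                     c("run_id", "step", "n_x", "agent", "support_mean",
                       "support_sd", "recommendation", "reported_assessment")]
  rownames(records) <- NULL
  structure(list(records = records, config = config), class = "ebpm_sims")
}

#' @export
print.ebpm_sims <- function(x, ...) {
  cat(sprintf("<ebpm_sims> %d runs, %d recorded steps, agents: %s\n",
              x$config$n_runs, length(unique(x$records$step)),
              paste(unique(x$records$agent), collapse = ", ")))
  invisible(x)
}

# Run-final support means for one agent; fast path used by equivalence_check
# and the acceptance analyses (no per-step trajectory needed).
final_support_means <- function(config, agent = 1L) {
  a <- config$agents[[agent]]
  vapply(seq_len(config$n_runs), function(run) {
    d <- draw_shared_data(config, run)
    bx <- update_belief(a$prior_x, config$stream_x$sigma, d$x + a$bias_x)
    by <- update_belief(a$prior_y, config$stream_y$sigma, d$y + a$bias_y)
    combine_streams(a, bx, by, config$threshold, config$truncate)$mu
  }, numeric(1))
}

fixture_table <- function() {
  fig35_stream <- function(mu, rate = 1) stream_spec(mu, 0.25, rate)
  list(
    # Fig 3: pristine case, weights 0.5 vs 0.9, prior m = 0.5
    fig3 = function() sim_config(
      fig35_stream(0.7), fig35_stream(0.2),
      list(D = agent_spec(0.5), R = agent_spec(0.9))),
    # Fig 4 is analytic (see uncertainty_curve); as a simulation scenario it
    # pits an equal-weight agent against one discounting stream Y entirely
    fig4 = function() sim_config(
      fig35_stream(0.7), fig35_stream(0.2),
      list(D = agent_spec(0.5), R = agent_spec(1))),
    # Fig 5: single learner (identical pair), equal weights, mu_X = 0.8
    fig5_equal = function() sim_config(
      fig35_stream(0.8), fig35_stream(0.2),
      list(D = agent_spec(0.5), R = agent_spec(0.5))),
    fig5_slow = function() sim_config(
      fig35_stream(0.8, rate = 0.1), fig35_stream(0.2),
      list(D = agent_spec(0.5), R = agent_spec(0.5))),
    fig5_slow_inertia = function() sim_config(
      fig35_stream(0.8, rate = 0.1), fig35_stream(0.2),
      list(D = agent_spec(0.5, inertia = 0.9),
           R = agent_spec(0.5, inertia = 0.9)))
  )
}

#' Published simulation scenarios
#'
#' Returns the configuration of a published scenario with its caption
#' parameters: `fig3` (pristine case, mu_X = 0.7, mu_Y = 0.2, sigma = 0.25,
#' weights 0.5 and 0.9, prior m = 0.5, 100 runs), `fig4` (equal vs fully
#' discounting weights on the same streams), and the three learning-speed
#' scenarios `fig5_equal`, `fig5_slow` (stream X at ten percent of stream
#' Y's speed) and `fig5_slow_inertia` (slow stream plus reporting inertia,
#' lambda = 0.9). Values the captions do not state (prior variance 1,
#' n_steps 1e4, seed 0) take the package defaults.
#'
#' @param name One of `fixture_names()`.
#' @return A [sim_config()].
#' @export
make_fixture <- function(name) {
  tbl <- fixture_table()
  if (!is.character(name) || length(name) != 1L || !name %in% names(tbl)) {
    stop_invalid("unknown fixture \"%s\"; known: %s",
                 paste(name, collapse = ","), paste(names(tbl), collapse = ", "))
  }
  tbl[[name]]()
}

#' @rdname make_fixture
#' @export
fixture_names <- function() names(fixture_table())
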