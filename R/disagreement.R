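# Classifying and quantifying the three kinds of disagreement between two
# agents: support (posterior means differ), policy (recommendations differ;
# entails support disagreement) and uncertainty (posterior SDs differ).

#' Classify the disagreement between two belief summaries
#'
#' @param belief_d,belief_r [belief_summary()]s computed against the same
#'   threshold.
#' @param epsilon Non-negative tolerance below which two means (or SDs) count
#'   as equal. The default 1e-9 implements strict-inequality disagreement at
#'   analytic precision; for noisy finite-sample classification a larger
#'   documented value (e.g. 0.01) is appropriate.
#' @return A list of class `disagreement_record` with fields `support`,
#'   `support_magnitude` (|mu_D - mu_R|), `policy`, `uncertainty`,
#'   `uncertainty_magnitude` (|sigma_D - sigma_R|, SD scale) and
#'   `uncertainty_magnitude_var` (variance scale).
#' @examples
#' d <- belief_summary(0.45, 1e-4, "AGAINST")
#' r <- belief_summary(0.65, 1e-4, "FOR")
#' classify_disagreement(d, r)
#' @export
classify_disagreement <- function(belief_d, belief_r, epsilon = 1e-9) {
  stopifnot(inherits(belief_d, "belief_summary"),
            inherits(belief_r, "belief_summary"))
  if (!is_number(epsilon) || epsilon < 0) {
    stop_invalid("epsilon must be non-negative, got %s", format(epsilon))
  }
  supp_mag <- abs(belief_d$mu - belief_r$mu)
  unc_mag <- abs(sqrt(belief_d$sigma2) - sqrt(belief_r$sigma2))
  structure(list(
    support = supp_mag > epsilon,
    support_magnitude = supp_mag,
    policy = belief_d$recommendation != belief_r$recommendation,
    uncertainty = unc_mag > epsilon,
    uncertainty_magnitude = unc_mag,
    uncertainty_magnitude_var = abs(belief_d$sigma2 - belief_r$sigma2)
  ), class = "disagreement_record")
}

#' Per-step pairwise disagreement from a simulation
#'
#' Compares the two agents at every recorded (run, step) of a paired
#' simulation and returns one tidy row per pair.
#'
#' @param sims An `ebpm_sims` object from [run_paired()].
#' @param epsilon Tolerance as in [classify_disagreement()].
#' @return Data frame with columns `run_id`, `step`, `n_x`, `support`,
#'   `support_magnitude`, `policy`, `uncertainty`, `uncertainty_magnitude`,
#'   `uncertainty_magnitude_var`.
#' @export
pair_disagreement <- function(sims, epsilon = 1e-9) {
  stopifnot(inherits(sims, "ebpm_sims"))
  if (!is_number(epsilon) || epsilon < 0) {
    stop_invalid("epsilon must be non-negative, got %s", format(epsilon))
  }
  r <- sims$records
  agents <- unique(r$agent)
  stopifnot(length(agents) == 2L)
  d <- r[r$agent == agents[1], ]
  a <- r[r$agent == agents[2], ]
  # run_paired emits records sorted by (run, step, agent): rows align
  stopifnot(all(d$run_id == a$run_id), all(d$step == a$step))
  supp_mag <- abs(d$support_mean - a$support_mean)
  unc_mag <- abs(d$support_sd - a$support_sd)
  data.frame(
    run_id = d$run_id, step = d$step, n_x = d$n_x,
    support = supp_mag > epsilon,
    support_magnitude = supp_mag,
    policy = d$recommendation != a$recommendation,
    uncertainty = unc_mag > epsilon,
    uncertainty_magnitude = unc_mag,
    uncertainty_magnitude_var = abs(d$support_sd^2 - a$support_sd^2)
  )
}

#' Aggregate disagreement records across runs
#'
#' @param records Either a data frame as returned by [pair_disagreement()]
#'   (rows for one step across runs, or several steps — see `by_step`) or a
#'   list of `disagreement_record`s.
#' @param by_step If `TRUE` and `records` has a `step` column, aggregate per
#'   step and return one row per step.
#' @return Data frame with `policy_rate` (fraction of runs in policy
#'   disagreement), `support_rate`, `uncertainty_rate`,
#'   `mean_support_magnitude`, `mean_uncertainty_magnitude` and `n_runs`
#'   (plus `step` when `by_step`).
#' @export
aggregate_disagreement <- function(records, by_step = FALSE) {
  if (is.list(records) && !is.data.frame(records)) {
    if (!length(records)) stop_invalid("cannot aggregate an empty record set")
    stopifnot(all(vapply(records, inherits, logical(1), "disagreement_record")))
    records <- do.call(rbind, lapply(records, function(x) as.data.frame(unclass(x))))
  }
  if (!is.data.frame(records) || !nrow(records)) {
    stop_invalid("cannot aggregate an empty record set")
  }
  one <- function(df) data.frame(
    n_runs = nrow(df),
    policy_rate = mean(df$policy),
    support_rate = mean(df$support),
    uncertainty_rate = mean(df$uncertainty),
    mean_support_magnitude = mean(df$support_magnitude),
    mean_uncertainty_magnitude = mean(df$uncertainty_magnitude)
  )
  if (by_step && "step" %in% names(records)) {
    parts <- lapply(split(records, records$step), one)
    out <- do.call(rbind, parts)
    out <- cbind(step = as.integer(names(parts)), out)
    out <- out[order(out$step), ]
    rownames(out) <- NULL
    return(out)
  }
  one(records)
}

#' Posterior support variance as a function of the stream weight
#'
#' For an agent with weight `w` who has seen `n_x` observations from stream X
#' and `n_y` from stream Y, the support posterior variance is
#' `w^2 * v_x + (1 - w)^2 * v_y` with `v = 1/(1/s2 + n/sigma^2)` per stream.
#' With equal priors, SDs and counts this is `(w^2 + (1-w)^2) * v(n)`:
#' symmetric around `w = 0.5`, minimised there, and exactly twice as large at
#' the extremes `w = 0` or `w = 1` — whichever agent weights the streams more
#' equally is less uncertain, for any amount of evidence.
#'
#' @param weights Numeric vector of weights in \[0, 1\].
#' @param n Observations seen from stream X (and from Y unless `n_y` given).
#' @param pr Prior over the stream means (shared unless `prior_y` given).
#' @param sigma Stream X observation SD (and Y's unless `sigma_y` given).
#' @param n_y,prior_y,sigma_y Optional stream-Y values for the unequal case.
#' @return Data frame with columns `weight` and `sigma2`.
#' @examples
#' uc <- uncertainty_curve(c(0, 0.5, 1), n = 100, pr = prior(0.5, 1), sigma = 0.25)
#' uc$sigma2[1] / uc$sigma2[2] # = 2
#' @export
uncertainty_curve <- function(weights, n, pr = prior(), sigma,
                              n_y = n, prior_y = pr, sigma_y = sigma) {
  if (!is.numeric(weights) || any(weights < 0 | weights > 1)) {
    stop_invalid("weights must lie in [0, 1]")
  }
  if (!is_number(sigma) || sigma <= 0) stop_invalid("sigma must be > 0")
  if (!is_number(sigma_y) || sigma_y <= 0) stop_invalid("sigma_y must be > 0")
  v_x <- 1 / (1 / pr$s2 + n / sigma^2)
  v_y <- 1 / (1 / prior_y$s2 + n_y / sigma_y^2)
  data.frame(weight = weights,
             sigma2 = weights^2 * v_x + (1 - weights)^2 * v_y)
}

#' @describeIn uncertainty_curve The Result-2 statistic: the ratio of the
#'   extreme-weight variance (`w = 0` or `1`) to the equal-weight variance
#'   (`w = 0.5`). Exactly 2 whenever the two streams have equal priors, SDs
#'   and counts.
#' @export
uncertainty_ratio <- function(n, pr = prior(), sigma,
                              n_y = n, prior_y = pr, sigma_y = sigma) {
  uc <- uncertainty_curve(c(0, 0.5), n, pr, sigma, n_y, prior_y, sigma_y)
  uc$sigma2[1] / uc$sigma2[2]
}
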