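# Can a faulty (biased) configuration be told apart from some faultless
# (weights-only) configuration, given only the agents' limiting support
# means? A limiting mean c is faultlessly reachable iff the weight
# w* = (c - mu_y)/(mu_x - mu_y) solving w*mu_x + (1-w)*mu_y = c lies in
# [0, 1], i.e. iff c lies in the convex hull of the two stream means. Inside
# the hull a bias can always be re-explained by a weight, so fault cannot be
# assigned post hoc without transparency of reasoning.

#' Observed limiting beliefs
#'
#' The post-hoc observables of a long-run disagreement: each agent's limiting
#' support mean, plus the true stream means (assumed known to the analyst in
#' the long-run idealisation).
#'
#' @param c_d,c_r Limiting support means of agents D and R.
#' @param mu_x,mu_y True stream means.
#' @return An object of class `observed_limits`.
#' @export
observed_limits <- function(c_d, c_r, mu_x, mu_y) {
  for (v in list(c_d, c_r, mu_x, mu_y)) {
    if (!is_number(v)) stop_invalid("all observed limits must be finite numbers")
  }
  structure(list(c_d = c_d, c_r = c_r, mu_x = mu_x, mu_y = mu_y),
            class = "observed_limits")
}

#' Weight of the faultless configuration matching a limiting mean
#'
#' Solves `w * mu_x + (1 - w) * mu_y = c` for the weight of a bias-free agent
#' whose limiting support mean equals `c`.
#'
#' @param c Observed limiting support mean.
#' @param mu_x,mu_y True stream means.
#' @return The solving weight (may fall outside \[0, 1\], in which case no
#'   faultless explanation exists). `NA` when `mu_x == mu_y` but `c` differs
#'   from them (no weight can reach `c`); when `mu_x == mu_y == c` every
#'   weight works and 0.5 is returned with attribute `degenerate = TRUE`.
#' @examples
#' equivalent_faultless_weight(0.55, 0.7, 0.2) # 0.7
#' equivalent_faultless_weight(0.80, 0.7, 0.2) # 1.2: unreachable without bias
#' @export
equivalent_faultless_weight <- function(c, mu_x, mu_y) {
  for (v in list(c, mu_x, mu_y)) {
    if (!is_number(v)) stop_invalid("c, mu_x, mu_y must be finite numbers")
  }
  if (mu_x == mu_y) {
    if (c == mu_x) return(structure(0.5, degenerate = TRUE))
    return(NA_real_)
  }
  (c - mu_y) / (mu_x - mu_y)
}

diagnose_one <- function(label, c, mu_x, mu_y) {
  w_star <- equivalent_faultless_weight(c, mu_x, mu_y)
  degenerate <- isTRUE(attr(w_star, "degenerate"))
  indist <- !is.na(w_star) && w_star >= 0 && w_star <= 1
  explanation <- if (degenerate) {
    sprintf(paste0("agent %s: the stream means coincide with the observed limit; ",
                   "every faultless weight reproduces it (reported w* = 0.5)"), label)
  } else if (is.na(w_star)) {
    sprintf(paste0("agent %s: the stream means coincide (mu_x = mu_y = %g) but the ",
                   "observed limit %g differs; no weights-only agent can reach it, ",
                   "so bias must be invoked"), label, mu_x, c)
  } else if (indist) {
    sprintf(paste0("agent %s: the faultless configuration (w = %.6g, bias = 0) has ",
                   "the same limiting support mean %g; faulty and faultless ",
                   "explanations are empirically indistinguishable"), label, w_star, c)
  } else {
    sprintf(paste0("agent %s: the observed limit %g lies outside the convex hull ",
                   "[%g, %g] of the stream means (solving weight %.6g is outside ",
                   "[0, 1]); no faultless configuration reaches it, so bias must ",
                   "be invoked"), label, c, min(mu_x, mu_y), max(mu_x, mu_y), w_star)
  }
  structure(list(agent = label,
                 equivalent_weight = if (is.na(w_star)) NA_real_ else as.numeric(w_star),
                 degenerate = degenerate,
                 indistinguishable = indist,
                 explanation = explanation),
            class = "ebpm_diagnosis")
}

#' Diagnose whether observed limits admit a faultless explanation
#'
#' Per agent: if the solving weight of [equivalent_faultless_weight()] lies
#' in \[0, 1\], some weights-only configuration yields the same limiting
#' belief, so a faulty and a faultless account cannot be distinguished from
#' the limiting support means alone. Otherwise the limit is unreachable
#' without bias and fault can be established.
#'
#' If standard errors are supplied (finite-data variant, where the limits are
#' estimated rather than known), the limit is treated as the interval
#' `c +/- 3 se` and indistinguishability holds if any value in the interval
#' maps to a weight in \[0, 1\].
#'
#' @param limits An [observed_limits()].
#' @param se_d,se_r Optional Monte Carlo / estimation standard errors for the
#'   two limiting means (default 0: the long-run idealisation).
#' @return List of two `ebpm_diagnosis` objects (fields `agent`,
#'   `equivalent_weight`, `degenerate`, `indistinguishable`, `explanation`),
#'   named D and R.
#' @examples
#' diagnose_limits(observed_limits(0.55, 0.65, 0.7, 0.2))
#' @export
diagnose_limits <- function(limits, se_d = 0, se_r = 0) {
  stopifnot(inherits(limits, "observed_limits"))
  if (!is_number(se_d) || se_d < 0 || !is_number(se_r) || se_r < 0) {
    stop_invalid("standard errors must be non-negative numbers")
  }
  band <- function(label, c, se) {
    if (se == 0) return(diagnose_one(label, c, limits$mu_x, limits$mu_y))
    lo <- c - 3 * se
    hi <- c + 3 * se
    hull <- range(limits$mu_x, limits$mu_y)
    # indistinguishable if the 3-se band intersects the hull
    if (hi >= hull[1] && lo <= hull[2]) {
      diagnose_one(label, min(max(c, hull[1]), hull[2]), limits$mu_x, limits$mu_y)
    } else {
      diagnose_one(label, c, limits$mu_x, limits$mu_y)
    }
  }
  list(D = band("D", limits$c_d, se_d), R = band("R", limits$c_r, se_r))
}

#' @export
print.ebpm_diagnosis <- function(x, ...) {
  cat(sprintf("<diagnosis %s> %s (w* = %s)\n",
              x$agent,
              if (x$indistinguishable) "indistinguishable" else "distinguishable",
              format(x$equivalent_weight)))
  cat(" ", x$explanation, "\n")
  invisible(x)
}

#' Numerical witness: do two configurations produce the same limiting beliefs?
#'
#' Simulates both configurations with common random numbers (the shared root
#' seed of `config_a`) and compares the run-averaged final support mean of
#' agent D under each. Returns `TRUE` iff the absolute difference is within 3
#' combined Monte Carlo standard errors (the standard error of the paired
#' per-run differences).
#'
#' @param config_a,config_b [sim_config()]s sharing stream specs and
#'   threshold (anything else is an invalid comparison).
#' @param n Override for `n_steps` (applied to both).
#' @param n_runs Override for `n_runs` (applied to both).
#' @return Logical, with attributes `difference`, `se` and `means`.
#' @export
equivalence_check <- function(config_a, config_b, n = NULL, n_runs = NULL) {
  stopifnot(inherits(config_a, "sim_config"), inherits(config_b, "sim_config"))
  same_stream <- function(a, b) {
    a$mu_true == b$mu_true && a$sigma == b$sigma && a$rate == b$rate
  }
  if (!same_stream(config_a$stream_x, config_b$stream_x) ||
      !same_stream(config_a$stream_y, config_b$stream_y) ||
      config_a$threshold != config_b$threshold) {
    stop(structure(
      class = c("ebpm_invalid_comparison", "error", "condition"),
      list(message = "configs must share stream specs and threshold",
           call = sys.call())))
  }
  tweak <- function(cfg) {
    if (!is.null(n)) cfg$n_steps <- as.integer(n)
    if (!is.null(n_runs)) cfg$n_runs <- as.integer(n_runs)
    cfg$seed <- config_a$seed  # common random numbers
    cfg
  }
  m_a <- final_support_means(tweak(config_a), 1L)
  m_b <- final_support_means(tweak(config_b), 1L)
  d <- m_a - m_b
  se <- stats::sd(d) / sqrt(length(d))
  structure(abs(mean(d)) <= 3 * se,
            difference = mean(d), se = se,
            means = c(a = mean(m_a), b = mean(m_b)))
}
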