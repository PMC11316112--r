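---
title: "Modelling faulty and faultless disagreement in evidence-based policymaking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling faulty and faultless disagreement in evidence-based policymaking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebpmsim)
```

## The model

Two agents, D and R, must judge how strongly the evidence supports a binary
policy. Evidence arrives from two streams, X and Y, each emitting i.i.d.
Gaussian observations with known standard deviation σ and unknown mean
(μ_X, μ_Y). Each agent tracks a conjugate posterior per stream: starting from
a N(m, s²) prior over the stream mean, after n observations with sample mean
x̄ the posterior is normal with precision 1/s² + n/σ² and mean
(m/s² + n·x̄/σ²)/(1/s² + n/σ²) (`update_belief()`). The agent's belief about
*policy support* is the linear pool of her two stream posteriors with her
weight w on stream X: mean w·μ̂_X + (1−w)·μ̂_Y and, treating the streams as
independent, variance w²·v̂_X + (1−w)²·v̂_Y (`combine_streams()`). She
recommends FOR iff the pooled mean strictly exceeds a threshold (default ½).

Fault is modelled as a systematic additive bias: a faulty reader of stream X
sees every observation shifted by b_X, so her stream-X posterior mean
converges to μ_X + b_X and her support mean to
w·(μ_X + b_X) + (1−w)·μ_Y (`limit_support()`). The *pristine case* sets all
biases to zero: the agents then differ only in their weights, which may be
legitimately held (different values, different roles), and any disagreement
is faultless.

### Assumptions worth keeping in view

* Streams are Gaussian with *known* σ; only the mean is learned.
* The support posterior is the *untruncated* linear-pool Gaussian, even
  though support is conceptually a quantity in [0, 1]. We chose this because
  the model's limiting formulas are linear, which mandatory truncation would
  break. Renormalisation onto [0, 1] (truncated-normal moments) is available
  via the `truncate` flag of `combine_streams()`/`sim_config()` and is off by
  default; with the shipped scenario parameters the two differ negligibly
  once a handful of observations have arrived.
* Ties at the threshold recommend AGAINST — a status-quo default; under
  continuous data the tie is a measure-zero event.
* Two agents, two streams, no communication between agents, no learning of
  σ. The types are parameterised so extensions are not precluded, but none
  are implemented.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `mu_true`, `sigma` | stream mean (unitless support scale), SD | scenario-specific, σ = 0.25 | published scenario values |
| `m`, `s2` | prior mean and variance per stream | 0.5, 1 | m = 0.5 is the published prior; s² is not printed anywhere, so we use a weakly informative unit variance (one observation at σ = 0.25 already carries 16× the prior's precision) |
| `w` | weight on stream X | — | the scenario's object of study |
| `bias_x`, `bias_y` | additive observation bias | 0 | pristine case |
| `threshold` | decision threshold | 0.5 | the published "here one-half" |
| `n_steps` | observations from stream Y per run | 10⁴ | beliefs are described as "settled"; at n = 10⁴ the posterior SD per stream is σ/√n ≈ 0.0025, two orders below the 0.2 support gap |
| `n_runs` | paired runs | 100 | published run count |
| `rate` | relative emission speed of a stream | 1 | the slow-stream scenario uses 0.1 |
| `inertia` | reporting lag coefficient λ | 0 | see below |

## What the simulator emulates — and what a green test establishes

`run_paired()` reproduces the published Monte Carlo design: in each run both
agents consume the *same* stream draws (common random numbers), each after
adding her own bias, so their trajectories are correlated exactly as in the
published runs. Each (seed, run, stream) triple owns an RNG substream, so
configurations are bit-reproducible and adding runs never perturbs earlier
ones. Stream Y is the clock: at step t the agent has seen t observations
from Y and ⌊rate_x · t⌋ from X — the simplest monotone schedule consistent
with a stream running "at ten percent of the speed" of the other.

The generator emulates the model's *stated world*, nothing more: stationary
Gaussian streams, constant weights and biases, no agent interaction, no
selection of which streams exist. A green test therefore establishes that
the implementation reproduces the model's behaviour (limits, disagreement
rates, variance ratios), not that real policy disputes behave this way —
real evidence streams are non-stationary, non-Gaussian, and entangled with
the processes the model deliberately sets aside.

## Reconstruction choices

Two mechanisms are used by the published figures but not specified in the
text we worked from; both are reconstructions and are flagged as such.

* **Update rule.** The exact update equations are not printed. Conjugate
  normal–normal updating with known observation variance is the unique
  standard rule consistent with "learning the true values" and the observed
  convergence to the weighted limits, and is what we commit to.
* **Inertia.** The slow-stream-with-inertia scenario says only that the
  agent's *reported* assessment lags her posterior. We implement exponential
  smoothing, `reported_t = λ·reported_{t−1} + (1−λ)·μ_t`, started at the
  prior-based support mean, with default λ = 0.9 (a half-life of ≈ 7 steps).
  `apply_inertia()` exposes the smoother directly.

Other choices where the source was silent: both agents share the same prior
per stream (one prior mean is printed, with no hint of per-agent priors;
per-agent priors remain configurable); trajectories are recorded on a
log-spaced grid by default because the published trajectory plots use
log-scaled axes; the missing config `seed` defaults to 0 with a warning
rather than an error, so every published-scenario file is runnable as-is.

## Numerical notes

* The posterior path inside the simulator is computed from running sums with
  the same closed form as `update_belief()`; tests assert exact agreement,
  and an independent grid-discretized Bayes oracle checks the closed form to
  1e−6.
* `uncertainty_curve()` is fully analytic: σ²(w) = w²v_X + (1−w)²v_Y with
  v = 1/(1/s² + n/σ²). With equal priors, SDs and counts the extreme/equal
  ratio is *exactly* 2 — the description "almost twice" matches ratios just
  below 2 that arise once the streams' effective precisions differ (e.g.
  unequal counts or a very small prior variance interacting asymmetrically).
  We report the ratio as the Result-2 statistic and bound it as ≤ 2.
* `equivalent_faultless_weight()` is closed-form algebra; degenerate stream
  means (μ_X = μ_Y) are signalled in the return value, not raised.
* `equivalence_check()` judges two configurations equivalent when the
  run-averaged final support means differ by at most 3 Monte Carlo standard
  errors of the paired per-run differences. With common random numbers an
  identical pair ties exactly; note a true 3-SE criterion still has a ≈ 0.4%
  false-alarm rate per comparison, visible as an occasional 49/50 on the
  50-point identifiability grid under unlucky seeds.

## The identifiability argument, operationally

"Empirically indistinguishable" is operationalised as *equality of limiting
support means* — the only observable the model exposes post hoc when agents
publish recommendations and support levels but not their reasoning. Under
that reading, any limit c inside the convex hull of (μ_X, μ_Y) is reachable
faultlessly by the witness weight w\* = (c − μ_Y)/(μ_X − μ_Y), so bias can
never be established; outside the hull no weight works and fault is proven.
If agents also published their posterior *uncertainties*, the witness would
additionally have to match σ² — a tie that weights alone cannot always
achieve — which is the formal face of the case for transparency of
reasoning: disclosure of the evidence considered, its weighting and judged
strength is exactly what breaks the indistinguishability.
`diagnose_limits()` reports σ-free diagnoses only; σ-based diagnostics are
available separately (`uncertainty_curve()`) without any claim that they
implement the identifiability result.

## Known limitations

* Finite-sample joint inference of (w, b) from trajectories is out of scope
  by construction — under-identification is the point of the analysis.
* The inertia mechanism and prior variance are reconstructions (above);
  conclusions that depend on their exact values should be re-run across a
  range.
* The CLI's config format is JSON only.
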