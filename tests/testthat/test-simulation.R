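test_that("draw_shared_data is deterministic per (seed, run) with independent substreams", {
  cfg <- small_fig3(n_steps = 200L)
  d1 <- draw_shared_data(cfg, 3)
  d2 <- draw_shared_data(cfg, 3)
  expect_identical(d1, d2)
  d3 <- draw_shared_data(cfg, 4)
  expect_false(any(d1$x == d3$x))
  expect_false(any(d1$y == d3$y))
  expect_length(d1$x, 200L)
  expect_length(d1$y, 200L)
})

test_that("draws respect the stream rate and the CLT bound", {
  cfg <- make_fixture("fig5_slow")
  cfg$n_steps <- 10000L
  d <- draw_shared_data(cfg, 1)
  expect_length(d$x, 1000L)  # floor(0.1 * 10000)
  expect_length(d$y, 10000L)
  expect_lt(abs(mean(d$y) - 0.2), 0.01)  # ~4 SE at sigma = 0.25
  cfg2 <- small_fig3(n_steps = 10000L)
  expect_lt(abs(mean(draw_shared_data(cfg2, 1)$x) - 0.7), 0.01)
})

test_that("run_paired is bit-reproducible and has the RunRecord shape", {
  cfg <- small_fig3(n_runs = 3L, n_steps = 300L)
  s1 <- run_paired(cfg)
  s2 <- run_paired(cfg)
  expect_identical(s1$records, s2$records)
  r <- s1$records
  expect_named(r, c("run_id", "step", "n_x", "agent", "support_mean",
                    "support_sd", "recommendation", "reported_assessment"))
  steps <- unique(r$step)
  expect_equal(nrow(r), 3L * length(steps) * 2L)
  expect_false(anyNA(r))
  expect_equal(max(r$step), 300L)
  expect_true(all(r$n_x == floor(cfg$stream_x$rate * r$step)))
})

test_that("identical pristine agents never diverge", {
  cfg <- make_fixture("fig5_equal")
  cfg$n_runs <- 4L; cfg$n_steps <- 400L
  r <- run_paired(cfg)$records
  d <- r[r$agent == "D", ]
  a <- r[r$agent == "R", ]
  expect_identical(d$support_mean, a$support_mean)
  expect_identical(d$support_sd, a$support_sd)
  expect_identical(d$recommendation, a$recommendation)
})

test_that("recorded posterior variance matches the closed form exactly", {
  cfg <- small_fig3(n_runs = 2L, n_steps = 500L)
  cfg$agents$R <- agent_spec(0.9, prior_x = prior(0.5, 2), prior_y = prior(0.3, 0.5))
  r <- run_paired(cfg)$records
  v <- function(s2, n, sigma) 1 / (1 / s2 + n / sigma^2)
  rr <- r[r$agent == "R", ]
  expected <- 0.9^2 * v(2, rr$n_x, 0.25) + 0.1^2 * v(0.5, rr$step, 0.25)
  expect_equal(rr$support_sd^2, expected, tolerance = 1e-12)
})

test_that("final support means converge to limit_support within 3 MC SE", {
  cfg <- small_fig3(n_runs = 20L, n_steps = 10000L, record = "final")
  sims <- run_paired(cfg)
  st <- list(cfg$stream_x, cfg$stream_y)
  for (ag in c("D", "R")) {
    mu <- sims$records$support_mean[sims$records$agent == ag]
    lim <- limit_support(cfg$agents[[ag]], st)
    se <- sd(mu) / sqrt(length(mu))
    expect_lt(abs(mean(mu) - lim), 3 * se + 1e-4)
  }
  # biased agent converges to the shifted limit
  cfg$agents$D <- agent_spec(0.5, bias_x = 0.2)
  mu_d <- run_paired(cfg)$records
  mu_d <- mu_d$support_mean[mu_d$agent == "D"]
  expect_lt(abs(mean(mu_d) - 0.55), 3 * sd(mu_d) / sqrt(length(mu_d)) + 1e-4)
})

test_that("apply_inertia: identity, fixed point and step-lag geometry", {
  x <- c(0.3, 0.7, 0.1, 0.9)
  expect_identical(apply_inertia(x, 0), x)
  expect_equal(apply_inertia(rep(0.4, 10), 0.9), rep(0.4, 10), tolerance = 1e-12)
  step <- c(0, rep(1, 12))
  sm <- apply_inertia(step, 0.9)
  expect_equal(sm[1], 0)
  expect_equal(sm[-1], 1 - 0.9^(1:12), tolerance = 1e-12)
  expect_equal(min(which(sm[-1] >= 0.5)), 7)  # 1 - 0.9^k >= 0.5 first at k = 7
  expect_error(apply_inertia(x, 1), class = "ebpm_invalid_parameter")
  expect_error(apply_inertia(x, -0.1), class = "ebpm_invalid_parameter")
})

test_that("inertia delays the reported assessment in simulation", {
  cfg <- make_fixture("fig5_slow_inertia")
  cfg$n_runs <- 5L; cfg$n_steps <- 500L
  r <- run_paired(cfg)$records
  early <- r[r$step <= 10 & r$agent == "D", ]
  # reported assessment stays closer to the prior-based 0.35 than the raw mean
  prior_mu <- 0.5 * 0.5 + 0.5 * 0.5
  expect_true(mean(abs(early$reported_assessment - prior_mu)) <
                mean(abs(early$support_mean - prior_mu)))
  no_inertia <- make_fixture("fig5_slow")
  no_inertia$n_runs <- 5L; no_inertia$n_steps <- 500L
  r0 <- run_paired(no_inertia)$records
  expect_identical(r0$reported_assessment, r0$support_mean)
})

test_that("fixtures carry the published scenario parameters", {
  f3 <- make_fixture("fig3")
  expect_equal(f3$stream_x$mu_true, 0.7)
  expect_equal(f3$stream_y$mu_true, 0.2)
  expect_equal(f3$stream_x$sigma, 0.25)
  expect_equal(c(f3$agents$D$w, f3$agents$R$w), c(0.5, 0.9))
  expect_equal(f3$agents$D$prior_x$m, 0.5)
  expect_equal(f3$threshold, 0.5)
  expect_equal(f3$n_runs, 100L)

  f5s <- make_fixture("fig5_slow")
  expect_equal(f5s$stream_x$mu_true, 0.8)
  expect_equal(f5s$stream_x$rate, 0.1)
  expect_equal(f5s$agents$D$w, 0.5)

  f5e <- make_fixture("fig5_equal")
  f5s$stream_x$rate <- 1
  expect_equal(f5s, f5e)  # differ only in rate_x

  expect_setequal(fixture_names(),
                  c("fig3", "fig4", "fig5_equal", "fig5_slow", "fig5_slow_inertia"))
  expect_error(make_fixture("fig6"), class = "ebpm_invalid_parameter")
})

test_that("record grids: log default, integer thinning, final-only", {
  g <- ebpmsim:::record_grid(10000L, "log")
  expect_true(all(diff(g) > 0))
  expect_equal(g[1], 1)
  expect_equal(g[length(g)], 10000L)
  expect_lt(length(g), 150)
  expect_equal(ebpmsim:::record_grid(100L, 30), c(30, 60, 90, 100))
  expect_equal(ebpmsim:::record_grid(500L, "final"), 500L)
  cfg <- small_fig3(n_runs = 2L, n_steps = 100L, record = 25)
  expect_setequal(unique(run_paired(cfg)$records$step), c(25, 50, 75, 100))
})
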