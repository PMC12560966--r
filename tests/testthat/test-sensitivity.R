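test_that("method-of-moments fits recover the stated mean and SD", {
  g <- fit_distribution(8399, 1679.8, "gamma")
  expect_equal(g$shape, 25, tolerance = 1e-12)
  expect_equal(g$scale, 335.96, tolerance = 1e-12)
  expect_equal(g$shape * g$scale, 8399, tolerance = 1e-9)
  expect_equal(sqrt(g$shape) * g$scale, 1679.8, tolerance = 1e-9)

  b <- fit_distribution(0.74, 0.02, "beta")
  m <- b$shape1 / (b$shape1 + b$shape2)
  v <- b$shape1 * b$shape2 /
    ((b$shape1 + b$shape2)^2 * (b$shape1 + b$shape2 + 1))
  expect_equal(m, 0.74, tolerance = 1e-9)
  expect_equal(sqrt(v), 0.02, tolerance = 1e-9)

  expect_error(fit_distribution(0.5, 0.5, "beta"), "inadmissible")
  expect_error(fit_distribution(0, 0.1, "beta"), "mean in \\(0, 1\\)")
  expect_error(fit_distribution(100, 0, "gamma"), "sd")
  expect_error(fit_distribution(-5, 1, "gamma"), "mean > 0")
})

test_that("parameter setter addresses shared, per-arm, common and difference keys", {
  st <- default_strategies()
  sh <- shared_parameters()
  m <- set_parameter(st, sh, "shared.cost_treat_infection", 5000)
  expect_equal(m$shared$cost_treat_infection, 5000)
  m <- set_parameter(st, sh, "TR.cost_rectal_swab", 10)
  expect_equal(m$strategies$TR$cost_rectal_swab, 10)
  expect_equal(m$strategies$TP, st$TP)
  m <- set_parameter(st, sh, "all.cost_mri", 0)
  expect_equal(m$strategies$TP$cost_mri, 0)
  expect_equal(m$strategies$TR$cost_mri, 0)
  m <- set_parameter(st, sh, "diff.cost_disposables", 100)
  expect_equal(m$strategies$TP$cost_disposables, 57.03 + 100)
  expect_error(set_parameter(st, sh, "shared.bogus", 1), "unknown")
  expect_error(set_parameter(st, sh, "TR.p_infection_7d", 2), "p_infection_7d")
})

test_that("bisection thresholds agree with an independent linear solve and
           flip the verdict across the boundary", {
  st <- default_strategies()
  sh <- shared_parameters()
  margin <- function(key, v) {
    m <- set_parameter(st, sh, key, v)
    ref <- evaluate_strategy(m$strategies$TR, m$shared)
    cmp <- evaluate_strategy(m$strategies$TP, m$shared)
    (sh$wtp * cmp$qaly_total - cmp$cost[["total"]]) -
      (sh$wtp * ref$qaly_total - ref$cost[["total"]])
  }
  # the decision margin is affine in any unit cost, so the root has a
  # closed form from two evaluations — an oracle independent of bisection
  for (key in c("shared.cost_treat_infection", "diff.cost_disposables",
                "TR.cost_rectal_swab")) {
    b <- switch(key, shared.cost_treat_infection = c(0, 8399),
                diff.cost_disposables = c(0, 1000),
                TR.cost_rectal_swab = c(0, 300))
    f0 <- margin(key, b[1])
    f1 <- margin(key, b[2])
    root <- b[1] - f0 * (b[2] - b[1]) / (f1 - f0)
    th <- one_way_threshold(key, b, st, sh)
    expect_equal(th$criterion_met, "icer_crosses_wtp")
    expect_equal(th$threshold, root, tolerance = 1e-5)
    # verdict flips across the reported boundary
    eps <- 1e-3 * diff(b)
    expect_true(margin(key, th$threshold - eps) *
                  margin(key, th$threshold + eps) < 0)
  }

  # pain duration: piecewise-linear margin; check the flip property only
  th <- one_way_threshold("TP.pain_duration_hours", c(0, 336), st, sh)
  expect_true(margin("TP.pain_duration_hours", th$threshold - 0.5) > 0)
  expect_true(margin("TP.pain_duration_hours", th$threshold + 0.5) < 0)

  # parameters whose verdict never flips in range
  none <- one_way_threshold("TR.cost_antibiotics", c(0, 100), st, sh)
  expect_equal(none$criterion_met, "none_in_range")
  expect_true(is.na(none$threshold))
  expect_equal(one_way_threshold("all.cost_mri", c(0, 2000), st,
                                 sh)$criterion_met, "none_in_range")

  # the incremental-QALY criterion finds where TP stops being more effective
  thq <- one_way_threshold("TP.pain_utility", c(0, 1), st, sh,
                           criterion = "incremental_qaly")
  expect_equal(thq$criterion_met, "dominance_lost")
  expect_true(thq$threshold > 0.15 && thq$threshold < 0.3)

  expect_error(one_way_threshold("shared.wtp", c(5, 1)), "increasing")
})

test_that("PSA distribution set follows the stated variance rules", {
  specs <- psa_distributions(arm_size = 375)
  # binomial sampling variance for observed probabilities
  d <- specs[["TR.p_infection_7d"]]$dist
  expect_equal(d$family, "beta")
  expect_equal(d$sd, sqrt(0.016 * 0.984 / 375), tolerance = 1e-12)
  # utilities with reported SDs keep them; others use the 20% rule
  expect_equal(specs[["shared.u_infection"]]$dist$sd, 0.02)
  expect_equal(specs[["shared.u_retention"]]$dist$sd, 0.03)
  expect_equal(specs[["shared.u_sepsis"]]$dist$sd, 0.2 * 0.51)
  expect_equal(specs[["shared.cost_treat_infection"]]$dist$sd, 0.2 * 8399)
  # zero-event probabilities stay fixed by default ...
  expect_equal(specs[["TP.p_infection_7d"]]$dist$family, "fixed")
  expect_equal(specs[["TP.p_infection_7d"]]$dist$value, 0)
  # ... or draw from a Jeffreys-style prior on request
  sj <- psa_distributions(arm_size = 375, zero_prob = "jeffreys")
  expect_equal(sj[["TP.p_infection_7d"]]$dist$shape1, 0.5)
  expect_equal(sj[["TP.p_infection_7d"]]$dist$shape2, 375.5)
  # common costs share one draw; arm-specific costs do not
  expect_equal(length(specs[["cost_mri.TP+TR"]]$targets), 2)
  expect_true(!is.null(specs[["cost_disposables.TP"]]))
  expect_true(!is.null(specs[["cost_disposables.TR"]]))
})

test_that("degenerate PSA reproduces the base case bit-for-bit", {
  base <- lapply(default_strategies(), evaluate_strategy,
                 shared = shared_parameters())
  p0 <- run_psa(n_draws = 4, seed = 11, sd_scale = 0,
                wtp_grid = c(0, 1e5, 2e6))
  for (k in c("TP", "TR")) {
    expect_identical(unique(p0$draws[[paste0(k, ".cost")]]),
                     unname(base[[k]]$cost[["total"]]))
    expect_identical(unique(p0$draws[[paste0(k, ".qaly")]]),
                     base[[k]]$qaly_total)
  }
  # with no parameter uncertainty the dominant strategy wins every draw
  expect_equal(unname(unlist(p0$ceac["TP"])), rep(1, 3))
})

test_that("PSA is reproducible given the seed and its CEAC is coherent", {
  a <- run_psa(n_draws = 40, seed = 33, wtp_grid = seq(0, 2e5, 5e4))
  b <- run_psa(n_draws = 40, seed = 33, wtp_grid = seq(0, 2e5, 5e4))
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  # probabilities across strategies sum to one at every WTP point
  expect_equal(unname(rowSums(a$ceac[, c("TP", "TR")])), rep(1, 5))
  expect_true(all(a$ceac$TP >= 0 & a$ceac$TP <= 1))
  # per-draw incremental columns are consistent
  expect_equal(a$draws$delta_cost, a$draws$TP.cost - a$draws$TR.cost)
  expect_equal(a$draws$infections_prevented,
               a$draws$TR.infections - a$draws$TP.infections)
})
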