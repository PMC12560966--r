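test_that("cost components sum to the total and events price correctly", {
  sh <- shared_parameters()
  for (st in default_strategies()) {
    r <- evaluate_strategy(st, sh)
    expect_equal(unname(r$cost[["total"]]),
                 unname(sum(r$cost[setdiff(names(r$cost), "total")])),
                 tolerance = 1e-9)
    # one-time entry costs: infection line = incidence x unit cost
    expect_equal(unname(r$cost[["infection"]]),
                 r$infections_per_1000 / 1000 * sh$cost_treat_infection,
                 tolerance = 1e-12)
    expect_equal(unname(r$cost[["retention"]]),
                 r$retentions_per_1000 / 1000 * sh$cost_treat_retention,
                 tolerance = 1e-12)
  }
  # complication-free strategy costs exactly the fixed bundle
  r0 <- evaluate_strategy(zero_complication_strategy(), sh)
  expect_equal(unname(r0$cost[["total"]]), 466 + 2066)
})

test_that("sepsis overlays incremental cost on the infection line", {
  sh <- shared_parameters()
  st <- strategy("septic TR", p_infection_7d = 0.046, p_sepsis_7d = 0.022,
                 p_retention_7d = 0.011, cost_disposables = 57.03,
                 cost_antibiotics = 4.68)
  r <- evaluate_strategy(st, sh)
  expect_equal(r$sepsis_per_1000, 22, tolerance = 1e-9)
  expect_equal(unname(r$cost[["infection"]]),
               0.046 * 8399 + 0.022 * (23435 - 8399), tolerance = 1e-9)
  # sepsis without infection is incoherent and rejected at construction
  expect_error(strategy("bad", p_infection_7d = 0, p_sepsis_7d = 0.01),
               "p_sepsis_7d")
})

test_that("QALY accumulation attains the perfect-health bound and matches a
           closed-form oracle when no infections occur", {
  sh <- shared_parameters()
  r0 <- evaluate_strategy(zero_complication_strategy(), sh)
  expect_equal(r0$qaly_total, (sh$horizon_days + 1) / sh$days_per_year,
               tolerance = 1e-15)

  # TP has no infections: the retention tunnel and pain adjustment have an
  # exact closed form, computed independently of the engine
  tp <- default_strategies()$TP
  expect_equal(evaluate_strategy(tp, sh)$qaly_total,
               oracle_qaly_no_infection(0.003, 0.83, 1, sh),
               tolerance = 1e-12)

  # pain longer than one cycle spills into later cycles
  tp48 <- tp
  tp48$pain_duration_hours <- 48
  long <- evaluate_strategy(tp48, sh)$qaly_total
  short <- evaluate_strategy(tp, sh)$qaly_total
  expect_lt(long, short)
  # roughly 47/24 extra pain-days at (1 - 0.83), diluted by tunnel occupancy
  expect_equal(short - long, 47 / 24 * (1 - 0.83) / 365, tolerance = 0.01)

  # QALYs never exceed the perfect-health bound
  for (st in default_strategies()) {
    expect_lte(evaluate_strategy(st, sh)$qaly_total,
               (sh$horizon_days + 1) / sh$days_per_year)
  }
})

test_that("comparison verdicts cover dominance, equivalence and the ICER", {
  sh <- shared_parameters()
  st <- default_strategies()
  tr <- evaluate_strategy(st$TR, sh)
  tp <- evaluate_strategy(st$TP, sh)

  cmp <- compare(tr, tp, wtp = sh$wtp)
  expect_equal(cmp$verdict, "dominant")
  expect_true(is.na(cmp$icer))
  expect_lt(cmp$delta_cost, 0)
  expect_gt(cmp$delta_qaly, 0)
  expect_gt(cmp$nmb_comparator, cmp$nmb_reference)
  # events prevented = reference minus comparator
  expect_equal(cmp$events_prevented_per_1000[["infections"]],
               tr$infections_per_1000 - tp$infections_per_1000)
  expect_equal(cmp$events_prevented_per_1000[["retentions"]],
               tr$retentions_per_1000 - tp$retentions_per_1000)

  # reversed direction: dominated
  expect_equal(compare(tp, tr, wtp = sh$wtp)$verdict, "dominated")
  # identical strategies: equivalent, zero deltas
  same <- compare(tr, tr, wtp = sh$wtp)
  expect_equal(same$verdict, "equivalent")
  expect_equal(same$delta_cost, 0)

  # a genuinely informative ICER: costlier and more effective comparator
  dear <- st$TP
  dear$cost_disposables <- 1000
  cmp2 <- compare(tr, evaluate_strategy(dear, sh), wtp = sh$wtp)
  expect_false(is.na(cmp2$icer))
  expect_equal(cmp2$icer, cmp2$delta_cost / cmp2$delta_qaly)
  expect_equal(cmp2$verdict, "not_cost_effective") # ICER far above 100k
})

test_that("NMB ordering and the ICER decision rule agree everywhere", {
  set.seed(202)
  sh <- shared_parameters()
  for (i in 1:30) {
    a <- strategy("a", p_infection_7d = runif(1, 0, 0.05),
                  p_retention_7d = runif(1, 0, 0.05),
                  cost_disposables = runif(1, 0, 400),
                  pain_utility = runif(1, 0.5, 1))
    b <- strategy("b", p_infection_7d = runif(1, 0, 0.05),
                  p_retention_7d = runif(1, 0, 0.05),
                  cost_disposables = runif(1, 0, 400),
                  pain_utility = runif(1, 0.5, 1))
    wtp <- runif(1, 0, 5e5)
    cmp <- compare(evaluate_strategy(a, sh), evaluate_strategy(b, sh), wtp)
    nmb_prefers <- cmp$nmb_comparator > cmp$nmb_reference
    icer_prefers <- switch(cmp$verdict,
                           dominant = TRUE,
                           dominated = FALSE,
                           equivalent = FALSE,
                           cost_minimization = cmp$delta_cost < 0,
                           cost_effective = ,
                           not_cost_effective =
                             if (cmp$delta_qaly > 0) cmp$icer < wtp
                             else cmp$icer > wtp)
    expect_equal(nmb_prefers, icer_prefers,
                 label = sprintf("draw %d (verdict %s)", i, cmp$verdict))
  }
})

test_that("the results table mirrors the per-strategy evaluations", {
  sh <- shared_parameters()
  res <- lapply(default_strategies(), evaluate_strategy, shared = sh)
  tab <- ce_table(res, reference = "TR", wtp = sh$wtp)
  expect_equal(names(tab), c("quantity", "TP with MRI", "TR with MRI"))
  get <- function(col, q) tab[[col]][tab$quantity == q]
  expect_equal(get("TR with MRI", "Total cost"),
               unname(res$TR$cost[["total"]]))
  expect_equal(get("TP with MRI", "Incremental cost"),
               unname(res$TP$cost[["total"]] - res$TR$cost[["total"]]))
  expect_true(is.na(get("TR with MRI", "ICER")))
})
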