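test_that("expanded state space unrolls the tunnels in a stable order", {
  sh <- shared_parameters()
  ss <- build_state_space(sh)
  # Healthy + 7 infection + 3 retention + 3 combined + PostRetention + Recovered
  expect_equal(nrow(ss), 16)
  expect_equal(ss$state[1], "Healthy")
  expect_equal(ss$state[nrow(ss)], "Recovered")
  expect_equal(sum(ss$tag == "Infection"), 7)
  expect_equal(sum(ss$tag == "Retention"), 3)
  expect_equal(sum(ss$tag == "Combined"), 3)
  expect_true(all(c("Retention1", "Retention2", "Retention3") %in% ss$state))
  expect_equal(ss$tunnel_day[ss$tag == "Infection"], 1:7)

  ss1 <- build_state_space(shared_parameters(infection_tunnel_days = 1,
                                             retention_tunnel_days = 1,
                                             combined_tunnel_days = 1,
                                             event_window_days = 1,
                                             horizon_days = 2))
  expect_equal(nrow(ss1), 6)
})

test_that("transition matrices are stochastic with deterministic tunnels", {
  sh <- shared_parameters()
  for (st in default_strategies()) {
    for (win in c(TRUE, FALSE)) {
      M <- build_transition_matrix(st, sh, in_event_window = win)
      expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
      # combined tunnel states have exactly one successor
      for (d in 1:3) {
        row <- M[paste0("Combined", d), ]
        expect_equal(sum(row > 0), 1)
        expect_equal(max(row), 1)
      }
      expect_equal(unname(M["Combined3", "Infection4"]), 1)
      expect_equal(unname(M["Recovered", "Recovered"]), 1)
    }
  }
})

test_that("healthy-row hazards match the closed-form daily probabilities", {
  sh <- shared_parameters()
  st <- default_strategies()$TR
  M <- build_transition_matrix(st, sh, in_event_window = TRUE)
  pd_i <- oracle_daily_prob(0.016, 7)
  pd_r <- oracle_daily_prob(0.011, 7)
  # frozen closed-form arithmetic: 0.0023015 * (1 - 0.0015789)
  expect_equal(unname(M["Healthy", "Infection1"]), 0.00229791091297439,
               tolerance = 1e-12)
  expect_equal(unname(M["Healthy", "Infection1"]), pd_i * (1 - pd_r),
               tolerance = 1e-12)
  expect_equal(unname(M["Healthy", "Combined1"]), pd_i * pd_r,
               tolerance = 1e-12)
  expect_equal(unname(M["Healthy", "Retention1"]), pd_r * (1 - pd_i),
               tolerance = 1e-12)
  # hazards also apply to the other complication's tunnel (independent
  # first-event processes)
  expect_equal(unname(M["Infection3", "Combined1"]), pd_r, tolerance = 1e-12)
  expect_equal(unname(M["Retention2", "Combined1"]), pd_i, tolerance = 1e-12)
  expect_equal(unname(M["PostRetention", "Infection1"]), pd_i,
               tolerance = 1e-12)

  # zero-complication strategy: Healthy row is the identity
  M0 <- build_transition_matrix(zero_complication_strategy(), sh, TRUE)
  expect_equal(unname(M0["Healthy", "Healthy"]), 1)

  # after the event window Healthy is absorbing
  Mpost <- build_transition_matrix(st, sh, in_event_window = FALSE)
  expect_equal(unname(Mpost["Healthy", "Healthy"]), 1)
  expect_equal(unname(Mpost["PostRetention", "Recovered"]), 1)
})

test_that("cohort is conserved at every cycle across random parameter sets", {
  set.seed(101)
  for (i in 1:20) {
    st <- strategy("rand",
                   p_infection_7d = runif(1, 0, 0.3),
                   p_retention_7d = runif(1, 0, 0.3),
                   cost_disposables = runif(1, 0, 500),
                   pain_utility = runif(1, 0.5, 1),
                   pain_duration_hours = sample(0:72, 1))
    tr <- run_cohort(st, shared_parameters())
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, nrow(tr$occupancy)),
                 tolerance = 1e-10)
    expect_true(all(tr$entrants$infection >= 0))
    expect_true(all(tr$entrants$retention >= 0))
  }
})

test_that("cumulative entrants reproduce the 7-day input probabilities", {
  sh <- shared_parameters()
  st <- default_strategies()
  tr <- run_cohort(st$TR, sh)
  ev <- cumulative_entrants(tr)
  # infection incidence is exact: a first-event hazard applied to everyone
  # not yet infected integrates back to the window probability
  expect_equal(ev[["infection"]], 0.016, tolerance = 1e-12)
  # retention is exact up to a < 1e-7 second-order re-entry term (patients
  # whose retention resolved through Combined re-enter the infection tunnel)
  expect_lt(abs(ev[["retention"]] - 0.011), 1e-6)

  tp <- run_cohort(st$TP, sh)
  ev_tp <- cumulative_entrants(tp)
  expect_equal(ev_tp[["infection"]], 0)
  expect_equal(ev_tp[["retention"]], 0.003, tolerance = 1e-12)

  # no complications -> everyone Healthy at every cycle
  t0 <- run_cohort(zero_complication_strategy(), sh)
  expect_equal(unname(t0$occupancy[, "Healthy"]), rep(1, sh$horizon_days + 1))

  # no entries after the event window closes
  expect_equal(tr$entrants$infection[(sh$event_window_days + 1):sh$horizon_days],
               rep(0, sh$horizon_days - sh$event_window_days))
})

test_that("trace export carries occupancy and entrant columns per cycle", {
  tr <- run_cohort(default_strategies()$TR)
  df <- trace_as_df(tr)
  expect_equal(nrow(df), 15)
  expect_true(all(c("cycle", "Healthy", "Infection1", "new_infections",
                    "new_retentions") %in% names(df)))
  expect_equal(sum(df$new_infections), 0.016, tolerance = 1e-12)
})
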