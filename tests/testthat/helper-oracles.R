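# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: closed forms and straight per-trajectory
# summation only.

# closed-form daily probability and window incidence for a first-event
# process with constant hazard
oracle_daily_prob <- function(p, t) 1 - (1 - p)^(1 / t)
oracle_window_incidence <- function(p_daily, w) 1 - (1 - p_daily)^w

# closed-form QALY total for a strategy with no infections (retention is
# then an unperturbed first-event tunnel and no Combined state arises)
oracle_qaly_no_infection <- function(p_ret, pain_u, pain_h, shared) {
  pd <- oracle_daily_prob(p_ret, shared$event_window_days)
  slots <- shared$horizon_days + 1
  ret_days <- p_ret * shared$retention_tunnel_days
  healthy_slot1 <- (1 - pd)
  pain_days <- healthy_slot1 * min(pain_h, 24) / 24  # pain fits in cycle 1
  (slots - ret_days * (shared$u_healthy - shared$u_retention) -
     pain_days * (shared$u_healthy - pain_u)) / shared$days_per_year
}

# naive per-trajectory accountant: recompute one simulated patient's cost
# and QALY by walking the expanded per-day state sequence
naive_account <- function(states, sepsis, strat, shared) {
  u_ip <- if (sepsis) shared$u_sepsis else shared$u_infection
  u_of <- function(s) {
    if (s %in% c("Healthy", "PostRetention", "Recovered")) return(shared$u_healthy)
    if (startsWith(s, "Infection")) return(u_ip)
    if (startsWith(s, "Retention")) return(shared$u_retention)
    if (startsWith(s, "Combined")) return(u_ip * shared$u_retention)
    stop("unknown state ", s)
  }
  util <- sum(vapply(states, u_of, numeric(1)))
  h <- strat$pain_duration_hours
  cyc <- 1
  while (h > 0 && cyc <= shared$horizon_days) {
    if (states[cyc + 1] == "Healthy") {
      util <- util - min(h, 24) / 24 * (shared$u_healthy - strat$pain_utility)
    }
    h <- h - 24
    cyc <- cyc + 1
  }
  had_inf <- any(startsWith(states, "Infection") | startsWith(states, "Combined"))
  had_ret <- any(startsWith(states, "Retention") | startsWith(states, "Combined"))
  cost <- strat$cost_mri + strat$cost_procedure +
    (strat$cost_disposables - shared$cost_disposables_baseline) +
    strat$cost_antibiotics + strat$cost_rectal_swab +
    had_inf * shared$cost_treat_infection +
    sepsis * (shared$cost_treat_sepsis - shared$cost_treat_infection) +
    had_ret * shared$cost_treat_retention
  c(cost = cost, qaly = util / shared$days_per_year)
}

# a complication-free strategy whose upfront disposables equal the baseline
# kit, so its only cost is the fixed bundle
zero_complication_strategy <- function(shared = shared_parameters()) {
  strategy("no complications", p_infection_7d = 0, p_retention_7d = 0,
           cost_disposables = shared$cost_disposables_baseline,
           cost_antibiotics = 0, cost_rectal_swab = 0,
           pain_utility = 1, pain_duration_hours = 0)
}
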