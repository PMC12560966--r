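#' Individual-level microsimulation of patient trajectories
#'
#' Brute-force stochastic counterpart of [run_cohort()]: each simulated
#' patient starts Healthy and, on every day of the event window, draws
#' independent Bernoulli events for first infection (while not yet
#' infected) and first retention (while not yet retained) at the model's
#' daily probabilities. Tunnel mechanics, joint-occurrence routing through
#' the Combined state, sepsis assignment (a `p_sepsis/p_infection` fraction
#' of infection entrants), costs and QALYs all follow the same rules as the
#' cohort engine, so sample means converge to the cohort expectations at
#' the usual `1/sqrt(n)` Monte Carlo rate — which is what makes this a
#' validation oracle for the deterministic trace.
#'
#' @param strat [strategy()].
#' @param shared [shared_parameters()]; the horizon must be long enough to
#'   hold every tunnel entered during the event window
#'   (`horizon_days >= event_window_days + infection_tunnel_days - 1` for
#'   base-style parameters).
#' @param n_patients Number of simulated patients.
#' @param seed Optional RNG seed.
#' @return Object of class `microsim_result`: `patients` (data.frame with
#'   per-patient infection/retention entry days, sepsis flag, realized
#'   `cost` and `qaly`), `summary` (means with Monte Carlo standard
#'   errors), and the inputs.
#' @export
simulate_patients <- function(strat, shared = shared_parameters(),
                              n_patients = 10000, seed = NULL) {
  stopifnot(n_patients >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- shared$event_window_days
  need <- w + shared$infection_tunnel_days - 1
  if (shared$horizon_days < need) {
    stop("horizon too short for the microsimulation's closed-form ",
         "day accounting", call. = FALSE)
  }
  pi_d <- daily_prob(strat$p_infection_7d, w)
  pr_d <- daily_prob(strat$p_retention_7d, w)

  first_event_day <- function(p) {
    if (p == 0) return(rep(NA_integer_, n_patients))
    day <- rep(NA_integer_, n_patients)
    for (d in seq_len(w)) {
      hit <- is.na(day) & stats::runif(n_patients) < p
      day[hit] <- d
    }
    day
  }
  ti <- first_event_day(pi_d)
  tr <- first_event_day(pr_d)
  inf <- !is.na(ti)
  ret <- !is.na(tr)
  f_sep <- sepsis_fraction(strat)
  sepsis <- inf & stats::runif(n_patients) < f_sep

  cost <- strat$cost_mri + strat$cost_procedure +
    (strat$cost_disposables - shared$cost_disposables_baseline) +
    strat$cost_antibiotics + strat$cost_rectal_swab +
    inf * shared$cost_treat_infection +
    sepsis * (shared$cost_treat_sepsis - shared$cost_treat_infection) +
    ret * shared$cost_treat_retention

  qaly <- microsim_qalys(ti, tr, sepsis, strat, shared)

  patients <- data.frame(infection_day = ti, retention_day = tr,
                         sepsis = sepsis, cost = cost, qaly = qaly)
  mse <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(n_patients))
  structure(list(
    patients = patients,
    n_patients = n_patients, seed = seed,
    strategy = strat, shared = shared,
    summary = list(
      cost = mse(cost), qaly = mse(qaly),
      infections_per_1000 = mse(inf * 1000),
      retentions_per_1000 = mse(ret * 1000),
      sepsis_per_1000 = mse(sepsis * 1000)
    )
  ), class = "microsim_result")
}

# Closed-form per-patient day accounting mirroring the cohort engine's
# routing: retention striking the infected (or infection striking the
# retained) spends combined_tunnel_days in Combined before the infection
# tunnel resumes at day combined_tunnel_days + 1.
microsim_qalys <- function(ti, tr, sepsis, strat, shared) {
  n_i <- shared$infection_tunnel_days
  n_r <- shared$retention_tunnel_days
  n_c <- shared$combined_tunnel_days
  u_ip <- ifelse(sepsis, shared$u_sepsis, shared$u_infection)
  u_r <- shared$u_retention
  u_h <- shared$u_healthy

  inf <- !is.na(ti)
  ret <- !is.na(tr)
  ti0 <- ifelse(inf, ti, 0L)
  tr0 <- ifelse(ret, tr, 0L)

  # slot counts by sojourn type
  d_c <- numeric(length(ti))    # combined days
  d_r <- numeric(length(ti))    # retention-only days
  d_i <- numeric(length(ti))    # infection-only days
  only_i <- inf & !ret
  only_r <- ret & !inf
  both <- inf & ret
  d_i[only_i] <- n_i
  d_r[only_r] <- n_r
  # retention during (or simultaneous with) the infection tunnel
  b1 <- both & ti0 <= tr0
  d_c[b1] <- n_c
  d_i[b1] <- (tr0[b1] - ti0[b1]) + (n_i - n_c)
  # infection while still in the retention tunnel (or leaving it)
  b2 <- both & tr0 < ti0 & ti0 <= tr0 + n_r
  d_c[b2] <- n_c
  d_r[b2] <- ti0[b2] - tr0[b2]
  d_i[b2] <- n_i - n_c
  # infection after retention resolved: independent episodes
  b3 <- both & ti0 > tr0 + n_r
  d_i[b3] <- n_i
  d_r[b3] <- n_r

  util_days <- (shared$horizon_days + 1) * u_h -
    d_i * (u_h - u_ip) - d_r * (u_h - u_r) - d_c * (u_h - u_ip * u_r)

  # procedural pain while Healthy, mirroring the cohort accumulator
  h <- strat$pain_duration_hours
  cyc <- 1
  while (h > 0 && cyc <= shared$horizon_days) {
    frac <- min(h, 24) / 24
    healthy <- (!inf | cyc < ti0) & (!ret | cyc < tr0)
    util_days <- util_days - healthy * frac * (u_h - strat$pain_utility)
    h <- h - 24
    cyc <- cyc + 1
  }
  util_days / shared$days_per_year
}

#' Expand selected simulated patients into per-day state sequences
#'
#' Audit view of a microsimulation: one row per patient-cycle with the
#' expanded-state label the patient occupies, built from the recorded event
#' days by an explicit day-by-day state machine (independent of the
#' closed-form accounting used for QALYs).
#'
#' @param sim A [simulate_patients()] result.
#' @param ids Patient indices to expand (default: first 100).
#' @return data.frame with columns `patient`, `cycle`, `state`.
#' @export
trajectories <- function(sim, ids = seq_len(min(100, sim$n_patients))) {
  shared <- sim$shared
  n_i <- shared$infection_tunnel_days
  n_r <- shared$retention_tunnel_days
  n_c <- shared$combined_tunnel_days
  out <- lapply(ids, function(id) {
    ti <- sim$patients$infection_day[id]
    tr <- sim$patients$retention_day[id]
    st <- character(shared$horizon_days + 1)
    phase <- "Healthy"
    day_in <- 0L
    for (cyc in 0:shared$horizon_days) {
      if (cyc > 0) {
        new_inf <- !is.na(ti) && cyc == ti
        new_ret <- !is.na(tr) && cyc == tr
        if (phase == "Healthy") {
          if (new_inf && new_ret) { phase <- "Combined"; day_in <- 1L }
          else if (new_inf) { phase <- "Infection"; day_in <- 1L }
          else if (new_ret) { phase <- "Retention"; day_in <- 1L }
        } else if (phase == "PostRetention") {
          if (new_inf) { phase <- "Infection"; day_in <- 1L }
          else if (cyc > shared$event_window_days) phase <- "Recovered"
        } else if (phase == "Infection") {
          if (new_ret) { phase <- "Combined"; day_in <- 1L }
          else if (day_in < n_i) day_in <- day_in + 1L
          else { phase <- "Recovered"; day_in <- 0L }
        } else if (phase == "Retention") {
          if (new_inf) { phase <- "Combined"; day_in <- 1L }
          else if (day_in < n_r) day_in <- day_in + 1L
          else { phase <- "PostRetention"; day_in <- 0L }
        } else if (phase == "Combined") {
          if (day_in < n_c) day_in <- day_in + 1L
          else if (n_c + 1 <= n_i) { phase <- "Infection"; day_in <- n_c + 1L }
          else { phase <- "Recovered"; day_in <- 0L }
        }
      }
      st[cyc + 1] <- if (day_in > 0) paste0(phase, day_in) else phase
    }
    data.frame(patient = id, cycle = 0:shared$horizon_days, state = st,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("Microsimulation: %s, n = %d%s\n", x$strategy$name,
              x$n_patients,
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  s <- x$summary
  cat(sprintf("  mean cost  %10.2f (SE %.3f)\n", s$cost["mean"], s$cost["se"]))
  cat(sprintf("  mean QALY  %10.7f (SE %.2e)\n", s$qaly["mean"], s$qaly["se"]))
  cat(sprintf("  infections / 1000: %6.2f (SE %.2f)\n",
              s$infections_per_1000["mean"], s$infections_per_1000["se"]))
  cat(sprintf("  retentions / 1000: %6.2f (SE %.2f)\n",
              s$retentions_per_1000["mean"], s$retentions_per_1000["se"]))
  invisible(x)
}
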