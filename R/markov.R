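#' Build the expanded (tunnel-unrolled) state space
#'
#' The five health states of the model — Healthy, Infection, Urinary
#' Retention, Combined (both complications), Recovered — with each
#' complication state unrolled into per-day tunnel sub-states so that time in
#' state is fixed: infection lasts `infection_tunnel_days` cycles (7),
#' retention `retention_tunnel_days` (3), and Combined
#' `combined_tunnel_days` (3) before continuing into the infection tunnel.
#'
#' A sixth bookkeeping tag, `PostRetention`, holds patients whose retention
#' has resolved inside the event window: they are back at full health but,
#' never having been infected, remain at risk of a first infection until the
#' window closes. It carries the healthy-state utility and merges into
#' `Recovered` once the window is over.
#'
#' @param shared [shared_parameters()].
#' @return A data.frame with columns `state` (label), `tag` (one of Healthy,
#'   Infection, Retention, Combined, PostRetention, Recovered) and
#'   `tunnel_day` (NA for non-tunnel tags), in the fixed order used by every
#'   matrix and trace in the package. 16 states for base parameters.
#' @export
build_state_space <- function(shared) {
  tags <- c("Healthy",
            rep("Infection", shared$infection_tunnel_days),
            rep("Retention", shared$retention_tunnel_days),
            rep("Combined", shared$combined_tunnel_days),
            "PostRetention", "Recovered")
  day <- c(NA, seq_len(shared$infection_tunnel_days),
           seq_len(shared$retention_tunnel_days),
           seq_len(shared$combined_tunnel_days), NA, NA)
  lbl <- ifelse(is.na(day), tags, paste0(tags, day))
  data.frame(state = lbl, tag = tags, tunnel_day = day,
             stringsAsFactors = FALSE)
}

#' Build the daily transition matrix
#'
#' During the event window each complication acts as an independent
#' first-event hazard: the daily infection probability applies to everyone
#' not yet infected (Healthy, the retention tunnel, PostRetention) and the
#' daily retention probability to everyone not yet retained (Healthy, the
#' infection tunnel). Joint acquisition — either simultaneously from Healthy
#' or by one complication striking a patient in the other's tunnel — routes
#' to the Combined tunnel, which resolves into the infection tunnel once the
#' retention has resolved. After the event window no new complications
#' arise; tunnels simply run out and Healthy/Recovered are absorbing.
#'
#' @param strat [strategy()].
#' @param shared [shared_parameters()].
#' @param in_event_window Logical: build the matrix for cycles inside the
#'   event window (complication hazards active) or after it.
#' @return Square matrix over [build_state_space()], rows summing to 1.
#' @export
build_transition_matrix <- function(strat, shared, in_event_window = TRUE) {
  ss <- build_state_space(shared)
  n <- nrow(ss)
  M <- matrix(0, n, n, dimnames = list(ss$state, ss$state))
  t_win <- shared$event_window_days
  pi_d <- if (in_event_window) daily_prob(strat$p_infection_7d, t_win) else 0
  pr_d <- if (in_event_window) daily_prob(strat$p_retention_7d, t_win) else 0

  n_i <- shared$infection_tunnel_days
  n_r <- shared$retention_tunnel_days
  n_c <- shared$combined_tunnel_days
  inf1 <- paste0("Infection", 1)
  ret1 <- paste0("Retention", 1)
  com1 <- paste0("Combined", 1)

  M["Healthy", inf1] <- pi_d * (1 - pr_d)
  M["Healthy", ret1] <- pr_d * (1 - pi_d)
  M["Healthy", com1] <- pi_d * pr_d
  M["Healthy", "Healthy"] <- (1 - pi_d) * (1 - pr_d)

  for (d in seq_len(n_i)) {
    from <- paste0("Infection", d)
    to <- if (d < n_i) paste0("Infection", d + 1) else "Recovered"
    M[from, com1] <- pr_d               # retention strikes the infected
    M[from, to] <- 1 - pr_d
  }
  for (d in seq_len(n_r)) {
    from <- paste0("Retention", d)
    to <- if (d < n_r) paste0("Retention", d + 1) else "PostRetention"
    M[from, com1] <- pi_d               # infection strikes the retained
    M[from, to] <- 1 - pi_d
  }
  # combined continues into the infection tunnel once retention has resolved
  cont <- if (n_c + 1 <= n_i) paste0("Infection", n_c + 1) else "Recovered"
  for (d in seq_len(n_c)) {
    from <- paste0("Combined", d)
    to <- if (d < n_c) paste0("Combined", d + 1) else cont
    M[from, to] <- 1
  }
  if (in_event_window) {
    M["PostRetention", inf1] <- pi_d    # still at risk of a first infection
    M["PostRetention", "PostRetention"] <- 1 - pi_d
  } else {
    M["PostRetention", "Recovered"] <- 1
  }
  M["Recovered", "Recovered"] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("internal consistency error: transition-matrix rows do not sum to 1",
         call. = FALSE)
  }
  M
}

#' Run the deterministic cohort trace
#'
#' Starts the whole cohort in Healthy and advances it cycle by cycle over
#' the time horizon, using the in-window transition matrix for cycles
#' `1..event_window_days` and the post-window matrix thereafter. Alongside
#' occupancy, the trace records state-*entry* fractions: a new infection is
#' an entry into Infection(1) or Combined(1) (from wherever), a new
#' retention an entry into Retention(1) or Combined(1). Events are counted
#' by entry (incidence), not occupancy, and complication treatment costs are
#' charged per entry.
#'
#' @param strat [strategy()].
#' @param shared [shared_parameters()].
#' @return Object of class `cohort_trace`: list with `occupancy`
#'   (`(horizon_days + 1) x n_states` matrix, rows = cycles 0..horizon),
#'   `entrants` (data.frame with per-cycle `infection` and `retention` entry
#'   fractions), `states` (the state-space data.frame), and the inputs.
#' @export
run_cohort <- function(strat, shared = shared_parameters()) {
  ss <- build_state_space(shared)
  n <- nrow(ss)
  M_in <- build_transition_matrix(strat, shared, in_event_window = TRUE)
  M_out <- build_transition_matrix(strat, shared, in_event_window = FALSE)

  horizon <- shared$horizon_days
  occ <- matrix(0, horizon + 1, n, dimnames = list(0:horizon, ss$state))
  occ[1, "Healthy"] <- 1

  inf_src <- c("Healthy", paste0("Retention", seq_len(shared$retention_tunnel_days)),
               "PostRetention")
  ret_src <- c("Healthy", paste0("Infection", seq_len(shared$infection_tunnel_days)))
  inf_dst <- c("Infection1", "Combined1")
  ret_dst <- c("Retention1", "Combined1")

  entr <- data.frame(cycle = seq_len(horizon), infection = 0, retention = 0)
  for (cyc in seq_len(horizon)) {
    M <- if (cyc <= shared$event_window_days) M_in else M_out
    prev <- occ[cyc, ]
    occ[cyc + 1, ] <- prev %*% M
    # entry flows, decomposed by source so Combined entries from the
    # infection tunnel count as retentions only (and vice versa)
    entr$infection[cyc] <- sum(prev[inf_src] * M[inf_src, inf_dst])
    entr$retention[cyc] <- sum(prev[ret_src] * M[ret_src, ret_dst])
  }

  if (any(abs(rowSums(occ) - 1) > 1e-10)) {
    stop("internal consistency error: cohort not conserved", call. = FALSE)
  }
  structure(list(occupancy = occ, entrants = entr, states = ss,
                 strategy = strat, shared = shared),
            class = "cohort_trace")
}

#' Total state-entry fractions over the horizon
#'
#' @param trace A [run_cohort()] trace.
#' @return Named numeric: cumulative `infection` and `retention` entry
#'   fractions (per patient; multiply by 1000 for per-1000 reporting).
#' @export
cumulative_entrants <- function(trace) {
  c(infection = sum(trace$entrants$infection),
    retention = sum(trace$entrants$retention))
}

#' Export a cohort trace as a data.frame
#'
#' One row per cycle, one column per expanded state, plus the per-cycle
#' entry fractions — suitable for CSV export.
#'
#' @param trace A [run_cohort()] trace.
#' @return data.frame.
#' @export
trace_as_df <- function(trace) {
  df <- data.frame(cycle = as.integer(rownames(trace$occupancy)),
                   trace$occupancy, check.names = FALSE)
  df$new_infections <- c(0, trace$entrants$infection)
  df$new_retentions <- c(0, trace$entrants$retention)
  df
}
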