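#' Accumulate per-patient costs from a cohort trace
#'
#' Upfront components (MRI + procedure fee as the fixed bundle, disposables
#' net of the standard-kit baseline, prophylactic antibiotics, rectal swab)
#' are charged once per patient at cycle 0. Complication treatment costs are
#' one-time entry costs: `cost_treat_infection` per entry into the infection
#' or combined tunnel, `cost_treat_retention` per entry into the retention
#' or combined tunnel. A fixed fraction `p_sepsis_7d / p_infection_7d` of
#' infection entrants additionally incurs
#' `cost_treat_sepsis - cost_treat_infection`; this increment is folded into
#' the infection line. All values are expectations over the cohort.
#'
#' @param trace A [run_cohort()] trace.
#' @param strat,shared The inputs the trace was produced under (defaults:
#'   taken from the trace).
#' @return Named numeric with components `fixed`, `disposables`,
#'   `antibiotics`, `swab`, `infection`, `retention` and their sum `total`,
#'   in US$ per patient.
#' @export
accumulate_costs <- function(trace, strat = trace$strategy,
                             shared = trace$shared) {
  if (strat$p_sepsis_7d > 0 && strat$p_infection_7d == 0) {
    stop("p_sepsis_7d > 0 requires p_infection_7d > 0 (sepsis is a subset of infection)",
         call. = FALSE)
  }
  ev <- cumulative_entrants(trace)
  f_sep <- sepsis_fraction(strat)
  cost <- c(
    fixed = strat$cost_mri + strat$cost_procedure,
    disposables = strat$cost_disposables - shared$cost_disposables_baseline,
    antibiotics = strat$cost_antibiotics,
    swab = strat$cost_rectal_swab,
    infection = ev[["infection"]] * shared$cost_treat_infection +
      f_sep * ev[["infection"]] *
        (shared$cost_treat_sepsis - shared$cost_treat_infection),
    retention = ev[["retention"]] * shared$cost_treat_retention
  )
  c(cost, total = sum(cost))
}

sepsis_fraction <- function(strat) {
  if (strat$p_infection_7d > 0) strat$p_sepsis_7d / strat$p_infection_7d else 0
}

# state utilities over the expanded space, with the sepsis fraction of the
# infection (and combined) tunnel carrying u_sepsis instead of u_infection
state_utilities <- function(states, strat, shared) {
  f_sep <- sepsis_fraction(strat)
  u_inf <- (1 - f_sep) * shared$u_infection + f_sep * shared$u_sepsis
  u <- c(Healthy = shared$u_healthy,
         Infection = u_inf,
         Retention = shared$u_retention,
         Combined = u_inf * shared$u_retention,
         PostRetention = shared$u_healthy,
         Recovered = shared$u_healthy)
  unname(u[states$tag])
}

#' Accumulate per-patient QALYs from a cohort trace
#'
#' Each of the `horizon_days + 1` daily accumulation slots (cycle-0
#' occupancy through the final cycle) contributes the occupancy-weighted
#' mean utility times `1 day / days_per_year`. State utilities:
#' Healthy/PostRetention/Recovered carry `u_healthy`, the infection tunnel
#' `u_infection` (with the sepsis fraction at `u_sepsis`), the retention
#' tunnel `u_retention`, and Combined the product of its two components'
#' utilities. Procedural pain replaces `pain_duration_hours / 24` of the
#' Healthy-state utility with `pain_utility`, starting at cycle 1 and
#' spilling into later cycles when the duration exceeds 24 h.
#'
#' @inheritParams accumulate_costs
#' @return QALYs per patient over the horizon.
#' @export
accumulate_qalys <- function(trace, strat = trace$strategy,
                             shared = trace$shared) {
  u <- state_utilities(trace$states, strat, shared)
  util_days <- sum(trace$occupancy %*% u)
  # pain adjustment on the Healthy occupancy of cycles 1, 2, ...
  h <- strat$pain_duration_hours
  cyc <- 1
  while (h > 0 && cyc <= shared$horizon_days) {
    frac <- min(h, 24) / 24
    util_days <- util_days - trace$occupancy[cyc + 1, "Healthy"] * frac *
      (shared$u_healthy - strat$pain_utility)
    h <- h - 24
    cyc <- cyc + 1
  }
  util_days / shared$days_per_year
}

#' Evaluate one strategy: cohort run plus economic accumulation
#'
#' @param strat [strategy()].
#' @param shared [shared_parameters()].
#' @return Object of class `econ_result`: costs (see
#'   [accumulate_costs()]), `qaly_total`, and event incidence per 1000
#'   patients (`infections_per_1000`, `retentions_per_1000`,
#'   `sepsis_per_1000`).
#' @export
evaluate_strategy <- function(strat, shared = shared_parameters()) {
  trace <- run_cohort(strat, shared)
  cost <- accumulate_costs(trace, strat, shared)
  ev <- cumulative_entrants(trace)
  res <- list(
    strategy = strat$name,
    cost = cost,
    qaly_total = accumulate_qalys(trace, strat, shared),
    infections_per_1000 = ev[["infection"]] * 1000,
    retentions_per_1000 = ev[["retention"]] * 1000,
    sepsis_per_1000 = sepsis_fraction(strat) * ev[["infection"]] * 1000
  )
  class(res) <- "econ_result"
  res
}

#' Compare two evaluated strategies
#'
#' Computes incremental cost and QALYs (comparator minus reference), the
#' ICER or a dominance verdict, net monetary benefit (`NMB = wtp * QALY -
#' cost`) for both strategies, events prevented per 1000 patients, and the
#' cost per event prevented. The latter adds the event's treatment-cost
#' difference back to the incremental cost before dividing by events
#' prevented per 1000, so it isolates what is spent (beyond the complication
#' treatment itself) to avoid one event; for sepsis the add-back is the full
#' infection cost line, of which sepsis treatment is part.
#'
#' @param reference,comparator [evaluate_strategy()] results under the same
#'   shared parameters.
#' @param wtp Willingness-to-pay threshold, US$/QALY.
#' @return Object of class `ce_comparison` with `delta_cost`, `delta_qaly`,
#'   `icer` (NA under dominance), `verdict` (one of `dominant`, `dominated`,
#'   `equivalent`, `cost_minimization`, `cost_effective`,
#'   `not_cost_effective`), `nmb_reference`, `nmb_comparator`,
#'   `events_prevented_per_1000` and `cost_per_event_prevented` (named:
#'   infections, retentions, sepsis).
#' @export
compare <- function(reference, comparator, wtp = 100000) {
  dc <- comparator$cost[["total"]] - reference$cost[["total"]]
  dq <- comparator$qaly_total - reference$qaly_total
  nmb_ref <- wtp * reference$qaly_total - reference$cost[["total"]]
  nmb_cmp <- wtp * comparator$qaly_total - comparator$cost[["total"]]

  icer <- NA_real_
  if (dc == 0 && dq == 0) {
    verdict <- "equivalent"
  } else if (dc <= 0 && dq >= 0) {
    verdict <- "dominant"
  } else if (dc >= 0 && dq <= 0) {
    verdict <- "dominated"
  } else if (dq == 0) {
    verdict <- "cost_minimization"
  } else {
    icer <- dc / dq
    verdict <- if (nmb_cmp > nmb_ref) "cost_effective" else "not_cost_effective"
  }

  prevented <- c(
    infections = reference$infections_per_1000 - comparator$infections_per_1000,
    retentions = reference$retentions_per_1000 - comparator$retentions_per_1000,
    sepsis = reference$sepsis_per_1000 - comparator$sepsis_per_1000
  )
  addback <- c(
    infections = reference$cost[["infection"]] - comparator$cost[["infection"]],
    retentions = reference$cost[["retention"]] - comparator$cost[["retention"]],
    sepsis = reference$cost[["infection"]] - comparator$cost[["infection"]]
  )
  cpe <- ifelse(prevented != 0, (dc + addback) / prevented, NA_real_)

  structure(list(
    reference = reference$strategy, comparator = comparator$strategy,
    delta_cost = dc, delta_qaly = dq, icer = icer, verdict = verdict,
    wtp = wtp, nmb_reference = nmb_ref, nmb_comparator = nmb_cmp,
    events_prevented_per_1000 = prevented,
    cost_per_event_prevented = cpe
  ), class = "ce_comparison")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("Strategy: %s\n", x$strategy))
  cat("Costs (per patient, US$):\n")
  for (nm in names(x$cost)) {
    cat(sprintf("  %-12s %10.2f\n", nm, x$cost[[nm]]))
  }
  cat(sprintf("QALYs (per patient):     %.7f\n", x$qaly_total))
  cat(sprintf("Infections  / 1000:      %.2f\n", x$infections_per_1000))
  cat(sprintf("Retentions  / 1000:      %.2f\n", x$retentions_per_1000))
  if (x$sepsis_per_1000 > 0) {
    cat(sprintf("Sepsis      / 1000:      %.2f\n", x$sepsis_per_1000))
  }
  invisible(x)
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (reference)\n", x$comparator, x$reference))
  cat(sprintf("  Incremental cost:  %9.2f US$/patient\n", x$delta_cost))
  cat(sprintf("  Incremental QALY:  %+.7f\n", x$delta_qaly))
  cat(sprintf("  ICER:              %s\n",
              if (is.na(x$icer)) x$verdict else sprintf("%.0f US$/QALY (%s)",
                                                        x$icer, x$verdict)))
  cat(sprintf("  NMB at %s US$/QALY: reference %.2f, comparator %.2f\n",
              format(x$wtp, big.mark = ","), x$nmb_reference, x$nmb_comparator))
  prev <- x$events_prevented_per_1000
  cpe <- x$cost_per_event_prevented
  for (nm in names(prev)) {
    if (prev[[nm]] != 0) {
      cat(sprintf("  %-11s prevented / 1000: %6.2f   cost/prevented: %8.2f\n",
                  nm, prev[[nm]], cpe[[nm]]))
    }
  }
  invisible(x)
}
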