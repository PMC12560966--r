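#' Convert a cumulative probability to a constant daily rate
#'
#' Complication risks are observed as cumulative probabilities over an event
#' window (here 7 days) but the model advances in 1-day cycles, so each
#' probability `p` is converted to a constant hazard `r = -ln(1 - p) / t`.
#' The corresponding per-cycle probability is `1 - exp(-r)` (see
#' [daily_rate_to_prob()]), which makes the round trip
#' `1 - (1 - p_daily)^t == p` exact.
#'
#' @param p_cumulative Probability of the event over the whole window, in
#'   `[0, 1)`.
#' @param t_days Length of the window in days (> 0).
#' @return Rate per day (>= 0).
#' @examples
#' prob_to_daily_rate(0.016, 7)
#' @export
prob_to_daily_rate <- function(p_cumulative, t_days) {
  if (!is.numeric(p_cumulative) || any(p_cumulative < 0)) {
    stop("`p_cumulative` must be a non-negative probability", call. = FALSE)
  }
  if (any(p_cumulative >= 1)) {
    stop("`p_cumulative` must be < 1: a certain event has no finite rate",
         call. = FALSE)
  }
  if (!is.numeric(t_days) || any(t_days <= 0)) {
    stop("`t_days` must be positive", call. = FALSE)
  }
  -log1p(-p_cumulative) / t_days
}

#' Convert a daily rate to a per-cycle probability
#'
#' @param r Rate per day (>= 0).
#' @return Probability `1 - exp(-r)` of the event within one 1-day cycle.
#' @examples
#' daily_rate_to_prob(prob_to_daily_rate(0.016, 7))
#' @export
daily_rate_to_prob <- function(r) {
  if (!is.numeric(r) || any(r < 0)) {
    stop("`r` must be a non-negative rate", call. = FALSE)
  }
  -expm1(-r)
}

#' Per-cycle event probability from a cumulative probability
#'
#' Convenience composition of [prob_to_daily_rate()] and
#' [daily_rate_to_prob()].
#'
#' @inheritParams prob_to_daily_rate
#' @return Daily probability in `[0, 1)`.
#' @export
daily_prob <- function(p_cumulative, t_days) {
  daily_rate_to_prob(prob_to_daily_rate(p_cumulative, t_days))
}

#' Shared model parameters
#'
#' Parameters common to every biopsy strategy: complication treatment costs
#' (2024 US$), health-state utilities, the event window during which new
#' complications can arise, tunnel durations, the time horizon, and the
#' willingness-to-pay threshold. Defaults are the model's base-case values.
#'
#' `cost_disposables_baseline` is the cost of the standard transrectal
#' disposable kit; each strategy's disposable cost enters the accounting net
#' of this baseline, so strategy totals reflect consumables beyond the
#' standard kit (see the package vignette for why).
#'
#' @param cost_treat_infection US$ to treat a post-biopsy infection.
#' @param cost_treat_retention US$ to treat an episode of urinary retention.
#' @param cost_treat_sepsis US$ to treat sepsis (applied as an increment over
#'   the infection treatment cost for the sepsis fraction).
#' @param u_healthy,u_infection,u_retention,u_sepsis Health-state utilities
#'   in `[0, 1]`.
#' @param sd_u_infection,sd_u_retention Standard deviations of the infection
#'   and retention utilities used in probabilistic sensitivity analysis.
#' @param event_window_days Days during which new complications can arise.
#' @param horizon_days Time-horizon length in days.
#' @param infection_tunnel_days,retention_tunnel_days,combined_tunnel_days
#'   Fixed sojourn times of the tunnel states, in cycles.
#' @param days_per_year Calendar constant converting utility-days to QALYs.
#' @param cost_disposables_baseline US$ cost of the standard (transrectal)
#'   disposable kit netted out of every strategy's disposable line.
#' @param wtp Willingness-to-pay threshold, US$ per QALY.
#' @param cohort_size Cohort size used when reporting events "per 1000".
#' @return A list of class `shared_parameters`.
#' @export
shared_parameters <- function(cost_treat_infection = 8399,
                              cost_treat_retention = 1776,
                              cost_treat_sepsis = 23435,
                              u_healthy = 1.00,
                              u_infection = 0.74,
                              u_retention = 0.87,
                              u_sepsis = 0.51,
                              sd_u_infection = 0.02,
                              sd_u_retention = 0.03,
                              event_window_days = 7L,
                              horizon_days = 14L,
                              infection_tunnel_days = 7L,
                              retention_tunnel_days = 3L,
                              combined_tunnel_days = 3L,
                              days_per_year = 365,
                              cost_disposables_baseline = 57.03,
                              wtp = 100000,
                              cohort_size = 1000) {
  shared <- list(
    cost_treat_infection = cost_treat_infection,
    cost_treat_retention = cost_treat_retention,
    cost_treat_sepsis = cost_treat_sepsis,
    u_healthy = u_healthy, u_infection = u_infection,
    u_retention = u_retention, u_sepsis = u_sepsis,
    sd_u_infection = sd_u_infection, sd_u_retention = sd_u_retention,
    event_window_days = as.integer(event_window_days),
    horizon_days = as.integer(horizon_days),
    infection_tunnel_days = as.integer(infection_tunnel_days),
    retention_tunnel_days = as.integer(retention_tunnel_days),
    combined_tunnel_days = as.integer(combined_tunnel_days),
    days_per_year = days_per_year,
    cost_disposables_baseline = cost_disposables_baseline,
    wtp = wtp, cohort_size = cohort_size
  )
  class(shared) <- "shared_parameters"
  validate_shared(shared)
  shared
}

#' Define a biopsy strategy
#'
#' Bundles one strategy's 7-day complication probabilities, cost components
#' (2024 US$), and procedural-pain settings.
#'
#' @param name Strategy label.
#' @param p_infection_7d Cumulative infection probability over the event
#'   window.
#' @param p_retention_7d Cumulative urinary-retention probability.
#' @param p_sepsis_7d Cumulative sepsis probability; must not exceed
#'   `p_infection_7d` (sepsis is modelled as a subset of infections).
#' @param cost_mri,cost_procedure,cost_disposables,cost_antibiotics,cost_rectal_swab
#'   Per-patient cost components in US$.
#' @param pain_utility Utility applied during the procedural-pain window.
#' @param pain_duration_hours Duration of elevated procedural pain, hours.
#' @return A list of class `biopsy_strategy`.
#' @examples
#' strategy("TP no prophylaxis", p_infection_7d = 0, p_retention_7d = 0.003,
#'          cost_disposables = 218.92, pain_utility = 0.83)
#' @export
strategy <- function(name,
                     p_infection_7d = 0,
                     p_retention_7d = 0,
                     p_sepsis_7d = 0,
                     cost_mri = 466,
                     cost_procedure = 2066,
                     cost_disposables = 0,
                     cost_antibiotics = 0,
                     cost_rectal_swab = 0,
                     pain_utility = 1,
                     pain_duration_hours = 1) {
  strat <- list(
    name = name,
    p_infection_7d = p_infection_7d,
    p_retention_7d = p_retention_7d,
    p_sepsis_7d = p_sepsis_7d,
    cost_mri = cost_mri, cost_procedure = cost_procedure,
    cost_disposables = cost_disposables,
    cost_antibiotics = cost_antibiotics,
    cost_rectal_swab = cost_rectal_swab,
    pain_utility = pain_utility,
    pain_duration_hours = pain_duration_hours
  )
  class(strat) <- "biopsy_strategy"
  validate_strategy(strat)
  strat
}

validate_strategy <- function(strat) {
  bad <- character()
  prb <- c("p_infection_7d", "p_retention_7d", "p_sepsis_7d", "pain_utility")
  for (f in prb) {
    v <- strat[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad <- c(bad, sprintf("%s must be a probability/utility in [0, 1]", f))
    }
  }
  if (is.numeric(strat$p_sepsis_7d) && is.numeric(strat$p_infection_7d) &&
      length(strat$p_sepsis_7d) == 1 && length(strat$p_infection_7d) == 1 &&
      !anyNA(c(strat$p_sepsis_7d, strat$p_infection_7d)) &&
      strat$p_sepsis_7d > strat$p_infection_7d) {
    bad <- c(bad, "p_sepsis_7d must not exceed p_infection_7d")
  }
  cst <- c("cost_mri", "cost_procedure", "cost_disposables",
           "cost_antibiotics", "cost_rectal_swab")
  for (f in cst) {
    v <- strat[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      bad <- c(bad, sprintf("%s must be a non-negative cost", f))
    }
  }
  if (!is.numeric(strat$pain_duration_hours) ||
      length(strat$pain_duration_hours) != 1 ||
      is.na(strat$pain_duration_hours) || strat$pain_duration_hours < 0) {
    bad <- c(bad, "pain_duration_hours must be >= 0")
  }
  if (length(bad)) {
    stop(sprintf("invalid strategy '%s':\n  - %s",
                 strat$name, paste(bad, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(strat)
}

validate_shared <- function(shared) {
  bad <- character()
  for (f in c("cost_treat_infection", "cost_treat_retention",
              "cost_treat_sepsis", "cost_disposables_baseline", "wtp")) {
    v <- shared[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      bad <- c(bad, sprintf("%s must be a non-negative number", f))
    }
  }
  for (f in c("u_healthy", "u_infection", "u_retention", "u_sepsis")) {
    v <- shared[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad <- c(bad, sprintf("%s must be a utility in [0, 1]", f))
    }
  }
  for (f in c("infection_tunnel_days", "retention_tunnel_days",
              "combined_tunnel_days")) {
    v <- shared[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1) {
      bad <- c(bad, sprintf("%s must be >= 1 cycle", f))
    }
  }
  if (shared$horizon_days < shared$event_window_days) {
    bad <- c(bad, "horizon_days must be >= event_window_days")
  }
  if (shared$days_per_year <= 0) bad <- c(bad, "days_per_year must be > 0")
  if (length(bad)) {
    stop(sprintf("invalid shared parameters:\n  - %s",
                 paste(bad, collapse = "\n  - ")), call. = FALSE)
  }
  invisible(shared)
}

#' Base-case strategy definitions
#'
#' The two office-based, MRI-guided biopsy strategies of the base case:
#' transperineal without antibiotic prophylaxis (`TP`) and transrectal with
#' rectal-swab-targeted prophylaxis (`TR`). Trial-derived 7-day complication
#' probabilities: TP infection 0%, retention 0.3%; TR infection 1.6%,
#' retention 1.1%. The transperineal arm carries a temporary pain utility of
#' 0.83 (a 1.2-fold higher immediate post-procedural pain score, 1/1.2) for
#' its first hour.
#'
#' @return Named list with elements `TP` and `TR`, each a
#'   [strategy()] object.
#' @export
default_strategies <- function() {
  list(
    TP = strategy(
      name = "TP with MRI",
      p_infection_7d = 0, p_retention_7d = 0.003,
      cost_mri = 466, cost_procedure = 2066,
      cost_disposables = 218.92,
      cost_antibiotics = 0, cost_rectal_swab = 0,
      pain_utility = 0.83, pain_duration_hours = 1
    ),
    TR = strategy(
      name = "TR with MRI",
      p_infection_7d = 0.016, p_retention_7d = 0.011,
      cost_mri = 466, cost_procedure = 2066,
      cost_disposables = 57.03,
      cost_antibiotics = 5.51, cost_rectal_swab = 91,
      pain_utility = 1, pain_duration_hours = 1
    )
  )
}

#' Load a model configuration from YAML or JSON
#'
#' Reads a configuration file with optional top-level `shared:` and
#' `strategies:` sections. Any field not present falls back to the base-case
#' default, so an empty file (or `path = NULL`) yields the default model.
#' Strategy entries are keyed `TP` / `TR` (or add new keys for additional
#' arms) and may override any [strategy()] field; `shared:` may override any
#' [shared_parameters()] field. All invariants are re-validated after
#' merging, and violations are reported with the offending fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults.
#' @return List with elements `strategies` (named list of
#'   [strategy()] objects) and `shared` ([shared_parameters()]).
#' @export
load_config <- function(path = NULL) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      stop("config must be .yaml, .yml or .json: ", path, call. = FALSE)
    }
    if (is.null(cfg)) cfg <- list()
    unknown <- setdiff(names(cfg), c("shared", "strategies"))
    if (length(unknown)) {
      stop("unknown top-level config sections: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  shared_args <- cfg$shared %||% list()
  unknown <- setdiff(names(shared_args), names(formals(shared_parameters)))
  if (length(unknown)) {
    stop("unknown shared parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  shared <- do.call(shared_parameters, shared_args)

  strategies <- default_strategies()
  for (key in names(cfg$strategies)) {
    over <- cfg$strategies[[key]]
    base <- strategies[[key]]
    if (is.null(base)) {
      # a brand-new arm: requires full specification through strategy()
      fields <- setdiff(names(formals(strategy)), "name")
      unknown <- setdiff(names(over), c("name", fields))
      if (length(unknown)) {
        stop(sprintf("unknown fields for strategy '%s': %s", key,
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      over$name <- over$name %||% key
      strategies[[key]] <- do.call(strategy, over)
    } else {
      unknown <- setdiff(names(over), names(base))
      if (length(unknown)) {
        stop(sprintf("unknown fields for strategy '%s': %s", key,
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      base[names(over)] <- over
      strategies[[key]] <- validate_strategy(base)
    }
  }
  list(strategies = strategies, shared = shared)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
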