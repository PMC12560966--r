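#' Set a model parameter by dotted key
#'
#' Addresses any model input for sensitivity analysis:
#' * `shared.<field>` — a [shared_parameters()] field;
#' * `<strategy>.<field>` — a field of one strategy (by list key, e.g.
#'   `TP.pain_duration_hours`);
#' * `all.<field>` — the same field in every strategy (e.g. `all.cost_mri`);
#' * `diff.<field>` — sets the comparator's field to the reference's value
#'   plus `value` (used for "difference between arms" analyses, e.g.
#'   `diff.cost_disposables`, `diff.p_infection_7d`).
#'
#' @param strategies Named list of [strategy()] objects.
#' @param shared [shared_parameters()].
#' @param key Dotted parameter key.
#' @param value New value.
#' @param comparator,reference Strategy keys used by `diff.` parameters.
#' @return List with modified `strategies` and `shared`, both re-validated.
#' @export
set_parameter <- function(strategies, shared, key, value,
                          comparator = "TP", reference = "TR") {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("parameter key must be '<scope>.<field>': ", key, call. = FALSE)
  }
  scope <- parts[1]
  field <- parts[2]
  if (scope == "shared") {
    if (!field %in% names(shared)) {
      stop("unknown shared parameter: ", field, call. = FALSE)
    }
    shared[[field]] <- value
    validate_shared(shared)
  } else if (scope == "all") {
    for (k in names(strategies)) {
      strategies[[k]][[field]] <- value
      validate_strategy(strategies[[k]])
    }
  } else if (scope == "diff") {
    base <- strategies[[reference]][[field]]
    if (is.null(base)) stop("unknown strategy field: ", field, call. = FALSE)
    strategies[[comparator]][[field]] <- base + value
    validate_strategy(strategies[[comparator]])
  } else {
    if (!scope %in% names(strategies)) {
      stop("unknown strategy key: ", scope, call. = FALSE)
    }
    if (!field %in% names(strategies[[scope]])) {
      stop("unknown strategy field: ", field, call. = FALSE)
    }
    strategies[[scope]][[field]] <- value
    validate_strategy(strategies[[scope]])
  }
  list(strategies = strategies, shared = shared)
}

# signed decision criterion at one parameter value: > 0 means the comparator
# is preferred under the chosen rule
decision_margin <- function(strategies, shared, key, value, wtp,
                            criterion, comparator, reference) {
  mod <- set_parameter(strategies, shared, key, value,
                       comparator = comparator, reference = reference)
  ref <- evaluate_strategy(mod$strategies[[reference]], mod$shared)
  cmp <- evaluate_strategy(mod$strategies[[comparator]], mod$shared)
  if (criterion == "nmb") {
    (wtp * cmp$qaly_total - cmp$cost[["total"]]) -
      (wtp * ref$qaly_total - ref$cost[["total"]])
  } else {
    cmp$qaly_total - ref$qaly_total
  }
}

#' One-way threshold sensitivity analysis
#'
#' Varies a single parameter over `bounds` and locates, by bisection, the
#' value at which the comparator strategy's cost-effectiveness verdict
#' flips. The default verdict is the net-monetary-benefit comparison at
#' `wtp` (equivalent to the ICER-vs-threshold rule in every quadrant,
#' without the sign ambiguity of raw ICER ratios). `criterion =
#' "incremental_qaly"` instead finds where the comparator stops being more
#' effective (incremental QALY crosses zero), the boundary at which
#' dominance is lost on the effectiveness side.
#'
#' A coarse scan (65 grid points) brackets the sign change before bisection,
#' which then runs to a relative precision of 1e-6.
#'
#' @param key Dotted parameter key (see [set_parameter()]).
#' @param bounds Length-2 numeric search interval.
#' @param strategies,shared Model inputs (defaults: base case).
#' @param wtp Willingness-to-pay, US$/QALY.
#' @param criterion `"nmb"` or `"incremental_qaly"`.
#' @param comparator,reference Strategy keys.
#' @return Object of class `threshold_result`: `parameter`, `threshold`
#'   (NA when no flip), `criterion_met` (`icer_crosses_wtp`,
#'   `dominance_lost`, or `none_in_range`), `bounds`, and the signed
#'   decision margins at the bounds.
#' @export
one_way_threshold <- function(key, bounds,
                              strategies = default_strategies(),
                              shared = shared_parameters(),
                              wtp = shared$wtp,
                              criterion = c("nmb", "incremental_qaly"),
                              comparator = "TP", reference = "TR") {
  criterion <- match.arg(criterion)
  if (length(bounds) != 2 || !is.numeric(bounds) || bounds[1] >= bounds[2]) {
    stop("`bounds` must be an increasing numeric interval", call. = FALSE)
  }
  f <- function(v) decision_margin(strategies, shared, key, v, wtp,
                                   criterion, comparator, reference)
  grid <- seq(bounds[1], bounds[2], length.out = 65)
  fv <- vapply(grid, f, numeric(1))
  sg <- sign(fv)
  flip <- which(sg[-1] * sg[-length(sg)] < 0 | sg[-length(sg)] == 0)
  met <- if (criterion == "nmb") "icer_crosses_wtp" else "dominance_lost"
  if (!length(flip)) {
    return(structure(list(parameter = key, threshold = NA_real_,
                          criterion = criterion,
                          criterion_met = "none_in_range", bounds = bounds,
                          margin_lower = fv[1],
                          margin_upper = fv[length(fv)]),
                     class = "threshold_result"))
  }
  lo <- grid[flip[1]]
  hi <- grid[flip[1] + 1]
  flo <- fv[flip[1]]
  while ((hi - lo) > 1e-6 * max(abs(lo), abs(hi), 1e-12)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo) && fm != 0) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  structure(list(parameter = key, threshold = (lo + hi) / 2,
                 criterion = criterion, criterion_met = met, bounds = bounds,
                 margin_lower = fv[1], margin_upper = fv[length(fv)]),
            class = "threshold_result")
}

#' Standard one-way sensitivity table
#'
#' Runs [one_way_threshold()] over the model's clinical, cost and utility
#' parameters, each across a wide plausible range. The pain-utility row is
#' reported under both decision criteria, since its net-monetary-benefit
#' verdict never flips on the unit interval while its incremental-QALY sign
#' does.
#'
#' @param strategies,shared Model inputs.
#' @param wtp Willingness-to-pay, US$/QALY.
#' @return data.frame with columns `parameter`, `key`, `criterion`,
#'   `lower`, `upper`, `threshold` (NA when no flip in range).
#' @export
one_way_table <- function(strategies = default_strategies(),
                          shared = shared_parameters(),
                          wtp = shared$wtp) {
  rows <- list(
    list("Difference in probability of infection (TP vs TR)",
         "diff.p_infection_7d", "nmb", -0.016, 0.03),
    list("Difference in probability of retention (TP vs TR)",
         "diff.p_retention_7d", "nmb", -0.011, 0.08),
    list("Duration of pain from procedure (hours)",
         "TP.pain_duration_hours", "nmb", 0, 336),
    list("Prostate MRI cost", "all.cost_mri", "nmb", 0, 2000),
    list("Prostate biopsy procedure fee", "all.cost_procedure", "nmb", 0, 6000),
    list("Cost of rectal swab", "TR.cost_rectal_swab", "nmb", 0, 300),
    list("Cost of prophylactic antibiotics", "TR.cost_antibiotics",
         "nmb", 0, 100),
    list("Difference in disposable costs (TP vs TR)",
         "diff.cost_disposables", "nmb", 0, 1000),
    list("Cost to treat infection", "shared.cost_treat_infection",
         "nmb", 0, 8399),
    list("Cost to treat urinary retention", "shared.cost_treat_retention",
         "nmb", 0, 10000),
    list("Temporary utility for TP arm (pain)", "TP.pain_utility",
         "nmb", 0, 1),
    list("Temporary utility for TP arm (pain)", "TP.pain_utility",
         "incremental_qaly", 0, 1),
    list("Infection utility", "shared.u_infection", "nmb", 0, 1),
    list("Urinary retention utility", "shared.u_retention", "nmb", 0, 1)
  )
  out <- lapply(rows, function(r) {
    th <- one_way_threshold(r[[2]], c(r[[4]], r[[5]]), strategies, shared,
                            wtp = wtp, criterion = r[[3]])
    data.frame(parameter = r[[1]], key = r[[2]], criterion = r[[3]],
               lower = r[[4]], upper = r[[5]], threshold = th$threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit a beta or gamma distribution by method of moments
#'
#' @param mean,sd Target mean and standard deviation.
#' @param family `"beta"` (for quantities bounded in `[0, 1]`) or `"gamma"`
#'   (for non-negative costs).
#' @return List of class `psa_distribution` with the family and shape
#'   parameters (`shape1`/`shape2` for beta, `shape`/`scale` for gamma).
#' @examples
#' fit_distribution(8399, 1679.8, "gamma")  # shape 25, scale 335.96
#' @export
fit_distribution <- function(mean, sd, family = c("beta", "gamma")) {
  family <- match.arg(family)
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) {
      stop("beta requires mean in (0, 1); degenerate parameters need a ",
           "fixed or prior-based handling, not method of moments",
           call. = FALSE)
    }
    if (sd^2 >= mean * (1 - mean)) {
      stop("inadmissible beta: sd^2 must be < mean * (1 - mean)",
           call. = FALSE)
    }
    k <- mean * (1 - mean) / sd^2 - 1
    structure(list(family = "beta", shape1 = mean * k,
                   shape2 = (1 - mean) * k, mean = mean, sd = sd),
              class = "psa_distribution")
  } else {
    if (mean <= 0) stop("gamma requires mean > 0", call. = FALSE)
    structure(list(family = "gamma", shape = (mean / sd)^2,
                   scale = sd^2 / mean, mean = mean, sd = sd),
              class = "psa_distribution")
  }
}

psa_draw <- function(dist, n) {
  switch(dist$family,
         fixed = rep(dist$value, n),
         beta = stats::rbeta(n, dist$shape1, dist$shape2),
         gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale))
}

fixed_dist <- function(value) {
  structure(list(family = "fixed", value = value), class = "psa_distribution")
}

#' Build the PSA parameter-distribution set
#'
#' Beta distributions for clinical event probabilities and health-state
#' utilities, gamma for costs. Clinical probabilities get binomial sampling
#' variance from the trial arm size (`sd = sqrt(p (1 - p) / arm_size)`);
#' utilities use their reported standard deviations where available
#' (infection 0.02, retention 0.03) and otherwise — like every cost — a
#' standard deviation of 20% of the baseline value. Parameters observed at
#' zero events carry zero sampling variance and stay fixed by default;
#' `zero_prob = "jeffreys"` instead draws them from a Jeffreys-style
#' `beta(0.5, arm_size + 0.5)`. Shared parameters are drawn once per
#' replicate and applied to every strategy; per-arm clinical probabilities
#' are drawn per arm; cost components equal across arms (MRI, procedure
#' fee) share one draw so that common costs cancel in the comparison, while
#' arm-specific costs are drawn per arm.
#'
#' @param strategies,shared Model inputs.
#' @param arm_size Trial arm size behind the binomial variances.
#' @param zero_prob `"fixed"` or `"jeffreys"`.
#' @param sd_scale Multiplier on every standard deviation; 0 collapses all
#'   distributions to point masses (degenerate PSA).
#' @return Named list of parameter specs (`targets`, `dist`).
#' @export
psa_distributions <- function(strategies = default_strategies(),
                              shared = shared_parameters(),
                              arm_size = 375,
                              zero_prob = c("fixed", "jeffreys"),
                              sd_scale = 1) {
  zero_prob <- match.arg(zero_prob)
  specs <- list()
  add <- function(id, targets, mean, sd, family) {
    specs[[id]] <<- list(
      targets = targets,
      dist = if (sd * sd_scale == 0) fixed_dist(mean) else
        fit_distribution(mean, sd * sd_scale, family)
    )
  }
  # shared treatment costs and utilities
  for (f in c("cost_treat_infection", "cost_treat_retention",
              "cost_treat_sepsis")) {
    add(paste0("shared.", f), list(c("shared", f)), shared[[f]],
        0.2 * shared[[f]], "gamma")
  }
  add("shared.u_infection", list(c("shared", "u_infection")),
      shared$u_infection, shared$sd_u_infection, "beta")
  add("shared.u_retention", list(c("shared", "u_retention")),
      shared$u_retention, shared$sd_u_retention, "beta")
  add("shared.u_sepsis", list(c("shared", "u_sepsis")), shared$u_sepsis,
      0.2 * shared$u_sepsis, "beta")

  # per-arm clinical probabilities: binomial sampling variance
  for (k in names(strategies)) {
    for (f in c("p_infection_7d", "p_retention_7d", "p_sepsis_7d")) {
      p <- strategies[[k]][[f]]
      id <- paste0(k, ".", f)
      if (p == 0) {
        if (zero_prob == "jeffreys" && f != "p_sepsis_7d" && sd_scale > 0) {
          specs[[id]] <- list(targets = list(c(k, f)),
                              dist = structure(list(family = "beta",
                                                    shape1 = 0.5,
                                                    shape2 = arm_size + 0.5),
                                               class = "psa_distribution"))
        } else {
          specs[[id]] <- list(targets = list(c(k, f)), dist = fixed_dist(0))
        }
      } else {
        add(id, list(c(k, f)), p, sqrt(p * (1 - p) / arm_size), "beta")
      }
    }
    # pain utility is a utility parameter; a value of 1 is degenerate
    u <- strategies[[k]]$pain_utility
    if (u < 1) {
      add(paste0(k, ".pain_utility"), list(c(k, "pain_utility")), u,
          0.2 * u, "beta")
    }
  }

  # strategy cost components: one draw per distinct baseline value, so
  # genuinely common costs cancel between arms
  for (f in c("cost_mri", "cost_procedure", "cost_disposables",
              "cost_antibiotics", "cost_rectal_swab")) {
    vals <- vapply(strategies, function(s) s[[f]], numeric(1))
    for (v in unique(vals[vals > 0])) {
      ks <- names(vals)[vals == v]
      add(paste0(f, ".", paste(ks, collapse = "+")),
          lapply(ks, function(k) c(k, f)), v, 0.2 * v, "gamma")
    }
  }
  specs
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: every replicate draws
#' all model parameters simultaneously from [psa_distributions()], runs the
#' full cohort model for every strategy, and records per-draw costs, QALYs
#' and event incidence. Cost-effectiveness acceptability curves (CEACs) are
#' computed on a willingness-to-pay grid as the fraction of draws in which
#' each strategy has the highest net monetary benefit, ties broken toward
#' the reference strategy.
#'
#' @param strategies,shared Model inputs.
#' @param n_draws Number of Monte Carlo replicates.
#' @param seed RNG seed (recorded in the result).
#' @param wtp_grid Willingness-to-pay grid, US$/QALY.
#' @param arm_size,zero_prob,sd_scale Passed to [psa_distributions()].
#' @param comparator,reference Strategy keys used for the incremental
#'   per-draw summaries and CEAC tie-breaks.
#' @return Object of class `psa_result`: `draws` (per-draw data.frame with
#'   cost/QALY/events per strategy and incremental columns), `ceac`
#'   (data.frame `wtp` + one probability column per strategy), `summary`
#'   (medians and quartiles of the incremental outcomes), `seed`,
#'   `n_draws`.
#' @export
run_psa <- function(strategies = default_strategies(),
                    shared = shared_parameters(),
                    n_draws = 5000, seed = NULL,
                    wtp_grid = seq(0, 2e6, by = 1e4),
                    arm_size = 375, zero_prob = c("fixed", "jeffreys"),
                    sd_scale = 1,
                    comparator = "TP", reference = "TR") {
  zero_prob <- match.arg(zero_prob)
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  specs <- psa_distributions(strategies, shared, arm_size = arm_size,
                             zero_prob = zero_prob, sd_scale = sd_scale)
  samples <- vapply(specs, function(sp) psa_draw(sp$dist, n_draws),
                    numeric(n_draws))
  if (n_draws == 1) samples <- matrix(samples, nrow = 1,
                                      dimnames = list(NULL, names(specs)))

  keys <- names(strategies)
  cols <- c("cost", "qaly", "infections", "retentions", "sepsis",
            "cost_infection", "cost_retention")
  out <- lapply(keys, function(k)
    matrix(NA_real_, n_draws, length(cols), dimnames = list(NULL, cols)))
  names(out) <- keys

  for (i in seq_len(n_draws)) {
    strat_i <- strategies
    shared_i <- shared
    for (j in seq_along(specs)) {
      v <- unname(samples[i, j])
      for (tg in specs[[j]]$targets) {
        if (tg[1] == "shared") shared_i[[tg[2]]] <- v
        else strat_i[[tg[1]]][[tg[2]]] <- v
      }
    }
    # a drawn sepsis probability may not exceed the drawn infection one
    for (k in keys) {
      if (strat_i[[k]]$p_sepsis_7d > strat_i[[k]]$p_infection_7d) {
        strat_i[[k]]$p_sepsis_7d <- strat_i[[k]]$p_infection_7d
      }
      r <- evaluate_strategy(strat_i[[k]], shared_i)
      out[[k]][i, ] <- c(r$cost[["total"]], r$qaly_total,
                         r$infections_per_1000, r$retentions_per_1000,
                         r$sepsis_per_1000, r$cost[["infection"]],
                         r$cost[["retention"]])
    }
  }

  ceac <- ceac_from_draws(out, wtp_grid, reference)

  dc <- out[[comparator]][, "cost"] - out[[reference]][, "cost"]
  dq <- out[[comparator]][, "qaly"] - out[[reference]][, "qaly"]
  inf_prev <- out[[reference]][, "infections"] - out[[comparator]][, "infections"]
  ret_prev <- out[[reference]][, "retentions"] - out[[comparator]][, "retentions"]
  cpi <- (dc + out[[reference]][, "cost_infection"] -
            out[[comparator]][, "cost_infection"]) / inf_prev
  cpr <- (dc + out[[reference]][, "cost_retention"] -
            out[[comparator]][, "cost_retention"]) / ret_prev

  draws <- data.frame(draw = seq_len(n_draws))
  for (k in keys) {
    d <- as.data.frame(out[[k]])
    names(d) <- paste0(k, ".", names(d))
    draws <- cbind(draws, d)
  }
  draws$delta_cost <- dc
  draws$delta_qaly <- dq
  draws$infections_prevented <- inf_prev
  draws$retentions_prevented <- ret_prev

  qs <- function(x) stats::quantile(x[is.finite(x)], c(0.25, 0.5, 0.75),
                                    names = FALSE)
  structure(list(
    draws = draws, ceac = ceac, seed = seed, n_draws = n_draws,
    comparator = comparator, reference = reference,
    summary = list(
      infections_prevented = qs(inf_prev),
      retentions_prevented = qs(ret_prev),
      cost_per_infection_prevented = qs(cpi),
      cost_per_retention_prevented = qs(cpr),
      prob_comparator_ce = ceac[[comparator]]
    )
  ), class = "psa_result")
}

ceac_from_draws <- function(out, wtp_grid, reference) {
  keys <- names(out)
  n <- nrow(out[[1]])
  # tie-break toward the reference: evaluate it first, strict inequality to
  # displace the incumbent
  ordered_keys <- c(reference, setdiff(keys, reference))
  probs <- matrix(0, length(wtp_grid), length(keys),
                  dimnames = list(NULL, keys))
  for (g in seq_along(wtp_grid)) {
    l <- wtp_grid[g]
    best <- rep(reference, n)
    best_nmb <- l * out[[reference]][, "qaly"] - out[[reference]][, "cost"]
    for (k in setdiff(ordered_keys, reference)) {
      nmb <- l * out[[k]][, "qaly"] - out[[k]][, "cost"]
      better <- nmb > best_nmb
      best[better] <- k
      best_nmb[better] <- nmb[better]
    }
    probs[g, ] <- vapply(keys, function(k) mean(best == k), numeric(1))
  }
  data.frame(wtp = wtp_grid, probs, check.names = FALSE)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("One-way threshold for %s over [%g, %g] (%s):\n",
              x$parameter, x$bounds[1], x$bounds[2], x$criterion))
  if (x$criterion_met == "none_in_range") {
    cat("  no verdict flip in range\n")
  } else {
    cat(sprintf("  threshold = %g (%s)\n", x$threshold, x$criterion_met))
  }
  invisible(x)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws%s, %s vs %s (reference)\n", x$n_draws,
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed),
              x$comparator, x$reference))
  s <- x$summary
  lab <- c(infections_prevented = "Infections prevented / 1000",
           retentions_prevented = "Retentions prevented / 1000",
           cost_per_infection_prevented = "Cost per infection prevented",
           cost_per_retention_prevented = "Cost per retention prevented")
  for (nm in names(lab)) {
    cat(sprintf("  %-29s median %7.2f (IQR %7.2f to %7.2f)\n",
                lab[[nm]], s[[nm]][2], s[[nm]][1], s[[nm]][3]))
  }
  cat(sprintf("  P(%s cost-effective): min %.3f over the WTP grid\n",
              x$comparator, min(s$prob_comparator_ce)))
  invisible(x)
}
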