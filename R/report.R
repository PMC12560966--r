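#' Base-case style results table
#'
#' Arranges evaluated strategies into the standard cost-effectiveness
#' report: per-patient cost components and total, total QALYs, incremental
#' cost/QALY/ICER against the reference, and clinical event rates per 1000
#' patients with cost-per-event-prevented.
#'
#' @param results Named list of [evaluate_strategy()] results.
#' @param reference Key of the reference strategy (incremental columns are
#'   blank for it).
#' @param wtp Willingness-to-pay used for the verdict, US$/QALY.
#' @return data.frame, one column per strategy, one row per quantity.
#' @export
ce_table <- function(results, reference = "TR", wtp = 100000) {
  stopifnot(reference %in% names(results))
  cols <- lapply(names(results), function(k) {
    r <- results[[k]]
    cmp <- if (k == reference) NULL else compare(results[[reference]], r, wtp)
    c(`Fixed (MRI, procedure fee)` = r$cost[["fixed"]],
      `Disposables (net of standard kit)` = r$cost[["disposables"]],
      `Antibiotics` = r$cost[["antibiotics"]],
      `Rectal swab` = r$cost[["swab"]],
      `Infection` = r$cost[["infection"]],
      `Retention` = r$cost[["retention"]],
      `Total cost` = r$cost[["total"]],
      `Total QALY` = r$qaly_total,
      `Incremental cost` = if (is.null(cmp)) NA_real_ else cmp$delta_cost,
      `Incremental QALY` = if (is.null(cmp)) NA_real_ else cmp$delta_qaly,
      `ICER` = if (is.null(cmp)) NA_real_ else cmp$icer,
      `Infections per 1000` = r$infections_per_1000,
      `Retentions per 1000` = r$retentions_per_1000,
      `Sepsis per 1000` = r$sepsis_per_1000,
      `Cost per infection prevented` =
        if (is.null(cmp)) NA_real_ else cmp$cost_per_event_prevented[["infections"]],
      `Cost per retention prevented` =
        if (is.null(cmp)) NA_real_ else cmp$cost_per_event_prevented[["retentions"]],
      `Cost per sepsis prevented` =
        if (is.null(cmp)) NA_real_ else cmp$cost_per_event_prevented[["sepsis"]])
  })
  out <- data.frame(quantity = names(cols[[1]]), stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[results[[i]]$strategy]] <- unname(cols[[i]])
  out
}

#' Write analysis outputs to CSV and JSON
#'
#' CSV for tables (full precision; round at presentation, not here) and a
#' JSON sidecar carrying the same content plus reproducibility metadata
#' (package version, seed where applicable, timestamp).
#'
#' @param x data.frame (or coercible) to export.
#' @param path Output path without extension.
#' @param seed Seed to record, if the content is stochastic.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(x, path, seed = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(x, csv, row.names = FALSE)
  meta <- list(
    package = "biopsycea",
    version = as.character(utils::packageVersion("biopsycea")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    data = x
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = json))
}
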