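#' @title Incremental cost-effectiveness outputs
#' @description Incremental comparisons (ICER per QALY and per
#'   life-year, strokes avoided, number needed to monitor), category
#'   cost-breakdown tables, and deterministic result files with a run
#'   manifest.
#' @name outputs
#' @keywords internal
NULL

#' Compare two strategy outcomes
#'
#' Differences are computed on unrounded values; the ICER is
#' `delta cost / delta QALY`. When the ICM strategy saves money and
#' gains QALYs it dominates (no ICER is reported); the reverse is
#' flagged dominated. A zero QALY difference leaves the ICER undefined.
#'
#' @param icm,soc `icm_strategy_outcome` objects from the same
#'   parameter set.
#' @return List of class `icm_ce_comparison`.
#' @export
compare_strategies <- function(icm, soc) {
  dc <- icm$discounted_cost_total - soc$discounted_cost_total
  dq <- icm$qalys - soc$qalys
  dl <- icm$life_years - soc$life_years
  avoided <- soc$is_events_per_1000 - icm$is_events_per_1000
  dominance <- "none"
  icer_q <- icer_l <- NA_real_
  if (dq == 0) {
    dominance <- if (dc < 0) "dominant" else if (dc > 0) "dominated" else "none"
  } else if (dc <= 0 && dq > 0) {
    dominance <- "dominant"
  } else if (dc >= 0 && dq < 0) {
    dominance <- "dominated"
  } else {
    icer_q <- dc / dq
    icer_l <- if (dl != 0) dc / dl else NA_real_
  }
  structure(list(
    delta_cost = dc, delta_qaly = dq, delta_ly = dl,
    icer_per_qaly = icer_q, icer_per_ly = icer_l,
    is_avoided_per_1000 = avoided,
    nnt_per_stroke_avoided = nnt(avoided),
    dominance_flag = dominance
  ), class = "icm_ce_comparison")
}

#' Number needed to monitor per stroke avoided
#'
#' `round(1000 / avoided)` to the nearest integer; undefined (NA) when
#' no strokes are avoided.
#'
#' @param is_avoided_per_1000 Strokes avoided per 1000 patients.
#' @return Integer NNT, or NA.
#' @export
nnt <- function(is_avoided_per_1000) {
  if (!is.finite(is_avoided_per_1000) || is_avoided_per_1000 <= 0) return(NA_integer_)
  as.integer(round(1000 / is_avoided_per_1000))
}

#' Cost breakdown by category
#'
#' @param icm,soc `icm_strategy_outcome` objects.
#' @param discounted Use discounted (default) or undiscounted costs.
#' @return data.frame with per-category ICM, SoC and difference columns;
#'   the final row is the total and categories sum to it.
#' @export
cost_breakdown_table <- function(icm, soc, discounted = TRUE) {
  a <- if (discounted) icm$cost_by_category else icm$undiscounted_cost_by_category
  b <- if (discounted) soc$cost_by_category else soc$undiscounted_cost_by_category
  out <- data.frame(category = c(names(a), "total"),
                    icm = c(a, sum(a)), soc = c(b, sum(b)))
  out$difference <- out$icm - out$soc
  rownames(out) <- NULL
  out
}

#' Write deterministic results with a run manifest
#'
#' Writes `results.json` (incremental outcomes, per-strategy totals,
#' category breakdown), `breakdown.csv`, and `manifest.json` recording
#' the parameter-bundle hash, seed and file list.
#'
#' @param result An `icm_cea_result` from [run_cea()].
#' @param params The parameter set used (for the bundle hash).
#' @param dir Output directory (created if needed).
#' @param seed Optional integer seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(result, params, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- result$comparison
  strat_block <- function(o) list(
    total_cost = o$discounted_cost_total,
    cost_by_category = as.list(o$cost_by_category),
    qalys = o$qalys, life_years = o$life_years,
    undiscounted_life_years = o$undiscounted_life_years,
    is_events_per_1000 = o$is_events_per_1000,
    strokes_by_severity_per_1000 = as.list(o$strokes_by_severity))
  res <- list(
    schema_version = "1.0",
    comparison = list(
      delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
      delta_ly = cmp$delta_ly, icer_per_qaly = cmp$icer_per_qaly,
      icer_per_ly = cmp$icer_per_ly,
      is_avoided_per_1000 = cmp$is_avoided_per_1000,
      nnt_per_stroke_avoided = cmp$nnt_per_stroke_avoided,
      dominance_flag = cmp$dominance_flag),
    icm = strat_block(result$icm), soc = strat_block(result$soc))
  res_path <- file.path(dir, "results.json")
  jsonlite::write_json(res, res_path, auto_unbox = TRUE, digits = NA, na = "null")
  bd_path <- file.path(dir, "breakdown.csv")
  utils::write.csv(cost_breakdown_table(result$icm, result$soc), bd_path,
                   row.names = FALSE)
  manifest <- run_manifest("run", params, seed,
                           outputs = c(res_path, bd_path))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

#' Build a run manifest
#'
#' @param command Short command label.
#' @param params Parameter set (hashed by writing its flattened table).
#' @param seed Optional seed.
#' @param outputs Character vector of produced files (must exist).
#' @return Manifest list.
#' @export
run_manifest <- function(command, params, seed = NULL, outputs = character()) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing)) stop("manifest lists outputs that do not exist: ",
                            paste(missing, collapse = ", "))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(flatten_parameters(params), tmp, row.names = FALSE)
  list(command = command,
       bundle_hash = unname(tools::md5sum(tmp)),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = as.list(basename(outputs)))
}

#' Export a cohort trace as long-format CSV
#' @param trace An `icm_cohort_trace` matrix.
#' @param space The `icm_state_space` that labels its columns.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_trace <- function(trace, space, path) {
  labels <- c(paste(space$states$af, space$states$dx, space$states$tx,
                    space$states$barred, space$states$health, sep = "|"), "dead")
  df <- data.frame(cycle = rep(seq_len(nrow(trace)) - 1L, times = ncol(trace)),
                   state = rep(labels, each = nrow(trace)),
                   occupancy = as.numeric(trace))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
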