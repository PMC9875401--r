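#' @title Sensitivity and scenario analysis
#' @description Probabilistic sensitivity analysis (joint parameter
#'   resampling with beta/gamma/lognormal/normal families), the
#'   cost-effectiveness acceptability curve, one-way deterministic
#'   sensitivity analysis for the tornado diagram, and the named
#'   scenario/subgroup grid.
#' @name uncertainty
#' @keywords internal
NULL

#' Draw one randomised value for a parameter leaf
#'
#' Families: `beta` (moment-matched to mean/SE, for probabilities and
#' utilities), `gamma` (costs; mean/SE), `lognormal` (ratios; either a
#' stored `sdlog` with median-preserving location, or moment-matched
#' from mean/SE), `normal`, `fixed`.
#' @noRd
draw_leaf <- function(leaf, path) {
  v <- leaf$value
  if (identical(leaf$dist, "fixed") || length(v) > 1L) return(v)
  se <- leaf$se
  switch(leaf$dist,
    beta = {
      if (is.null(se)) stop("beta parameter without se: ", path)
      if (se^2 >= v * (1 - v)) stop("se too large for beta moment match: ", path)
      k <- v * (1 - v) / se^2 - 1
      stats::rbeta(1, v * k, (1 - v) * k)
    },
    gamma = {
      if (is.null(se)) stop("gamma parameter without se: ", path)
      if (v == 0) return(0)
      stats::rgamma(1, shape = (v / se)^2, rate = v / se^2)
    },
    lognormal = {
      if (!is.null(leaf$sdlog)) {
        stats::rlnorm(1, meanlog = log(v), sdlog = leaf$sdlog)
      } else if (!is.null(se)) {
        s2 <- log(1 + (se / v)^2)
        stats::rlnorm(1, meanlog = log(v) - s2 / 2, sdlog = sqrt(s2))
      } else stop("lognormal parameter without sdlog or se: ", path)
    },
    normal = {
      if (is.null(se)) stop("normal parameter without se: ", path)
      stats::rnorm(1, v, se)
    },
    stop("unknown distribution family '", leaf$dist, "' for ", path))
}

#' Draw perturbed parameter sets for PSA
#'
#' Walks every parameter leaf and samples from its declared
#' distribution family; fixed-family parameters stay constant. The
#' stroke-risk grid is rescaled consistently with the drawn relative
#' risks (subclinical-AF columns by the subclinical-AF relative risk;
#' the NOAC and warfarin columns additionally by their
#' efficacy-vs-aspirin ratios). Reproducible given the seed.
#'
#' @param params Base `icm_params`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List of `n` perturbed `icm_params` objects.
#' @export
draw_psa <- function(params, n, seed) {
  set.seed(seed)
  base_rr <- c(sub = param_value(params, "clinical.rr_subclinical_af"),
               noac = param_value(params, "clinical.rr_noac_vs_aspirin"),
               warf = param_value(params, "clinical.rr_warfarin_vs_aspirin"))
  draw_node <- function(node, prefix) {
    for (nm in names(node)) {
      x <- node[[nm]]
      if (is_param_leaf(x)) {
        x$value <- draw_leaf(x, paste(c(prefix, nm), collapse = "."))
        node[[nm]] <- x
      } else if (is.list(x)) {
        node[[nm]] <- draw_node(x, c(prefix, nm))
      }
    }
    node
  }
  lapply(seq_len(n), function(i) {
    ps <- params
    for (g in PARAM_GROUPS) ps[[g]] <- draw_node(ps[[g]], g)
    ps <- scale_risk_grid(
      ps,
      sub = param_value(ps, "clinical.rr_subclinical_af") / base_rr["sub"],
      noac = param_value(ps, "clinical.rr_noac_vs_aspirin") / base_rr["noac"],
      warf = param_value(ps, "clinical.rr_warfarin_vs_aspirin") / base_rr["warf"])
    ps
  })
}

#' Rescale the subclinical-AF columns of the stroke-risk grid
#'
#' Multiplies the subclinical-AF columns by `sub` (relative-risk ratio
#' against the bundled grid) and the NOAC/warfarin columns additionally
#' by `noac`/`warf`; all cells capped at 1. Used by the PSA and by the
#' clinical-AF (RR 4.8) and NOAC-efficacy (RR 0.28) scenarios.
#'
#' @param params An `icm_params`.
#' @param sub,noac,warf Multiplicative ratios (1 = unchanged).
#' @return A new `icm_params` with the rescaled grid.
#' @export
scale_risk_grid <- function(params, sub = 1, noac = 1, warf = 1) {
  g <- params$tables$risk_grid
  g$subaf_none <- pmin(1, g$subaf_none * sub)
  g$subaf_aspirin <- pmin(1, g$subaf_aspirin * sub)
  g$subaf_noac <- pmin(1, g$subaf_noac * sub * noac)
  g$subaf_warfarin <- pmin(1, g$subaf_warfarin * sub * warf)
  params$tables$risk_grid <- g
  params
}

#' Run the probabilistic sensitivity analysis
#'
#' Evaluates the full ICM-vs-SoC model on `n` joint parameter draws.
#' The mean ICER is the ratio of mean increments (not the mean of
#' per-draw ratios, which is unstable); 95% credible intervals are the
#' 2.5/97.5 percentiles of each stored output. Draws failing
#' validation are skipped and counted.
#'
#' @param params Base `icm_params`.
#' @param n Number of draws (the analysis default is 1000).
#' @param seed Integer seed.
#' @return Object of class `icm_psa_result`: `samples` data.frame (one
#'   row per successful draw), `mean_icer`, `cri_95`, `seed`, `n`,
#'   `n_failed`.
#' @export
run_psa <- function(params, n, seed) {
  draws <- draw_psa(params, n, seed)
  rows <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      ps <- draws[[i]]
      v <- validate(ps)
      if (nrow(v)) stop("draw failed validation: ", v$parameter[1])
      res <- run_cea(ps)
      data.frame(
        draw = i,
        cost_icm = res$icm$discounted_cost_total,
        cost_soc = res$soc$discounted_cost_total,
        qaly_icm = res$icm$qalys, qaly_soc = res$soc$qalys,
        ly_icm = res$icm$life_years, ly_soc = res$soc$life_years,
        is_icm = res$icm$is_events_per_1000, is_soc = res$soc$is_events_per_1000,
        delta_cost = res$comparison$delta_cost,
        delta_qaly = res$comparison$delta_qaly,
        delta_ly = res$comparison$delta_ly)
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      NULL
    })
  }
  samples <- do.call(rbind, rows)
  if (is.null(samples) || !nrow(samples)) stop("every PSA draw failed")
  cri <- lapply(samples[, -1], function(x)
    stats::quantile(x, c(0.025, 0.975), names = FALSE))
  structure(list(
    samples = samples,
    mean_icer = mean(samples$delta_cost) / mean(samples$delta_qaly),
    means = colMeans(samples[, -1]),
    cri_95 = cri, seed = seed, n = nrow(samples), n_failed = n_failed
  ), class = "icm_psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA samples
#' with positive net monetary benefit
#' (`threshold * delta QALY - delta cost > 0`).
#'
#' @param result An `icm_psa_result`.
#' @param thresholds Thresholds in USD per QALY.
#' @return data.frame with `threshold` and `prob_cost_effective`.
#' @export
ceac <- function(result, thresholds) {
  s <- result$samples
  if (!nrow(s)) stop("PSA result holds no samples")
  data.frame(
    threshold = thresholds,
    prob_cost_effective = vapply(thresholds, function(l)
      mean(l * s$delta_qaly - s$delta_cost > 0), numeric(1)))
}

#' @noRd
RR_GRID_PATHS <- c("clinical.rr_subclinical_af", "clinical.rr_noac_vs_aspirin",
                   "clinical.rr_warfarin_vs_aspirin")

#' Set one parameter, propagating relative risks into the risk grid
#' @noRd
apply_parameter_value <- function(params, parameter, value) {
  base <- param_value(params, parameter)
  ps <- apply_overrides(params, stats::setNames(list(value), parameter))
  if (parameter %in% RR_GRID_PATHS) {
    r <- value / base
    ps <- switch(parameter,
      "clinical.rr_subclinical_af" = scale_risk_grid(ps, sub = r),
      "clinical.rr_noac_vs_aspirin" = scale_risk_grid(ps, noac = r),
      "clinical.rr_warfarin_vs_aspirin" = scale_risk_grid(ps, warf = r))
  }
  ps
}

#' One-way deterministic sensitivity analysis for one parameter
#'
#' Two deterministic model runs with the parameter set to each bound
#' (everything else at base values). Relative-risk parameters propagate
#' into the stroke-risk grid.
#'
#' @param params Base `icm_params`.
#' @param parameter Dotted parameter path.
#' @param low,high Bounds to test.
#' @return One-row data.frame: parameter, bounds, ICER at each bound.
#' @export
one_way_dsa <- function(params, parameter, low, high) {
  base <- param_value(params, parameter)  # errors on unknown paths
  stopifnot(is.numeric(base))
  icer_at <- function(v) {
    run_cea(apply_parameter_value(params, parameter, v))$comparison$icer_per_qaly
  }
  data.frame(parameter = parameter, low_value = low, high_value = high,
             icer_low = icer_at(low), icer_high = icer_at(high),
             stringsAsFactors = FALSE)
}

#' Default tornado-diagram parameter ranges
#'
#' Bounds follow the published intervals where stated (detection hazard
#' ratio lower confidence limit 13.2, with a log-symmetric upper bound;
#' the 0.8-2.16 interval on the per-decade stroke-risk age factor;
#' uptake 66.35%-100%; non-bleed discontinuation 0-26%) and a +/-30%
#' band on costs otherwise.
#'
#' @param params Base `icm_params` (for base values).
#' @return data.frame with `parameter`, `low`, `high`.
#' @export
tornado_parameters <- function(params) {
  pv <- function(p) param_value(params, p)
  hr <- pv("detection.hr_icm_vs_soc")
  rbind(
    data.frame(parameter = "detection.hr_icm_vs_soc",
               low = 13.2, high = hr^2 / 13.2),
    data.frame(parameter = "economics.cost_icm_insertion",
               low = 0.7 * pv("economics.cost_icm_insertion"),
               high = 1.3 * pv("economics.cost_icm_insertion")),
    data.frame(parameter = "economics.cost_noac_cycle",
               low = 0.7 * pv("economics.cost_noac_cycle"),
               high = 1.3 * pv("economics.cost_noac_cycle")),
    data.frame(parameter = "economics.cost_icm_monitoring_cycle",
               low = 0.7 * pv("economics.cost_icm_monitoring_cycle"),
               high = 1.3 * pv("economics.cost_icm_monitoring_cycle")),
    data.frame(parameter = "treatment.noac_uptake", low = 0.6635, high = 1),
    data.frame(parameter = "treatment.background_discontinuation_annual",
               low = 0, high = 0.26),
    data.frame(parameter = "clinical.age_adjust_per_decade", low = 0.8, high = 2.16),
    data.frame(parameter = "clinical.rr_noac_vs_aspirin", low = 0.28, high = 0.52),
    data.frame(parameter = "clinical.rr_subclinical_af", low = 1.8, high = 3.2),
    data.frame(parameter = "economics.u_baseline",
               low = pv("economics.u_baseline") - 1.96 * 0.008,
               high = pv("economics.u_baseline") + 1.96 * 0.008))
}

#' Run the tornado analysis
#' @param params Base `icm_params`.
#' @param entries data.frame as from [tornado_parameters()].
#' @return data.frame of [one_way_dsa()] rows plus the base ICER.
#' @export
run_tornado <- function(params, entries = tornado_parameters(params)) {
  base_icer <- run_cea(params)$comparison$icer_per_qaly
  out <- do.call(rbind, lapply(seq_len(nrow(entries)), function(i)
    one_way_dsa(params, entries$parameter[i], entries$low[i], entries$high[i])))
  out$icer_base <- base_icer
  out$spread <- abs(out$icer_high - out$icer_low)
  out[order(-out$spread), ]
}

#' The named scenario and subgroup grid
#'
#' Scenario specifications for the published grid: CHADS2 subgroups,
#' warfarin substitution, zero aspirin cost, bleed-only
#' discontinuation, 4.5-year battery life under three extrapolation
#' variants, SoC monitoring variants (zero-cost pulse check at 1/24th
#' SoC yield; a single 24-h Holter), the 5.5-hour AF-episode
#' definition, 66.35% NOAC uptake, truncated horizons, the private
#' payer uplift, the lower ICM-vs-SoC detection ratio (3.17), the
#' clinical-AF relative risk (4.8) and the stronger NOAC efficacy
#' (0.28), plus the heart-failure subgroup bundle and its scenarios.
#'
#' @return Named list of `icm_scenario` objects; entries may carry a
#'   `grid_ratios` attribute consumed by [run_scenario_grid()].
#' @export
scenario_table <- function() {
  sc <- function(name, overrides = list(), grid_ratios = NULL, description = NULL) {
    s <- scenario_spec(name, overrides, description)
    s$grid_ratios <- grid_ratios
    s
  }
  hf <- hf_subgroup_overrides()
  specs <- list(
    sc("base_case"),
    sc("chads2_2", list("structural.chads2_distribution" = c("2" = 1))),
    sc("chads2_3", list("structural.chads2_distribution" = c("3" = 1))),
    sc("chads2_4_6", list("structural.chads2_distribution" =
                            c("4" = 0.16, "5" = 0.05, "6" = 0.02) / 0.23)),
    sc("warfarin", list("treatment.oac_drug" = "warfarin")),
    sc("aspirin_cost_zero", list("economics.cost_aspirin_cycle" = 0)),
    sc("no_nonbleed_discontinuation",
       list("treatment.background_discontinuation_annual" = 0)),
    sc("battery_4.5y", list("detection.battery_years" = 4.5)),
    sc("battery_4.5y_linear", list("detection.battery_years" = 4.5,
                                   "detection.extrapolation" = "linear")),
    sc("battery_4.5y_no_extrapolation",
       list("detection.battery_years" = 4.5, "detection.extrapolation" = "none")),
    sc("soc_pulse_check", list("detection.soc_detection_scale" = 1 / 24,
                               "economics.cost_soc_monitoring_cycle" = 0),
       description = "zero-cost pulse check identifying 1/24th of SoC detection"),
    sc("soc_one_holter", list("economics.soc_monitoring_mode" = "one_holter")),
    sc("af_episode_5.5h",
       list("files.detection_curve" = "detection_curve_55h_synthetic.csv")),
    sc("noac_uptake_66.35", list("treatment.noac_uptake" = 0.6635)),
    sc("horizon_5y", list("structural.horizon_years" = 5)),
    sc("horizon_10y", list("structural.horizon_years" = 10)),
    sc("horizon_25y", list("structural.horizon_years" = 25)),
    sc("private_payer", list("economics.payer_uplift" = 0.25)),
    sc("loop_hr_3.17", list("detection.hr_icm_vs_soc" = 3.17)),
    sc("clinical_af_rr_4.8", grid_ratios = c(sub = 2)),
    sc("noac_rr_0.28", grid_ratios = c(noac = 0.28 / 0.39)),
    sc("hf_base", hf),
    sc("hf_warfarin", c(hf, list("treatment.oac_drug" = "warfarin"))),
    sc("hf_battery_4.5y", c(hf, list("detection.battery_years" = 4.5))),
    sc("hf_battery_4.5y_linear",
       c(hf, list("detection.battery_years" = 4.5,
                  "detection.extrapolation" = "linear"))),
    sc("hf_battery_4.5y_no_extrapolation",
       c(hf, list("detection.battery_years" = 4.5,
                  "detection.extrapolation" = "none"))))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Heart-failure subgroup overrides
#'
#' A synthetic subgroup bundle: its own (higher) detection curve, a
#' CHADS2 mix shifted upward, and modestly elevated NOAC bleeding
#' risks, standing in for the unpublished subgroup inputs.
#'
#' @return Named override list.
#' @export
hf_subgroup_overrides <- function() {
  list(
    "files.detection_curve" = "detection_curve_hf_synthetic.csv",
    "structural.chads2_distribution" =
      c("2" = 0.10, "3" = 0.38, "4" = 0.32, "5" = 0.14, "6" = 0.06),
    "clinical.bleed_risks.noac.ech" = 0.037,
    "clinical.bleed_risks.noac.crnm" = 0.16,
    "clinical.bleed_risks.noac.hs" = 0.0033,
    "clinical.bleed_risks.noac.other_ich" = 0.0046)
}

#' Run the scenario/subgroup grid
#'
#' One deterministic comparison per scenario; scenarios whose inputs
#' are unavailable are reported with a skipped status instead of
#' aborting the grid.
#'
#' @param base Base `icm_params`.
#' @param specs List of `icm_scenario` objects (default: the full grid).
#' @return data.frame mirroring the published layout: scenario,
#'   incremental cost, incremental QALYs, ICER, status.
#' @export
run_scenario_grid <- function(base, specs = scenario_table()) {
  rows <- lapply(specs, function(spec) {
    tryCatch({
      ps <- apply_overrides(base, spec)
      gr <- spec$grid_ratios
      if (!is.null(gr)) {
        gr <- c(gr, c(sub = 1, noac = 1, warf = 1)[setdiff(c("sub", "noac", "warf"), names(gr))])
        ps <- scale_risk_grid(ps, sub = gr[["sub"]], noac = gr[["noac"]], warf = gr[["warf"]])
      }
      res <- run_cea(ps)
      data.frame(scenario = spec$name,
                 delta_cost = res$comparison$delta_cost,
                 delta_qaly = res$comparison$delta_qaly,
                 icer_per_qaly = res$comparison$icer_per_qaly,
                 is_avoided_per_1000 = res$comparison$is_avoided_per_1000,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(scenario = spec$name, delta_cost = NA_real_,
                 delta_qaly = NA_real_, icer_per_qaly = NA_real_,
                 is_avoided_per_1000 = NA_real_,
                 status = paste("skipped:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
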