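#' @title Synthetic inputs and the microsimulation oracle
#' @description Generates every input needed to exercise the pipeline
#'   without downloads: Gompertz-Makeham life tables standing in for
#'   the cerebrovascular-deleted US table, trial-like AF
#'   first-detection times drawn from a target cumulative curve,
#'   randomized-but-valid parameter bundles for property testing, and
#'   a patient-level microsimulation that replays the cohort engine's
#'   per-cycle probabilities to validate its algebra.
#' @name synthdata
#' @keywords internal
NULL

#' Synthetic life table (Gompertz-Makeham)
#'
#' Annual death probability `q(x) = min(1, c + a * exp(b * x))`, forced
#' to 1 at the terminal age. The defaults give a residual life
#' expectancy at age 71.3 plausible for a US cohort after removing
#' cerebrovascular deaths; the real adjusted table can be dropped in
#' through the same CSV interface.
#'
#' @param a,b Gompertz level and slope (positive).
#' @param c Makeham age-independent hazard component.
#' @param min_age,max_age Table range; `q(max_age) = 1`.
#' @return data.frame with `age`, `qx`.
#' @export
synth_life_table <- function(a = 2e-5, b = 0.1, c = 0.002,
                             min_age = 50, max_age = 100) {
  stopifnot(a > 0, b > 0, c >= 0)
  age <- seq(min_age, max_age)
  qx <- pmin(1, c + a * exp(b * age))
  qx[age >= max_age] <- 1
  qx <- cummax(qx)  # monotone by construction; guard numeric edge
  data.frame(age = age, qx = qx)
}

#' Residual life expectancy from a life table
#'
#' Continuous-time expectation under a piecewise-constant hazard per
#' year of age: each year contributes `S * (1 - exp(-h)) / h`.
#'
#' @param lt Life table data.frame (`age`, `qx`).
#' @param age Starting age (must be at or above the table minimum).
#' @return Expected residual years.
#' @export
life_expectancy <- function(lt, age) {
  keep <- lt$age >= floor(age)
  q <- pmin(lt$qx[keep], 1 - 1e-12)
  h <- -log(1 - q)
  S <- c(1, cumprod(exp(-h)))[seq_along(h)]
  sum(S * (1 - exp(-h)) / h)
}

#' Synthetic AF first-detection trial
#'
#' Samples per-patient first-detection times by inverse transform from
#' a target cumulative detection curve (linear interpolation between
#' curve points); patients whose uniform draw exceeds the curve's final
#' value are censored at the final month.
#'
#' @param target_curve A `detection_curve`.
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return List of class `icm_synth_trial`: `detection_months` (NA when
#'   censored), `censored`, `censor_month`, `n`, `seed`.
#' @export
synth_detection_trial <- function(target_curve, n, seed) {
  set.seed(seed)
  m <- target_curve$month; C <- target_curve$cumulative
  u <- stats::runif(n)
  cmax <- C[length(C)]
  censored <- u > cmax
  times <- rep(NA_real_, n)
  if (any(!censored)) {
    uu <- u[!censored]
    i <- findInterval(uu, C, left.open = TRUE)  # segment [i, i+1] holds uu
    i <- pmax(pmin(i, length(C) - 1L), 1L)
    denom <- C[i + 1L] - C[i]
    frac <- ifelse(denom > 0, (uu - C[i]) / denom, 1)
    times[!censored] <- m[i] + frac * (m[i + 1L] - m[i])
  }
  structure(list(detection_months = times, censored = censored,
                 censor_month = m[length(m)], n = n, seed = seed),
            class = "icm_synth_trial")
}

#' Empirical cumulative detection curve of a synthetic trial
#' @param trial An `icm_synth_trial`.
#' @param months Evaluation months (default: 3-month grid to censoring).
#' @return A `detection_curve`.
#' @export
empirical_detection_curve <- function(trial,
                                      months = seq(0, trial$censor_month, by = 3)) {
  cum <- vapply(months, function(mm)
    mean(!trial$censored & trial$detection_months <= mm), numeric(1))
  detection_curve(months, cummax(cum))
}

#' Randomized valid parameter bundle
#'
#' Perturbs the packaged base-case bundle multiplicatively (clinical,
#' treatment and economics groups; structure and detection settings
#' untouched), respecting every type bound and renormalising
#' simplexes, so that the result always validates. Used for
#' property-based testing of the full pipeline.
#'
#' @param seed Integer seed.
#' @param spread Half-width of the multiplicative perturbation.
#' @return A valid `icm_params`.
#' @export
synth_parameter_bundle <- function(seed, spread = 0.15) {
  set.seed(seed)
  ps <- load_parameters(base_case_bundle())
  jitter_node <- function(node) {
    for (nm in names(node)) {
      x <- node[[nm]]
      if (is_param_leaf(x)) {
        f <- stats::runif(length(x$value), 1 - spread, 1 + spread)
        v <- x$value * f
        type <- if (is.null(x$type)) "" else x$type
        if (type == "probability") v <- pmin(pmax(v, 0), 1)
        if (type == "utility") v <- pmin(pmax(v, -1), 1)
        if (type == "simplex") v <- v / sum(v)
        x$value <- v
        node[[nm]] <- x
      } else if (is.list(x)) {
        node[[nm]] <- jitter_node(x)
      }
    }
    node
  }
  for (g in c("clinical", "treatment", "economics")) ps[[g]] <- jitter_node(ps[[g]])
  v <- validate(ps)
  if (nrow(v)) stop("internal error: synthetic bundle failed validation")
  ps
}

#' Patient-level microsimulation oracle
#'
#' Simulates individual trajectories by sampling from exactly the
#' per-cycle stage probabilities and flow payoffs of the cohort engine
#' (shared through the model context), so that, up to Monte-Carlo
#' error, its averaged outcomes must equal the cohort engine's. Tests
#' the cohort propagation/accumulation algebra, not the rates.
#'
#' @param params An `icm_params`.
#' @param strategy `"ICM"` or `"SoC"`.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed.
#' @param mc Optional prebuilt `icm_model_context`.
#' @param chads2 Single stratum to simulate; when `NULL`, strata are
#'   sampled from the bundle's CHADS2 distribution.
#' @return List of class `icm_microsim_outcome` with means and
#'   Monte-Carlo standard errors of discounted cost, QALYs, life-years
#'   and ischemic strokes per 1000.
#' @export
microsim_oracle <- function(params, strategy, n_patients, seed,
                            mc = NULL, chads2 = NULL) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  if (is.null(mc)) mc <- build_model_context(params)
  sp <- mc$space; S <- sp$n; dead <- sp$dead; ns <- S - 1L
  tr <- mc$trip
  sch <- mc$schedule
  icm_arm <- strategy == "ICM"
  p_bg <- annual_to_cycle(
    param_value(params, "treatment.background_discontinuation_annual"),
    mc$cycles_per_year)

  # per-state triplet ranges (trip is sorted by source state)
  g0 <- match(seq_len(ns), mc$ev_groups)
  g1 <- c(g0[-1L] - 1L, nrow(tr))

  # stage maps as full-length lookup vectors
  inc_map <- rep(NA_integer_, S); inc_map[mc$inc_src] <- mc$inc_dst
  det_states <- unique(mc$det_i)
  det_d1 <- rep(NA_integer_, S); det_f1 <- rep(0, S)
  det_d2 <- rep(NA_integer_, S)
  for (z in seq_along(mc$det_i)) {
    i <- mc$det_i[z]
    if (is.na(det_d1[i])) { det_d1[i] <- mc$det_j[z]; det_f1[i] <- mc$det_frac[z] }
    else det_d2[i] <- mc$det_j[z]
  }
  disc_map <- rep(NA_integer_, S); disc_map[mc$disc_src] <- mc$disc_dst

  if (is.null(chads2)) {
    dist <- param_value(params, "structural.chads2_distribution")
    stratum <- sample(as.integer(names(dist)), n_patients, TRUE, as.numeric(dist))
  } else {
    stratum <- rep(as.integer(chads2), n_patients)
  }
  state <- sample.int(S, n_patients, TRUE, prob = sp$init)

  cost_p <- numeric(n_patients)
  qaly_p <- numeric(n_patients)
  ly_p <- numeric(n_patients)
  is_p <- numeric(n_patients)
  if (icm_arm) cost_p[] <- mc$costs$insertion

  for (t in seq_len(mc$horizon_cycles)) {
    alive_any <- state != dead
    if (!any(alive_any)) break
    d <- mc$disc[t]
    s0 <- sch$device_surviving_start[t]; s1 <- sch$device_surviving_end[t]
    removal_t <- if (icm_arm) {
      (s0 - s1) * mc$costs$removal +
        if (t == sch$battery_cycles) s1 * mc$costs$removal else 0
    } else 0

    for (k2 in unique(stratum)) {
      sel <- which(stratum == k2 & state != dead)
      if (!length(sel)) next
      k <- cycle_stage_probs(mc, k2, strategy, t)
      ev <- event_probs(mc, k$P)
      st <- state[sel]
      # AF incidence
      can <- !is.na(inc_map[st])
      hit <- can & stats::runif(length(st)) < k$p_inc
      st[hit] <- inc_map[st[hit]]
      # detection
      can <- st %in% det_states
      u <- stats::runif(length(st))
      got <- can & u < k$q_det
      if (any(got)) {
        frac_draw <- stats::runif(sum(got))
        first <- frac_draw < det_f1[st[got]] | is.na(det_d2[st[got]])
        st[got][first] <- det_d1[st[got][first]]
        st[got][!first] <- det_d2[st[got][!first]]
      }
      # background death
      dies <- stats::runif(length(st)) < k$pd[st]
      st[dies] <- dead
      # competing events
      alive_idx <- which(st != dead)
      for (s in unique(st[alive_idx])) {
        who <- alive_idx[st[alive_idx] == s]
        rng <- g0[s]:g1[s]
        probs <- c(ev$p_trip[rng], ev$p_noev[s])
        pick <- sample.int(length(probs), length(who), TRUE, prob = probs)
        is_event <- pick <= length(rng)
        rows <- rng[pick[is_event]]
        st[who[is_event]] <- tr[rows, "j"]
        st[who[!is_event]] <- mc$noev_dst[s]
        gsel <- sel[who[is_event]]
        cost_p[gsel] <- cost_p[gsel] + tr[rows, "cost"] * d
        qaly_p[gsel] <- qaly_p[gsel] + tr[rows, "du"] * d
        is_p[gsel] <- is_p[gsel] + (tr[rows, "sel"] == 1)
      }
      # background OAC discontinuation
      can <- !is.na(disc_map[st])
      hit <- can & stats::runif(length(st)) < p_bg
      st[hit] <- disc_map[st[hit]]
      state[sel] <- st
    }

    # end-of-cycle payoffs
    alive <- state != dead
    if (any(alive)) {
      sa <- state[alive]
      mon <- if (icm_arm) {
        s1 * mc$costs$icm_cycle +
          ifelse(mc$undx[sa], (1 - s1) * soc_monitoring_cost(mc, t), 0)
      } else {
        ifelse(mc$undx[sa], soc_monitoring_cost(mc, t), 0)
      }
      cyc_cost <- mc$drug_cost[sa] + mc$post_cost[sa] + mon + removal_t
      cost_p[alive] <- cost_p[alive] + cyc_cost * d
      qaly_p[alive] <- qaly_p[alive] + mc$u_state[sa] * mc$cy * d
      ly_p[alive] <- ly_p[alive] + mc$cy * d
    }
  }

  mse <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    strategy = strategy, n = n_patients, seed = seed,
    cost = mean(cost_p), cost_se = mse(cost_p),
    qalys = mean(qaly_p), qalys_se = mse(qaly_p),
    life_years = mean(ly_p), life_years_se = mse(ly_p),
    is_events_per_1000 = mean(is_p) * 1000, is_events_se = mse(is_p) * 1000
  ), class = "icm_microsim_outcome")
}
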