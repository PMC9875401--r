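#' @title Markov cohort engine
#' @description Assembles the factored state space (AF status x
#'   diagnosis x treatment x barred-from-OAC flag x post-stroke health
#'   state x absorbing death), builds per-cycle transition dynamics, and
#'   propagates the cohort over a lifetime horizon while accumulating
#'   discounted costs (by category), QALYs, life-years and event counts.
#' @name engine
#' @keywords internal
NULL

HEALTH_LEVELS <- c("event_free", "post_mild", "post_moderate", "post_severe")
TX_LEVELS <- c("none", "aspirin", "noac", "paused", "warfarin")

#' Enumerate the factored state space
#'
#' States are tuples (af, diagnosed, treatment, barred, health) plus an
#' absorbing Dead state. Invalid tuples are excluded: diagnosis implies
#' AF; OAC (NOAC, paused course, warfarin) implies diagnosis and an
#' unbarred patient; undiagnosed patients are untreated or on aspirin.
#'
#' @param params An `icm_params` object.
#' @return List of class `icm_state_space` with the state table, the
#'   Dead index, and the initial occupancy vector (73% aspirin / 27%
#'   untreated; everyone event-free with no AF detected — prior strokes
#'   enter through the CHADS2 score distribution, not through initial
#'   post-stroke occupancy, which keeps the post-stroke health-state
#'   cost stream attributable to modelled events).
#' @export
enumerate_states <- function(params) {
  rows <- list()
  add <- function(af, dx, tx, barred, health) {
    rows[[length(rows) + 1L]] <<- data.frame(
      af = af, dx = dx, tx = tx, barred = barred, health = health,
      stringsAsFactors = FALSE)
  }
  for (h in HEALTH_LEVELS) {
    for (b in 0:1) {
      for (af in 0:1) for (tx in c("none", "aspirin")) add(af, 0L, tx, b, h)
      for (tx in c("aspirin", "none")) add(1L, 1L, tx, b, h)
      if (b == 0L) for (tx in c("noac", "paused", "warfarin")) add(1L, 1L, tx, b, h)
    }
  }
  st <- do.call(rbind, rows)
  st <- st[order(st$health, st$barred, st$dx, st$tx, st$af), ]
  rownames(st) <- NULL
  S <- nrow(st) + 1L
  key <- function(af, dx, tx, barred, health) {
    paste(af, dx, tx, barred, health, sep = "|")
  }
  lut <- stats::setNames(seq_len(nrow(st)),
                         key(st$af, st$dx, st$tx, st$barred, st$health))
  idx <- function(af, dx, tx, barred, health) {
    i <- lut[key(af, dx, tx, barred, health)]
    if (any(is.na(i))) stop("invalid state tuple requested")
    unname(i)
  }

  asp <- param_value(params, "treatment.pre_detection_aspirin_share")
  init <- numeric(S)
  init[idx(0, 0, "aspirin", 0, "event_free")] <- asp
  init[idx(0, 0, "none", 0, "event_free")] <- 1 - asp
  structure(list(states = st, n = S, dead = S, idx = idx, init = init),
            class = "icm_state_space")
}

#' @noRd
worse_health <- function(current, severity) {
  HEALTH_LEVELS[pmax(match(current, HEALTH_LEVELS), severity + 1L)]
}

#' Build the model context
#'
#' Precomputes everything a cohort evaluation needs: the state space,
#' per-state payoff and risk-lookup vectors, the event-transition
#' triplet table with flow payoffs, the detection schedule, and
#' per-cycle age/discount factors. Both the cohort engine and the
#' microsimulation oracle consume this context, so they share per-cycle
#' probabilities and payoffs exactly.
#'
#' @param params An `icm_params` object.
#' @param n_cycles Optional cycle-count override (defaults to lifetime).
#' @param schedule Optional prebuilt `detection_schedule`.
#' @return List of class `icm_model_context`.
#' @export
build_model_context <- function(params, n_cycles = NULL, schedule = NULL) {
  cm <- param_value(params, "structural.cycle_months")
  cy <- cm / 12
  a0 <- param_value(params, "structural.baseline_age")
  if (is.null(n_cycles)) {
    n_cycles <- as.integer(ceiling((param_value(params, "structural.terminal_age") - a0) / cy)) + 1L
  }
  horizon <- param_value(params, "structural.horizon_years")
  horizon_cycles <- if (is.null(horizon) || !length(horizon) ||
                        is.na(horizon[1]) || horizon[1] <= 0) {
    n_cycles
  } else {
    min(n_cycles, as.integer(round(horizon[1] / cy)))
  }
  if (is.null(schedule)) schedule <- build_schedule(params, n_cycles = n_cycles)

  sp <- enumerate_states(params)
  st <- sp$states
  ns <- nrow(st)
  pv <- function(p) param_value(params, p)

  oac_drug <- params$treatment$oac_drug
  if (is.null(oac_drug)) oac_drug <- "noac"
  on_oac <- st$tx %in% c("noac", "paused", "warfarin")

  # risk-grid column per state (1..6 in grid column order)
  grid_cols <- c("noaf_none", "noaf_aspirin", "subaf_none", "subaf_aspirin",
                 "subaf_noac", "subaf_warfarin")
  col_ix <- integer(ns)
  for (i in seq_len(ns)) {
    col_ix[i] <- if (st$af[i] == 0L) {
      if (st$tx[i] == "aspirin") 2L else 1L
    } else {
      switch(st$tx[i], none = 3L, aspirin = 4L, paused = 4L, noac = 5L, warfarin = 6L)
    }
  }

  bleed_classes <- c("none", "aspirin", "noac", "warfarin")
  bc_ix <- match(ifelse(st$tx == "paused", "none", st$tx), bleed_classes)
  bleed_annual <- t(vapply(bleed_classes, function(cl) {
    br <- params$clinical$bleed_risks[[cl]]
    c(hs = br$hs$value, other_ich = br$other_ich$value,
      ech = br$ech$value, crnm = br$crnm$value)
  }, numeric(4)))

  mort_mult <- numeric(ns)
  for (i in seq_len(ns)) {
    mort_mult[i] <- if (st$health[i] == "event_free") 1 else {
      pv(paste0("clinical.post_stroke_mortality_multiplier.",
                sub("^post_", "", st$health[i]))) *
        pv(paste0("clinical.post_stroke_mortality_treatment_factor.", st$tx[i]))
    }
  }

  u_health_by <- c(event_free = pv("economics.u_baseline"),
                   post_mild = pv("economics.u_post_mild"),
                   post_moderate = pv("economics.u_post_moderate"),
                   post_severe = pv("economics.u_post_severe"))
  u_state <- u_health_by[st$health] + st$af * pv("economics.u_af_decrement")
  drug_cost <- c(none = 0, aspirin = pv("economics.cost_aspirin_cycle"),
                 noac = pv("economics.cost_noac_cycle"), paused = 0,
                 warfarin = pv("economics.cost_warfarin_cycle") +
                   pv("economics.cost_inr_monitoring_cycle"))[st$tx]
  post_cost <- c(event_free = 0, post_mild = pv("economics.cost_post_mild_cycle"),
                 post_moderate = pv("economics.cost_post_moderate_cycle"),
                 post_severe = pv("economics.cost_post_severe_cycle"))[st$health]

  # --- stage maps -----------------------------------------------------
  sidx <- sp$idx
  inc_src <- which(st$af == 0L)
  inc_dst <- sidx(1L, 0L, st$tx[inc_src], st$barred[inc_src], st$health[inc_src])

  det_src <- which(st$af == 1L & st$dx == 0L)
  det_i <- integer(0); det_j <- integer(0); det_frac <- numeric(0)
  uptake <- pv("treatment.noac_uptake")
  for (i in det_src) {
    if (st$barred[i] == 1L) {
      det_i <- c(det_i, i)
      det_j <- c(det_j, sidx(1L, 1L, "aspirin", 1L, st$health[i]))
      det_frac <- c(det_frac, 1)
    } else {
      det_i <- c(det_i, i, i)
      det_j <- c(det_j, sidx(1L, 1L, oac_drug, 0L, st$health[i]),
                 sidx(1L, 1L, st$tx[i], 0L, st$health[i]))
      det_frac <- c(det_frac, uptake, 1 - uptake)
    }
  }

  disc_src <- which(st$dx == 1L & st$tx == oac_drug)
  disc_dst <- sidx(1L, 1L, "aspirin", 0L, st$health[disc_src])

  # resume target for a completed pause
  resume_tx <- ifelse(st$tx == "paused", oac_drug, st$tx)
  noev_dst <- vapply(seq_len(ns), function(i) {
    sidx(st$af[i], st$dx[i], resume_tx[i], st$barred[i], st$health[i])
  }, integer(1))

  # --- event triplets -------------------------------------------------
  split_is <- pv("clinical.severity_split_is")
  split_hs <- pv("clinical.severity_split_hs")
  gi <- pv("treatment.gi_share_of_ech")
  cost_ech <- gi * pv("economics.cost_gi_bleed") + (1 - gi) * pv("economics.cost_other_ech")
  cost_is <- c(pv("economics.cost_is_mild"), pv("economics.cost_is_moderate"),
               pv("economics.cost_is_severe"), pv("economics.cost_is_fatal"))
  cost_hs <- c(pv("economics.cost_hs_mild"), pv("economics.cost_hs_moderate"),
               pv("economics.cost_hs_severe"), pv("economics.cost_hs_fatal"))
  u_acute <- c(pv("economics.u_stroke_acute_mild"), pv("economics.u_stroke_acute_moderate"),
               pv("economics.u_stroke_acute_severe"), 0)
  du_rec <- pv("economics.du_recurrent_acute")
  du_bleed <- pv("economics.du_bleed") * cy
  ech_tmp <- pv("treatment.ech_temporary_share")
  ich_tmp <- pv("treatment.ich_temporary_share")
  ech_bar <- pv("treatment.ech_barred_share")
  ich_bar <- pv("treatment.ich_barred_share")

  ti <- list(); n_tr <- 0L
  push <- function(i, j, sel, mult, cost, du, cat, sev) {
    n_tr <<- n_tr + 1L
    ti[[n_tr]] <<- c(i, j, sel, mult, cost, du, cat, sev)
  }
  # sel: 1 = IS, 2 = HS, 3 = other ICH, 4 = ECH, 5 = CRNM
  for (i in seq_len(ns)) {
    h <- st$health[i]; rec <- h != "event_free"
    # ischemic stroke (treatment course unaffected; a pause still completes)
    for (k in 1:4) {
      if (k < 4) {
        hh <- worse_health(h, k)
        j <- sidx(st$af[i], st$dx[i], resume_tx[i], st$barred[i], hh)
        du <- (u_acute[k] - u_health_by[hh]) * cy + if (rec) du_rec * cy else 0
        push(i, j, 1L, split_is[k], cost_is[k], du, 1L, k)
      } else {
        push(i, sp$dead, 1L, split_is[4], cost_is[4], 0, 1L, 4L)
      }
    }
    # hemorrhagic stroke: permanent OAC stop, everyone barred from future OAC
    hs_tx <- if (on_oac[i]) "aspirin" else st$tx[i]
    for (k in 1:4) {
      if (k < 4) {
        hh <- worse_health(h, k)
        j <- sidx(st$af[i], st$dx[i], hs_tx, 1L, hh)
        du <- (u_acute[k] - u_health_by[hh]) * cy + if (rec) du_rec * cy else 0
        push(i, j, 2L, split_hs[k], cost_hs[k], du, 2L, 0L)
      } else {
        push(i, sp$dead, 2L, split_hs[4], cost_hs[4], 0, 2L, 0L)
      }
    }
    # other intracranial hemorrhage
    c_oich <- pv("economics.cost_other_ich")
    if (on_oac[i]) {
      push(i, sidx(st$af[i], st$dx[i], "paused", 0L, h), 3L, ich_tmp, c_oich, du_bleed, 2L, 0L)
      push(i, sidx(st$af[i], st$dx[i], "aspirin", 1L, h), 3L, 1 - ich_tmp, c_oich, du_bleed, 2L, 0L)
    } else if (st$barred[i] == 1L) {
      push(i, noev_dst[i], 3L, 1, c_oich, du_bleed, 2L, 0L)
    } else {
      push(i, sidx(st$af[i], st$dx[i], st$tx[i], 1L, h), 3L, ich_bar, c_oich, du_bleed, 2L, 0L)
      push(i, noev_dst[i], 3L, 1 - ich_bar, c_oich, du_bleed, 2L, 0L)
    }
    # extracranial hemorrhage
    if (on_oac[i]) {
      push(i, sidx(st$af[i], st$dx[i], "paused", 0L, h), 4L, ech_tmp, cost_ech, du_bleed, 2L, 0L)
      push(i, sidx(st$af[i], st$dx[i], "aspirin", 1L, h), 4L, 1 - ech_tmp, cost_ech, du_bleed, 2L, 0L)
    } else if (st$barred[i] == 1L) {
      push(i, noev_dst[i], 4L, 1, cost_ech, du_bleed, 2L, 0L)
    } else {
      push(i, sidx(st$af[i], st$dx[i], st$tx[i], 1L, h), 4L, ech_bar, cost_ech, du_bleed, 2L, 0L)
      push(i, noev_dst[i], 4L, 1 - ech_bar, cost_ech, du_bleed, 2L, 0L)
    }
    # clinically relevant non-major bleed: therapy continues
    push(i, noev_dst[i], 5L, 1, pv("economics.cost_crnm"), du_bleed, 2L, 0L)
  }
  tr <- do.call(rbind, ti)
  colnames(tr) <- c("i", "j", "sel", "mult", "cost", "du", "cat", "sev")
  tr <- tr[order(tr[, "i"]), , drop = FALSE]
  ev_groups <- as.integer(tr[, "i"])
  flow_grp <- c(as.integer(tr[, "j"]), noev_dst)
  flow_ugrp <- sort(unique(flow_grp))

  # --- per-cycle factors ---------------------------------------------
  t_ix <- seq_len(n_cycles)
  ages <- a0 + (t_ix - 1L) * cy
  agef_is <- pv("clinical.age_adjust_per_decade")^((ages - a0) / 10)
  agef_bleed <- pv("clinical.bleed_age_factor_per_decade")^((ages - a0) / 10)
  lt <- params$tables$life_table
  qx <- vapply(ages, function(a) if (a >= max(lt$age)) 1 else lt$qx[findInterval(floor(a), lt$age)],
               numeric(1))
  qx_cycle <- annual_to_cycle(pmin(qx, 1), 1 / cy)
  r <- pv("economics.discount_rate_annual")
  disc <- (1 + r)^(-(t_ix * cy))

  uplift <- 1 + pv("economics.payer_uplift")
  monitoring_mode <- params$economics$soc_monitoring_mode
  if (is.null(monitoring_mode)) monitoring_mode <- "per_cycle"

  structure(list(
    params = params, space = sp, schedule = schedule,
    n_cycles = n_cycles, horizon_cycles = horizon_cycles, cy = cy,
    ages = ages, agef_is = agef_is, agef_bleed = agef_bleed,
    qx_cycle = qx_cycle, disc = disc,
    col_ix = col_ix, bc_ix = bc_ix, bleed_annual = bleed_annual,
    mort_mult = mort_mult, u_state = u_state, drug_cost = drug_cost,
    post_cost = post_cost, undx = st$dx == 0L,
    inc_src = inc_src, inc_dst = inc_dst,
    det_i = det_i, det_j = det_j, det_frac = det_frac,
    disc_src = disc_src, disc_dst = disc_dst, noev_dst = noev_dst,
    trip = tr, ev_groups = ev_groups, flow_grp = flow_grp, flow_ugrp = flow_ugrp,
    mask_is = tr[, "cat"] == 1L, mask_bleed = tr[, "cat"] == 2L,
    mask_sev = lapply(1:4, function(k) tr[, "sel"] == 1L & tr[, "sev"] == k),
    mask_ev = lapply(2:5, function(s) tr[, "sel"] == s),
    grid_cols = grid_cols,
    grid_ann = {
      grid <- params$tables$risk_grid
      m <- as.matrix(grid[, grid_cols])
      rownames(m) <- as.character(grid$chads2)
      m
    },
    split_is = pv("clinical.severity_split_is"),
    costs = list(
      insertion = pv("economics.cost_icm_insertion") * uplift,
      removal = pv("economics.cost_icm_removal") * uplift,
      icm_cycle = pv("economics.cost_icm_monitoring_cycle") * uplift,
      soc_cycle = pv("economics.cost_soc_monitoring_cycle") * uplift,
      holter = pv("economics.cost_holter") * uplift),
    monitoring_mode = monitoring_mode,
    cycles_per_year = 1 / cy
  ), class = "icm_model_context")
}

#' Per-cycle stage probabilities
#'
#' The shared kernel: per-cycle AF incidence, effective conditional
#' detection for the strategy, per-state background-death vector, and
#' the (state x event-family) probability matrix, all for cycle `t` of
#' the given CHADS2 stratum. Consumed identically by the cohort engine
#' and the microsimulation oracle.
#'
#' @param mc An `icm_model_context`.
#' @param chads2 CHADS2 stratum (row of the risk grid).
#' @param strategy `"ICM"` or `"SoC"`.
#' @param t Cycle index (1-based).
#' @return List with `p_inc`, `q_det`, `pd`, and event matrix `P`.
#' @export
cycle_stage_probs <- function(mc, chads2, strategy, t) {
  sch <- mc$schedule
  p_inc <- sch$per_cycle_af_incidence[t]
  q_det <- if (strategy == "ICM") {
    s <- sch$device_surviving_start[t]
    s * sch$per_cycle_conditional_detection_icm[t] +
      (1 - s) * sch$per_cycle_conditional_detection_soc[t]
  } else {
    sch$per_cycle_conditional_detection_soc[t]
  }
  pd <- pmin(1, mc$qx_cycle[t] * mc$mort_mult)

  if (!(as.character(chads2) %in% rownames(mc$grid_ann))) {
    stop("CHADS2 score not in risk grid: ", chads2)
  }
  ann6 <- mc$grid_ann[as.character(chads2), ]
  p_is <- annual_to_cycle(pmin(ann6[mc$col_ix] * mc$agef_is[t], 1), mc$cycles_per_year)
  bl <- annual_to_cycle(pmin(mc$bleed_annual * mc$agef_bleed[t], 1), mc$cycles_per_year)
  P <- cbind(is = p_is, hs = bl[mc$bc_ix, "hs"], other_ich = bl[mc$bc_ix, "other_ich"],
             ech = bl[mc$bc_ix, "ech"], crnm = bl[mc$bc_ix, "crnm"])
  list(p_inc = p_inc, q_det = q_det, pd = pd, P = P)
}

#' Precompute all per-cycle event/death probabilities for one stratum
#'
#' Vectorised over cycles: returns the per-cycle triplet event
#' probabilities (after the competing-risk rescale), the no-event
#' remainders, and the per-state background-death probabilities, as
#' (rows x cycles) matrices. Column `t` agrees exactly with
#' [cycle_stage_probs()]/[event_probs()] at cycle `t`; both strategies
#' share the kernel (only detection differs between arms).
#'
#' @param mc An `icm_model_context`.
#' @param chads2 CHADS2 stratum.
#' @return List with `p_trip`, `p_noev`, `pd` matrices.
#' @export
stratum_kernel <- function(mc, chads2) {
  if (!(as.character(chads2) %in% rownames(mc$grid_ann))) {
    stop("CHADS2 score not in risk grid: ", chads2)
  }
  Tn <- mc$n_cycles
  ns <- mc$space$n - 1L
  cpy <- mc$cycles_per_year
  ann6 <- mc$grid_ann[as.character(chads2), ]
  # (state x cycle) ischemic-stroke and bleed probabilities
  p_is <- 1 - (1 - pmin(outer(ann6[mc$col_ix], mc$agef_is), 1))^(1 / cpy)
  bl_ann <- mc$bleed_annual[mc$bc_ix, , drop = FALSE]  # state x 4
  Pall <- array(0, c(ns, 5L, Tn))
  Pall[, 1L, ] <- p_is
  for (k in 1:4) {
    Pall[, k + 1L, ] <- 1 - (1 - pmin(outer(bl_ann[, k], mc$agef_bleed), 1))^(1 / cpy)
  }
  tr <- mc$trip
  flat <- matrix(Pall, ns * 5L, Tn)  # row (sel-1)*ns + i
  p_trip <- flat[(tr[, "sel"] - 1L) * ns + tr[, "i"], , drop = FALSE] * tr[, "mult"]
  tot <- rowsum(p_trip, mc$ev_groups, reorder = FALSE)
  scale <- ifelse(tot > 1, 1 / tot, 1)
  p_trip <- p_trip * scale[mc$ev_groups, , drop = FALSE]
  p_noev <- pmax(1 - pmin(tot, 1), 0)
  pd <- pmin(outer(mc$mort_mult, mc$qx_cycle), 1)
  list(p_trip = p_trip, p_noev = p_noev, pd = pd)
}

#' Compose the full one-cycle transition matrix
#'
#' Chains the within-cycle stages (AF incidence, detection, background
#' death, competing events with pause completion, background OAC
#' discontinuation) into a single row-stochastic matrix; raises an
#' error if any row sum deviates from 1 by more than 1e-9. Used for
#' validation and the microsimulation oracle, not the accumulation path
#' (which needs the stage-resolved flows for event payoffs).
#'
#' @inheritParams cycle_stage_probs
#' @return Dense (n-states x n-states) matrix.
#' @export
build_transition_matrix <- function(mc, chads2, strategy, t) {
  S <- mc$space$n
  k <- cycle_stage_probs(mc, chads2, strategy, t)
  A <- diag(S)
  A[cbind(mc$inc_src, mc$inc_src)] <- 1 - k$p_inc
  A[cbind(mc$inc_src, mc$inc_dst)] <- A[cbind(mc$inc_src, mc$inc_dst)] + k$p_inc
  B <- diag(S)
  B[cbind(mc$det_i, mc$det_i)] <- 1 - k$q_det
  B[cbind(mc$det_i, mc$det_j)] <- B[cbind(mc$det_i, mc$det_j)] + k$q_det * mc$det_frac
  ns <- S - 1L
  Cm <- diag(S)
  Cm[cbind(seq_len(ns), seq_len(ns))] <- 1 - k$pd
  Cm[cbind(seq_len(ns), rep(mc$space$dead, ns))] <- k$pd
  ev <- event_probs(mc, k$P)
  E <- matrix(0, S, S)
  lin <- c((mc$trip[, "j"] - 1) * S + mc$trip[, "i"],
           (mc$noev_dst - 1) * S + seq_len(ns))
  agg <- rowsum(c(ev$p_trip, ev$p_noev), lin, reorder = TRUE)
  E[sort(unique(lin))] <- agg[, 1L]
  E[S, S] <- 1
  D <- diag(S)
  p_bg <- annual_to_cycle(
    param_value(mc$params, "treatment.background_discontinuation_annual"),
    mc$cycles_per_year)
  D[cbind(mc$disc_src, mc$disc_src)] <- 1 - p_bg
  D[cbind(mc$disc_src, mc$disc_dst)] <- D[cbind(mc$disc_src, mc$disc_dst)] + p_bg
  M <- A %*% B %*% Cm %*% E %*% D
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("transition matrix assembly error: row sums deviate from 1 (max ",
         format(max(abs(rs - 1))), ")")
  }
  M
}

#' @noRd
event_probs <- function(mc, P) {
  tr <- mc$trip
  p_trip <- P[cbind(tr[, "i"], tr[, "sel"])] * tr[, "mult"]
  tot <- as.numeric(rowsum(p_trip, mc$ev_groups, reorder = FALSE))
  scale <- ifelse(tot > 1, 1 / tot, 1)
  p_trip <- p_trip * scale[mc$ev_groups]
  p_noev <- pmax(0, 1 - pmin(tot, 1))
  list(p_trip = p_trip, p_noev = p_noev)
}

#' Propagate an occupancy vector through per-cycle matrices
#'
#' `occupancy_{t+1} = occupancy_t %*% M_t`. Stops early once the alive
#' fraction falls below `1e-6`.
#'
#' @param init Initial occupancy vector.
#' @param matrices List of transition matrices (one per cycle) or a
#'   function `function(t)` returning the cycle-`t` matrix.
#' @param n_cycles Number of cycles (required when `matrices` is a function).
#' @param dead Index of the absorbing Dead state (for the early stop).
#' @return Matrix `(n_cycles + 1) x n_states` of occupancies; class
#'   `icm_cohort_trace`.
#' @export
propagate <- function(init, matrices, n_cycles = length(matrices), dead = length(init)) {
  get_m <- if (is.function(matrices)) matrices else function(t) matrices[[t]]
  trace <- matrix(0, n_cycles + 1L, length(init))
  trace[1L, ] <- init
  occ <- init
  for (t in seq_len(n_cycles)) {
    occ <- as.numeric(occ %*% get_m(t))
    if (any(!is.finite(occ))) stop("non-finite occupancy at cycle ", t)
    trace[t + 1L, ] <- occ
    if (1 - occ[dead] < 1e-6) {
      if (t < n_cycles) trace[(t + 2L):(n_cycles + 1L), ] <- rep(occ, each = n_cycles - t)
      break
    }
  }
  structure(trace, class = c("icm_cohort_trace", "matrix"))
}

#' Run one strategy for one CHADS2 stratum
#'
#' Staged cohort propagation with full payoff accumulation. Event costs
#' and disutilities attach to the transition flows of the cycle in
#' which they occur; state costs and utilities accrue on end-of-cycle
#' occupancy (no half-cycle correction); one-time ICM insertion is paid
#' at cycle 0 and removal on unplanned explant or at battery expiry.
#'
#' @param mc An `icm_model_context`.
#' @param chads2 CHADS2 stratum.
#' @param strategy `"ICM"` or `"SoC"`.
#' @param kern Optional precomputed [stratum_kernel()] for this stratum.
#' @return List of class `icm_strategy_outcome` (see [run_cea()]).
#' @export
run_strategy_stratum <- function(mc, chads2, strategy, kern = NULL) {
  if (is.null(kern)) kern <- stratum_kernel(mc, chads2)
  S <- mc$space$n
  ns <- S - 1L
  dead <- mc$space$dead
  occ <- mc$space$init
  tr <- mc$trip
  sch <- mc$schedule
  p_bg <- annual_to_cycle(
    param_value(mc$params, "treatment.background_discontinuation_annual"),
    mc$cycles_per_year)

  cats <- c("device_monitoring", "drugs", "is_events", "bleed_events", "post_stroke")
  zero <- stats::setNames(numeric(5), cats)
  acc <- list(d_cost = zero, u_cost = zero, d_qaly = 0, u_qaly = 0,
              d_ly = 0, u_ly = 0)
  counts <- c(is_mild = 0, is_moderate = 0, is_severe = 0, is_fatal = 0,
              hs = 0, other_ich = 0, ech = 0, crnm = 0)
  icm_arm <- strategy == "ICM"
  if (icm_arm) {
    acc$d_cost["device_monitoring"] <- mc$costs$insertion
    acc$u_cost["device_monitoring"] <- mc$costs$insertion
  }
  trace <- matrix(0, mc$n_cycles + 1L, S)
  trace[1L, ] <- occ

  det_states <- unique(mc$det_i)
  n_run <- mc$horizon_cycles
  for (t in seq_len(n_run)) {
    p_inc <- sch$per_cycle_af_incidence[t]
    q_det <- if (icm_arm) {
      s <- sch$device_surviving_start[t]
      s * sch$per_cycle_conditional_detection_icm[t] +
        (1 - s) * sch$per_cycle_conditional_detection_soc[t]
    } else {
      sch$per_cycle_conditional_detection_soc[t]
    }
    # AF incidence
    mv <- occ[mc$inc_src] * p_inc
    occ[mc$inc_src] <- occ[mc$inc_src] - mv
    occ[mc$inc_dst] <- occ[mc$inc_dst] + mv
    # detection
    det_mass <- occ[mc$det_i] * q_det * mc$det_frac
    occ[det_states] <- occ[det_states] * (1 - q_det)
    for (z in seq_along(mc$det_j)) occ[mc$det_j[z]] <- occ[mc$det_j[z]] + det_mass[z]
    # background death
    dying <- occ[seq_len(ns)] * kern$pd[, t]
    occ[seq_len(ns)] <- occ[seq_len(ns)] - dying
    occ[dead] <- occ[dead] + sum(dying)
    # competing events
    occ_alive <- occ[seq_len(ns)]
    f <- occ_alive[tr[, "i"]] * kern$p_trip[, t]
    noev_flow <- occ_alive * kern$p_noev[, t]
    res <- rowsum(c(f, noev_flow), mc$flow_grp, reorder = TRUE)
    occ_new <- numeric(S)
    occ_new[mc$flow_ugrp] <- res[, 1L]
    occ_new[dead] <- occ_new[dead] + occ[dead]
    occ <- occ_new
    # background OAC discontinuation
    mv <- occ[mc$disc_src] * p_bg
    occ[mc$disc_src] <- occ[mc$disc_src] - mv
    occ[mc$disc_dst] <- occ[mc$disc_dst] + mv

    trace[t + 1L, ] <- occ

    # ---- payoffs ----
    d <- mc$disc[t]
    alive <- 1 - occ[dead]
    fc <- f * tr[, "cost"]
    ev_cost_is <- sum(fc[mc$mask_is])
    ev_cost_bl <- sum(fc[mc$mask_bleed])
    ev_du <- sum(f * tr[, "du"])
    for (k2 in 1:4) counts[k2] <- counts[k2] + sum(f[mc$mask_sev[[k2]]])
    counts["hs"] <- counts["hs"] + sum(f[mc$mask_ev[[1L]]])
    counts["other_ich"] <- counts["other_ich"] + sum(f[mc$mask_ev[[2L]]])
    counts["ech"] <- counts["ech"] + sum(f[mc$mask_ev[[3L]]])
    counts["crnm"] <- counts["crnm"] + sum(f[mc$mask_ev[[4L]]])

    drug <- sum(occ[seq_len(ns)] * mc$drug_cost)
    post <- sum(occ[seq_len(ns)] * mc$post_cost)
    undx_alive <- sum(occ[seq_len(ns)][mc$undx])
    mon <- if (icm_arm) {
      s_end <- sch$device_surviving_end[t]
      alive * s_end * mc$costs$icm_cycle +
        undx_alive * (1 - s_end) * soc_monitoring_cost(mc, t)
    } else {
      undx_alive * soc_monitoring_cost(mc, t)
    }
    removal <- 0
    if (icm_arm) {
      s0 <- sch$device_surviving_start[t]; s1 <- sch$device_surviving_end[t]
      removal <- alive * (s0 - s1) * mc$costs$removal
      if (t == sch$battery_cycles) removal <- removal + alive * s1 * mc$costs$removal
    }
    cyc_cost <- c(device_monitoring = mon + removal, drugs = drug,
                  is_events = ev_cost_is, bleed_events = ev_cost_bl,
                  post_stroke = post)
    acc$d_cost <- acc$d_cost + cyc_cost * d
    acc$u_cost <- acc$u_cost + cyc_cost
    q <- sum(occ[seq_len(ns)] * mc$u_state) * mc$cy + ev_du
    acc$d_qaly <- acc$d_qaly + q * d
    acc$u_qaly <- acc$u_qaly + q
    acc$d_ly <- acc$d_ly + alive * mc$cy * d
    acc$u_ly <- acc$u_ly + alive * mc$cy
    if (alive < 1e-6) {
      if (t < mc$n_cycles) {
        trace[(t + 2L):(mc$n_cycles + 1L), ] <- rep(occ, each = mc$n_cycles - t)
      }
      break
    }
  }
  unfilled <- which(rowSums(trace) == 0)
  if (length(unfilled)) trace[unfilled, ] <- rep(occ, each = length(unfilled))

  is_total <- sum(counts[1:4])
  structure(list(
    strategy = strategy, chads2 = chads2,
    discounted_cost_total = sum(acc$d_cost), cost_by_category = acc$d_cost,
    undiscounted_cost_total = sum(acc$u_cost), undiscounted_cost_by_category = acc$u_cost,
    qalys = acc$d_qaly, undiscounted_qalys = acc$u_qaly,
    life_years = acc$d_ly, undiscounted_life_years = acc$u_ly,
    is_events_per_1000 = is_total * 1000,
    strokes_by_severity = counts[1:4] * 1000,
    bleed_events_per_1000 = counts[5:8] * 1000,
    trace = structure(trace, class = c("icm_cohort_trace", "matrix"))
  ), class = "icm_strategy_outcome")
}

#' @noRd
soc_monitoring_cost <- function(mc, t) {
  if (identical(mc$monitoring_mode, "one_holter")) {
    if (t == 1L) mc$costs$holter else 0
  } else {
    mc$costs$soc_cycle
  }
}

#' @noRd
combine_outcomes <- function(outs, weights) {
  w <- weights / sum(weights)
  num_fields <- c("discounted_cost_total", "undiscounted_cost_total", "qalys",
                  "undiscounted_qalys", "life_years", "undiscounted_life_years",
                  "is_events_per_1000")
  vec_fields <- c("cost_by_category", "undiscounted_cost_by_category",
                  "strokes_by_severity", "bleed_events_per_1000")
  agg <- outs[[1L]]
  for (f in num_fields) agg[[f]] <- sum(vapply(outs, `[[`, numeric(1), f) * w)
  for (f in vec_fields) {
    m <- vapply(outs, `[[`, outs[[1L]][[f]], f)
    agg[[f]] <- as.numeric(m %*% w)
    names(agg[[f]]) <- names(outs[[1L]][[f]])
  }
  agg$chads2 <- "aggregate"
  agg$trace <- NULL
  agg
}

#' Run one strategy, aggregated over the CHADS2 mix
#'
#' @param params An `icm_params` object.
#' @param strategy `"ICM"` or `"SoC"`.
#' @param mc Optional prebuilt model context (rebuilt when missing).
#' @return An `icm_strategy_outcome` aggregated over the bundle's
#'   CHADS2 distribution.
#' @export
run_strategy <- function(params, strategy, mc = NULL) {
  if (is.null(mc)) mc <- build_model_context(params)
  dist <- param_value(params, "structural.chads2_distribution")
  scores <- as.integer(names(dist))
  outs <- lapply(scores, function(k) run_strategy_stratum(mc, k, strategy))
  combine_outcomes(outs, as.numeric(dist))
}

#' Run the full ICM-vs-SoC comparison
#'
#' Evaluates both strategies on the same parameter set and model
#' context and returns per-strategy outcomes plus the incremental
#' comparison (see [compare_strategies()]).
#'
#' @param params An `icm_params` object.
#' @param mc Optional prebuilt `icm_model_context`.
#' @return List of class `icm_cea_result` with elements `icm`, `soc`
#'   and `comparison`.
#' @export
run_cea <- function(params, mc = NULL) {
  if (is.null(mc)) mc <- build_model_context(params)
  dist <- param_value(params, "structural.chads2_distribution")
  scores <- as.integer(names(dist))
  kerns <- lapply(scores, function(k) stratum_kernel(mc, k))
  one_arm <- function(strategy) {
    outs <- lapply(seq_along(scores), function(z)
      run_strategy_stratum(mc, scores[z], strategy, kern = kerns[[z]]))
    combine_outcomes(outs, as.numeric(dist))
  }
  icm <- one_arm("ICM")
  soc <- one_arm("SoC")
  structure(list(icm = icm, soc = soc,
                 comparison = compare_strategies(icm, soc)),
            class = "icm_cea_result")
}
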