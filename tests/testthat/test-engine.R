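test_that("the state space excludes invalid tuples and seeds the published mix", {
  ps <- base_params()
  sp <- enumerate_states(ps)
  st <- sp$states
  expect_identical(sp$n, nrow(st) + 1L)
  # diagnosis implies AF; OAC implies diagnosis; barred excludes OAC
  expect_true(all(st$af[st$dx == 1L] == 1L))
  expect_true(all(st$dx[st$tx %in% c("noac", "paused", "warfarin")] == 1L))
  expect_true(all(st$barred[st$tx %in% c("noac", "paused", "warfarin")] == 0L))
  expect_true(all(st$tx[st$dx == 0L] %in% c("none", "aspirin")))

  expect_equal(sum(sp$init), 1)
  on_asp <- st$tx == "aspirin" & st$dx == 0L
  expect_equal(sum(sp$init[seq_len(nrow(st))][on_asp]), 0.73)
  expect_true(all(sp$init[seq_len(nrow(st))][st$health != "event_free"] == 0))
  expect_true(all(sp$init[seq_len(nrow(st))][st$af == 1L] == 0))
})

test_that("per-cycle transition matrices are row-stochastic across the horizon", {
  mc <- build_model_context(base_params())
  for (t in c(1L, 2L, 12L, 13L, 60L, 110L)) {
    for (strat in c("ICM", "SoC")) {
      M <- build_transition_matrix(mc, 3, strat, t)
      expect_lt(max(abs(rowSums(M) - 1)), 1e-9)
      expect_true(all(M >= 0))
      expect_equal(M[mc$space$dead, mc$space$dead], 1)  # death absorbs
    }
  }
})

test_that("staged propagation equals brute-force matrix multiplication", {
  mc <- build_model_context(base_params())
  out <- run_strategy_stratum(mc, 4, "ICM")
  tr_prod <- propagate(mc$space$init,
                       function(t) build_transition_matrix(mc, 4, "ICM", t),
                       n_cycles = 15, dead = mc$space$dead)
  expect_lt(max(abs(out$trace[1:16, ] - tr_prod)), 1e-12)
})

test_that("propagate keeps identity dynamics constant and death nondecreasing", {
  mc <- build_model_context(base_params())
  S <- mc$space$n
  tr <- propagate(mc$space$init, function(t) diag(S), n_cycles = 5, dead = S)
  expect_true(all(apply(tr, 1, function(r) identical(r, tr[1, ]))))

  out <- run_strategy_stratum(mc, 3, "SoC")
  expect_true(all(diff(out$trace[, mc$space$dead]) >= -1e-12))
})

test_that("a zero-risk cohort accrues the closed-form QALYs and the ICM insertion cost", {
  ps <- zero_risk_params(utility = 0.81, horizon_years = 1)
  res <- run_cea(ps)
  # one undiscounted year alive at utility 0.81
  expect_equal(res$soc$qalys, 0.81, tolerance = 1e-9)
  expect_equal(res$soc$life_years, 1, tolerance = 1e-9)
  expect_equal(res$icm$qalys, 0.81, tolerance = 1e-9)
  # no events anywhere
  expect_equal(res$soc$is_events_per_1000, 0)
  expect_equal(unname(res$icm$cost_by_category[c("is_events", "bleed_events",
                                                 "post_stroke")]), rep(0, 3))
  # cycle-0 insertion cost appears only in the ICM arm
  expect_gte(res$icm$cost_by_category[["device_monitoring"]], 7042)
  expect_equal(res$soc$undiscounted_cost_total,
               sum(res$soc$undiscounted_cost_by_category))
})

test_that("discounting uses (1 + r)^(-t) on the annual scale", {
  mc <- build_model_context(base_params())
  # end of year 2 = cycle 8
  expect_equal(mc$disc[8], 1.03^-2, tolerance = 1e-12)
  expect_true(all(diff(mc$disc) < 0))
  out <- run_strategy_stratum(mc, 3, "SoC")
  expect_lte(out$discounted_cost_total, out$undiscounted_cost_total)
  expect_lte(out$qalys, out$undiscounted_qalys)
})

test_that("cost categories sum to the total and uptake=1 sends all detections to OAC", {
  res <- run_cea(base_params())
  for (o in list(res$icm, res$soc)) {
    expect_equal(sum(o$cost_by_category), o$discounted_cost_total)
    expect_equal(sum(o$undiscounted_cost_by_category), o$undiscounted_cost_total)
  }
  # with full uptake (and no discontinuation or bleeds) no mass ever
  # reaches diagnosed-aspirin:
  zr <- zero_risk_params(horizon_years = 2)
  zr$treatment$background_discontinuation_annual$value <- 0
  mc <- build_model_context(zr)
  out <- run_strategy_stratum(mc, 3, "ICM")
  st <- mc$space$states
  dx_asp_unbarred <- which(st$dx == 1L & st$tx == "aspirin" & st$barred == 0L)
  expect_equal(max(out$trace[, dx_asp_unbarred]), 0)
})

test_that("base-case dominance direction favours ICM on strokes and QALYs", {
  res <- run_cea(base_params())
  expect_lte(res$icm$is_events_per_1000, res$soc$is_events_per_1000)
  expect_gte(res$icm$qalys, res$soc$qalys)
  expect_gt(res$comparison$delta_cost, 0)
})

test_that("cohort occupancy is conserved at every cycle of both arms", {
  mc <- build_model_context(base_params())
  for (strat in c("ICM", "SoC")) {
    for (k in c(2, 4, 6)) {
      tr <- run_strategy_stratum(mc, k, strat)$trace
      expect_lt(max(abs(rowSums(tr) - 1)), 1e-10)
    }
  }
})
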