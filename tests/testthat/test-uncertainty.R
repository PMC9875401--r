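test_that("PSA draws are reproducible, respect fixed families, and centre on base values", {
  ps <- base_params()
  d1 <- draw_psa(ps, 5, seed = 21)
  d2 <- draw_psa(ps, 5, seed = 21)
  expect_equal(lapply(d1, flatten_parameters), lapply(d2, flatten_parameters))

  n <- 400
  draws <- draw_psa(ps, n, seed = 22)
  grab <- function(path) vapply(draws, function(p) param_value(p, path), numeric(1))
  # fixed parameters never move
  expect_identical(unique(grab("detection.device_sensitivity")), 0.961)
  expect_identical(unique(grab("treatment.noac_uptake")), 1)
  # sampled parameters stay near their means (law of large numbers, 3 se/sqrt(n))
  for (path in c("economics.cost_is_mild", "economics.u_baseline",
                 "treatment.background_discontinuation_annual")) {
    leaf <- param_leaf(ps, path)
    expect_lt(abs(mean(grab(path)) - leaf$value), 3 * leaf$se / sqrt(n) + 1e-9,
              label = path)
  }
  # lognormal HR is median-preserving on the log scale
  hr <- grab("detection.hr_icm_vs_soc")
  expect_lt(abs(mean(log(hr)) - log(33.9)), 3 * 0.4811 / sqrt(n))
  expect_true(all(hr > 0))
  # drawn relative risks propagate into the grid
  g3 <- vapply(draws, function(p) p$tables$risk_grid$subaf_none[4], numeric(1))
  rr <- grab("clinical.rr_subclinical_af")
  expect_equal(g3, 0.062 * rr / 2.4, tolerance = 1e-12)
})

test_that("an infeasible beta moment match names the parameter", {
  ps <- base_params()
  ps$economics$u_baseline$se <- 0.6
  expect_error(draw_psa(ps, 1, seed = 1), "u_baseline")
})

test_that("PSA with point-mass distributions reproduces the deterministic run exactly", {
  ps <- point_mass_params()
  det <- run_cea(ps)
  psa <- run_psa(ps, n = 3, seed = 5)
  expect_equal(psa$n_failed, 0L)
  expect_true(all(psa$samples$delta_cost == det$comparison$delta_cost))
  expect_true(all(psa$samples$delta_qaly == det$comparison$delta_qaly))
  expect_equal(psa$mean_icer, det$comparison$icer_per_qaly)
})

test_that("CEAC is monotone in the threshold and bracketed by the trivial limits", {
  ps <- base_params()
  psa <- run_psa(ps, n = 40, seed = 9)
  expect_identical(psa$n, 40L)
  cc <- ceac(psa, seq(0, 3e5, by = 2.5e4))
  expect_true(all(diff(cc$prob_cost_effective) >= 0))
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  if (all(psa$samples$delta_cost > 0)) {
    expect_equal(cc$prob_cost_effective[cc$threshold == 0], 0)
  }
  # credible intervals bracket the means
  expect_gte(psa$means[["delta_cost"]], psa$cri_95$delta_cost[1])
  expect_lte(psa$means[["delta_cost"]], psa$cri_95$delta_cost[2])
})

test_that("independent-seed PSA means agree within Monte-Carlo error", {
  ps <- base_params()
  p1 <- run_psa(ps, n = 30, seed = 101)
  p2 <- run_psa(ps, n = 30, seed = 202)
  for (col in c("delta_cost", "delta_qaly")) {
    se <- sqrt(stats::var(p1$samples[[col]]) / 30 + stats::var(p2$samples[[col]]) / 30)
    expect_lt(abs(mean(p1$samples[[col]]) - mean(p2$samples[[col]])), 3 * se,
              label = col)
  }
})

test_that("one-way DSA honours bounds and degenerates at the base value", {
  ps <- base_params()
  base_icer <- run_cea(ps)$comparison$icer_per_qaly
  hr0 <- param_value(ps, "detection.hr_icm_vs_soc")
  same <- one_way_dsa(ps, "detection.hr_icm_vs_soc", hr0, hr0)
  expect_equal(same$icer_low, base_icer, tolerance = 1e-9)
  expect_equal(same$icer_high, base_icer, tolerance = 1e-9)

  hr <- one_way_dsa(ps, "detection.hr_icm_vs_soc", 13.2, 60)
  expect_gt(hr$icer_low, base_icer)   # weaker relative yield worsens the ICER
  expect_lt(hr$icer_high, base_icer)

  dev <- one_way_dsa(ps, "economics.cost_icm_insertion", 7042 * 0.7, 7042 * 1.3)
  expect_lt(dev$icer_low, base_icer)
  expect_gt(dev$icer_high, base_icer)

  expect_error(one_way_dsa(ps, "economics.cost_unicorn", 1, 2), "unknown parameter")
  expect_error(one_way_dsa(ps, "treatment.noac_uptake", -0.2, 1), "validation")
})

test_that("the scenario grid runs, reports skips, and the empty override is the base", {
  ps <- base_params()
  specs <- scenario_table()[c("base_case", "warfarin", "private_payer")]
  specs$broken <- scenario_spec("broken", list("files.detection_curve" = "missing.csv"))
  grid <- run_scenario_grid(ps, specs)
  expect_identical(grid$status[1:3], rep("ok", 3))
  expect_match(grid$status[4], "skipped")
  base_icer <- run_cea(ps)$comparison$icer_per_qaly
  expect_equal(grid$icer_per_qaly[grid$scenario == "base_case"], base_icer)
  expect_gt(grid$icer_per_qaly[grid$scenario == "warfarin"], base_icer)
  expect_gt(grid$icer_per_qaly[grid$scenario == "private_payer"], base_icer)
})
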