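test_that("the packaged base case loads, validates, and matches the published inputs", {
  ps <- base_params()
  expect_s3_class(ps, "icm_params")
  expect_identical(nrow(validate(ps)), 0L)

  # provenance spot checks against the published cost/utility/risk tables
  expected <- list(
    c("economics.discount_rate_annual", 0.03),
    c("economics.cost_is_mild", 21567), c("economics.cost_is_moderate", 25124),
    c("economics.cost_is_severe", 32279), c("economics.cost_hs_mild", 23622),
    c("economics.cost_hs_severe", 43195), c("economics.cost_other_ich", 25149),
    c("economics.cost_crnm", 1163), c("economics.cost_gi_bleed", 9136),
    c("economics.cost_other_ech", 13813), c("economics.cost_post_mild_cycle", 3239),
    c("economics.cost_post_severe_cycle", 19212),
    c("economics.cost_icm_insertion", 7042), c("economics.cost_icm_removal", 738),
    c("economics.cost_icm_monitoring_cycle", 119),
    c("economics.cost_soc_monitoring_cycle", 35),
    c("economics.cost_noac_cycle", 118),
    c("economics.u_baseline", 0.81), c("economics.u_af_decrement", -0.014),
    c("economics.u_post_moderate", 0.45), c("economics.du_bleed", -0.181),
    c("detection.hr_icm_vs_soc", 33.9), c("detection.device_sensitivity", 0.961),
    c("detection.battery_years", 3), c("detection.unplanned_removal_annual", 0.029),
    c("detection.soc_holters_per_year", 0.17), c("detection.soc_ecgs_per_year", 3.40),
    c("treatment.noac_uptake", 1), c("treatment.background_discontinuation_annual", 0.148),
    c("treatment.pre_detection_aspirin_share", 0.73),
    c("clinical.rr_subclinical_af", 2.4), c("clinical.age_adjust_per_decade", 1.46),
    c("structural.baseline_age", 71.3))
  for (e in expected) {
    expect_equal(param_value(ps, e[1]), as.numeric(e[2]), label = e[1])
  }
  expect_equal(param_value(ps, "clinical.severity_split_is"),
               c(0.42, 0.26, 0.10, 0.22), ignore_attr = TRUE)

  # stroke-risk grid cells mirror the printed table (annual %, as fractions)
  g <- ps$tables$risk_grid
  expect_equal(g$subaf_none[g$chads2 == 3], 0.062)
  expect_equal(g$subaf_noac[g$chads2 == 3], 0.017)
  expect_equal(g$noaf_aspirin[g$chads2 == 2], 0.009)
  expect_equal(g$subaf_warfarin[g$chads2 == 6], 0.026)

  # the four ambiguous print cells carry a review marker
  flat <- flatten_parameters(ps)
  flagged <- flat$parameter[!is.na(flat$review) & flat$review == "ambiguous-in-print"]
  expect_setequal(flagged, c("economics.cost_holter", "economics.cost_ecg",
                             "economics.cost_aspirin_cycle",
                             "economics.cost_warfarin_cycle"))
})

test_that("missing uncertainty defaults to the fixed family", {
  tmp <- withr::local_tempdir()
  ps <- base_params()
  ps$economics$cost_noac_cycle <- structure(list(value = 118, dist = "fixed"),
                                            class = "icm_param")
  write_parameters(ps, tmp)
  re <- load_parameters(file.path(tmp, "bundle.yaml"))
  expect_identical(re$economics$cost_noac_cycle$dist, "fixed")
})

test_that("validation reports out-of-range values, broken simplexes and bad ses", {
  ps <- base_params()
  ps$treatment$noac_uptake$value <- 1.2
  v <- validate(ps)
  expect_true(any(grepl("noac_uptake", v$parameter) & grepl("probability", v$rule)))

  ps <- base_params()
  ps$clinical$severity_split_is$value <- c(0.42, 0.26, 0.10, 0.20)
  v <- validate(ps)
  expect_true(any(grepl("severity_split_is", v$parameter) & grepl("sum", v$rule)))

  ps <- base_params()
  ps$economics$cost_crnm$value <- -5
  expect_true(any(grepl("cost_crnm", validate(ps)$parameter)))

  # loading an invalid bundle aborts with the offending field named
  tmp <- withr::local_tempdir()
  bad <- base_params()
  bad$detection$device_sensitivity$value <- 1.2
  write_parameters(bad, tmp)
  expect_error(load_parameters(file.path(tmp, "bundle.yaml")),
               "device_sensitivity")
})

test_that("scenario overrides change exactly the named fields and re-validate", {
  ps <- base_params()
  sc <- scenario_spec("uptake", list("treatment.noac_uptake" = 0.6635))
  ps2 <- apply_overrides(ps, sc)
  expect_equal(param_value(ps2, "treatment.noac_uptake"), 0.6635)
  f1 <- flatten_parameters(ps); f2 <- flatten_parameters(ps2)
  changed <- f1$parameter[f1$value != f2$value]
  expect_identical(changed, "treatment.noac_uptake")

  expect_equal(flatten_parameters(apply_overrides(ps, scenario_spec("noop"))),
               flatten_parameters(ps))
  expect_error(apply_overrides(ps, list("economics.no_such_thing" = 1)),
               "economics.no_such_thing")
  expect_error(apply_overrides(ps, list("treatment.noac_uptake" = 2)), "validation")

  # battery override propagates into the detection schedule downstream
  ps3 <- apply_overrides(ps, list("detection.battery_years" = 4.5))
  expect_identical(build_schedule(ps3)$battery_cycles, 18)
})

test_that("write/load round-trips every parameter field", {
  tmp <- withr::local_tempdir()
  ps <- base_params()
  write_parameters(ps, tmp)
  re <- load_parameters(file.path(tmp, "bundle.yaml"))
  expect_equal(flatten_parameters(re), flatten_parameters(ps))
  expect_equal(re$tables$risk_grid, ps$tables$risk_grid)
  expect_equal(re$tables$life_table, ps$tables$life_table)
  expect_equal(re$tables$detection_curve$cumulative,
               ps$tables$detection_curve$cumulative)
})
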