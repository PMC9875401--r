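mock_outcome <- function(cost, qaly, ly, is1000,
                         cats = c(device_monitoring = cost, drugs = 0,
                                  is_events = 0, bleed_events = 0, post_stroke = 0)) {
  structure(list(
    discounted_cost_total = cost, cost_by_category = cats,
    undiscounted_cost_total = cost, undiscounted_cost_by_category = cats,
    qalys = qaly, undiscounted_qalys = qaly,
    life_years = ly, undiscounted_life_years = ly,
    is_events_per_1000 = is1000,
    strokes_by_severity = c(is_mild = 0, is_moderate = 0, is_severe = 0, is_fatal = 0),
    bleed_events_per_1000 = c(hs = 0, other_ich = 0, ech = 0, crnm = 0)
  ), class = "icm_strategy_outcome")
}

test_that("incremental comparison arithmetic, dominance and NNT rounding", {
  a <- mock_outcome(11000, 5.5, 7, 240)
  b <- mock_outcome(10000, 5.0, 6.8, 280)
  cmp <- compare_strategies(a, b)
  expect_equal(cmp$delta_cost, 1000)
  expect_equal(cmp$delta_qaly, 0.5)
  expect_equal(cmp$icer_per_qaly, 2000)
  expect_equal(cmp$icer_per_ly, 1000 / 0.2)
  expect_equal(cmp$is_avoided_per_1000, 40)
  expect_equal(cmp$nnt_per_stroke_avoided, 25L)
  expect_identical(cmp$dominance_flag, "none")

  dom <- compare_strategies(mock_outcome(9000, 5.5, 7, 240), b)
  expect_identical(dom$dominance_flag, "dominant")
  expect_true(is.na(dom$icer_per_qaly))

  same <- compare_strategies(b, b)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_true(is.na(same$icer_per_qaly))
  expect_true(is.na(same$nnt_per_stroke_avoided))

  expect_equal(nnt(34), 29L)
  expect_equal(nnt(1000), 1L)
  expect_equal(nnt(40), 25L)
  expect_true(is.na(nnt(0)))
})

test_that("ICER is invariant to per-1000 scaling of event counts", {
  a <- mock_outcome(11000, 5.5, 7, 240)
  b <- mock_outcome(10000, 5.0, 6.8, 280)
  a2 <- a; b2 <- b
  a2$is_events_per_1000 <- a$is_events_per_1000 / 1000
  b2$is_events_per_1000 <- b$is_events_per_1000 / 1000
  expect_equal(compare_strategies(a, b)$icer_per_qaly,
               compare_strategies(a2, b2)$icer_per_qaly)
  # per-patient strokes x 1000 match the per-1000 field in real runs
  res <- run_cea(toy_params(3))
  expect_equal(res$soc$is_events_per_1000, sum(res$soc$strokes_by_severity))
})

test_that("the cost breakdown table mirrors categories and sums to totals", {
  res <- run_cea(base_params())
  bd <- cost_breakdown_table(res$icm, res$soc)
  tot <- bd[bd$category == "total", ]
  expect_equal(tot$icm, sum(bd$icm[bd$category != "total"]))
  expect_equal(tot$soc, res$soc$discounted_cost_total)
  expect_equal(bd$difference, bd$icm - bd$soc)
  # improved detection trades stroke costs for bleed costs
  expect_lt(bd$icm[bd$category == "is_events"], bd$soc[bd$category == "is_events"])
  expect_gt(bd$icm[bd$category == "bleed_events"], bd$soc[bd$category == "bleed_events"])

  zero <- run_cea(zero_risk_params())
  bdz <- cost_breakdown_table(zero$icm, zero$soc)
  expect_equal(bdz$icm[bdz$category %in% c("is_events", "bleed_events", "post_stroke")],
               rep(0, 3))
})

test_that("result files are schema-complete and byte-identical across reruns", {
  ps <- toy_params(2)
  res <- run_cea(ps)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_results(res, ps, d1, seed = 7)
  m2 <- write_results(res, ps, d2, seed = 7)
  j1 <- jsonlite::read_json(file.path(d1, "results.json"))
  expect_true(all(c("icer_per_qaly", "icer_per_ly", "nnt_per_stroke_avoided") %in%
                    names(j1$comparison)))
  expect_identical(readLines(file.path(d1, "results.json")),
                   readLines(file.path(d2, "results.json")))
  expect_identical(readLines(file.path(d1, "breakdown.csv")),
                   readLines(file.path(d2, "breakdown.csv")))
  expect_identical(m1$bundle_hash, m2$bundle_hash)
  expect_true(all(c("results.json", "breakdown.csv") %in% unlist(m1$outputs)))
  expect_error(run_manifest("x", ps, outputs = "no/such/file.json"), "do not exist")
})

test_that("trace export writes one row per cycle and state", {
  mc <- build_model_context(toy_params(1))
  out <- run_strategy_stratum(mc, 3, "SoC")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(out$trace, mc$space, path)
  df <- read.csv(path)
  expect_identical(nrow(df), nrow(out$trace) * mc$space$n)
  expect_equal(sum(df$occupancy[df$cycle == 0]), 1)
})
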