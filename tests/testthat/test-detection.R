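test_that("logarithmic fit recovers coefficients and excludes the first cycle", {
  m <- seq(6, 30, by = 3)
  curve <- detection_curve(c(0, m), c(0, 0.10 * log(m) + 0.05))
  expect_equal(fit_log_extrapolation(curve), c(a = 0.10, b = 0.05), tolerance = 1e-10)

  # a wildly off-the-line month-3 point must not move the fit
  curve2 <- detection_curve(c(0, 3, m), c(0, 0.001, 0.10 * log(m) + 0.05))
  expect_equal(fit_log_extrapolation(curve2), c(a = 0.10, b = 0.05), tolerance = 1e-10)

  expect_error(fit_log_extrapolation(detection_curve(c(0, 3), c(0, 0.05))),
               "at least 2")
})

test_that("noisy log-curve fit matches a closed-form least-squares oracle", {
  set.seed(11)
  a <- 0.08; b <- 0.02; sd <- 0.005
  m <- seq(6, 30, by = 3)  # 9 points
  y <- a * log(m) + b + rnorm(length(m), 0, sd)
  y <- cummax(pmin(pmax(y, 0), 1))  # keep it a valid curve
  curve <- detection_curve(c(0, m), c(0, y))
  fit <- fit_log_extrapolation(curve)

  # normal-equation oracle, independent of lm()
  x <- log(m)
  a_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b_hat <- mean(y) - a_hat * mean(x)
  expect_equal(unname(fit["a"]), a_hat, tolerance = 1e-12)
  expect_equal(unname(fit["b"]), b_hat, tolerance = 1e-12)

  # and both recover the truth within 3 noise sd
  expect_lt(abs(fit["a"] - a), 3 * sd)
  expect_lt(abs(fit["b"] - b), 3 * sd)
})

test_that("linear extension appends the stated per-cycle increments, capped at 1", {
  curve <- detection_curve(c(0, 30), c(0, 0.40))
  ext <- extend_linear(curve, 0.039, 36)
  expect_equal(ext$cumulative, c(0, 0.40, 0.439, 0.478))
  expect_identical(extend_linear(curve, 0.039, 30), curve)  # no-op
  expect_equal(extend_linear(curve, 0, 36)$cumulative, c(0, 0.4, 0.4, 0.4))
  hi <- detection_curve(c(0, 30), c(0, 0.99))
  expect_equal(max(extend_linear(hi, 0.039, 36)$cumulative), 1)
})

test_that("underlying incidence is the detected curve over sensitivity", {
  curve <- detection_curve(c(0, 3), c(0, 0.40))
  expect_equal(derive_incidence(curve, 0.961)$cumulative[2], 0.40 / 0.961)
  expect_equal(derive_incidence(curve, 1)$cumulative, curve$cumulative)
  expect_equal(derive_incidence(detection_curve(c(0, 3), c(0, 0.98)), 0.961)$cumulative[2], 1)
  expect_error(derive_incidence(curve, 0), "sensitivity")
})

test_that("conditional probabilities round-trip the cumulative curve", {
  expect_equal(cumulative_to_conditional(detection_curve(c(0, 3, 6), c(0, 0.10, 0.19))),
               c(0.10, 0.10))
  expect_equal(cumulative_to_conditional(detection_curve(c(0, 3, 6), c(0, 0, 0))),
               c(0, 0))
  set.seed(7)
  for (i in 1:20) {
    C <- cummax(c(0, sort(runif(8, 0, 0.9))))
    curve <- detection_curve(seq(0, by = 3, length.out = 9), C)
    q <- cumulative_to_conditional(curve)
    expect_equal(conditional_to_cumulative(q)$cumulative, C, tolerance = 1e-12)
  }
})

test_that("hazard-ratio scaling of detection behaves as a hazard transform", {
  expect_equal(soc_hazard_from_hr(0.039, 33.9), 1 - exp(log(1 - 0.039) / 33.9))
  expect_equal(round(soc_hazard_from_hr(0.039, 33.9), 6), 0.001173)
  expect_equal(soc_hazard_from_hr(0.25, 1), 0.25)
  expect_equal(soc_hazard_from_hr(0, 5), 0)
  expect_error(soc_hazard_from_hr(1, 5), "degenerate")
  expect_error(soc_hazard_from_hr(0.1, 0), "positive")
})

test_that("the full schedule respects battery life, ordering and extrapolation variants", {
  ps <- base_params()
  sch <- build_schedule(ps)
  expect_identical(sch$battery_cycles, 12)
  expect_true(all(sch$battery_active[1:12]) && !any(sch$battery_active[-(1:12)]))

  sch45 <- build_schedule(apply_overrides(ps, list("detection.battery_years" = 4.5)))
  expect_identical(sch45$battery_cycles, 18)

  # SoC never detects faster than ICM; incidence dominates detection
  q_icm <- sch$per_cycle_conditional_detection_icm
  q_soc <- sch$per_cycle_conditional_detection_soc
  expect_true(all(q_soc <= q_icm + 1e-12))
  expect_true(all(sch$cumulative_incidence >= sch$cumulative_detected_icm - 1e-12))
  expect_true(all(q_icm >= 0 & q_icm <= 1 & q_soc >= 0 & q_soc <= 1))
  expect_true(all(sch$per_cycle_af_incidence >= 0 & sch$per_cycle_af_incidence <= 1))

  # no extrapolation: AF accrual flat after the 30-month trial data
  sch0 <- build_schedule(ps, extrapolation = "none")
  expect_true(all(sch0$per_cycle_af_incidence[11:sch0$n_cycles] == 0))
  expect_error(build_schedule(ps, extrapolation = "spline"), "unknown extrapolation")

  # under the base logarithmic variant accrual continues to battery end
  expect_gt(sch$cumulative_incidence[12], sch0$cumulative_incidence[12])
  expect_equal(sch$cumulative_incidence[13], sch$cumulative_incidence[12 + 8])
})

test_that("device removal hazard converts the annual rate to cycle scale", {
  ps <- base_params()
  sch <- build_schedule(ps)
  expect_equal(sch$removal_hazard_per_cycle, 1 - (1 - 0.029)^0.25)
  s <- sch$device_surviving_start
  expect_equal(s[1], 1)
  expect_true(all(diff(s[1:12]) < 0))
  expect_true(all(s[13:sch$n_cycles] == 0))
})
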