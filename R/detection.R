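#' @title AF detection curves and per-cycle detection schedules
#' @description Builds per-cycle AF incidence and first-detection
#'   probabilities for the ICM and SoC strategies from one cumulative
#'   ICM detection curve: extrapolation beyond trial follow-up
#'   (logarithmic fit, linear rate, or none), device sensitivity,
#'   battery expiry and unplanned device removal.
#' @name detection
#' @keywords internal
NULL

#' Cumulative AF-detection curve
#'
#' @param month Ordered months (multiples of the cycle length, starting at 0).
#' @param cumulative Nondecreasing cumulative detection probabilities in \[0,1\].
#' @return Object of class `detection_curve`.
#' @export
detection_curve <- function(month, cumulative) {
  stopifnot(length(month) == length(cumulative))
  o <- order(month)
  month <- month[o]; cumulative <- cumulative[o]
  if (month[1] != 0 || cumulative[1] != 0) {
    stop("detection curve must start at (month 0, cumulative 0)")
  }
  if (any(diff(cumulative) < -1e-12)) stop("cumulative detection must be nondecreasing")
  if (any(cumulative < 0 | cumulative > 1)) stop("cumulative detection outside [0, 1]")
  structure(list(month = month, cumulative = cumulative), class = "detection_curve")
}

#' Fit the logarithmic extrapolation of a detection curve
#'
#' Least-squares fit of `cumulative = a * log(month) + b` over the curve
#' points with month strictly greater than 3 (the first cycle is
#' excluded as unrepresentative of the long-run detection process).
#'
#' @param curve A `detection_curve`.
#' @return Named vector `c(a, b)`.
#' @export
fit_log_extrapolation <- function(curve) {
  keep <- curve$month > 3
  if (sum(keep) < 2L) stop("need at least 2 points with month > 3 to fit")
  m <- curve$month[keep]; y <- curve$cumulative[keep]
  fit <- stats::lm(y ~ log(m))
  c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
}

#' Extend a detection curve linearly
#'
#' Appends cycles that increase the cumulative probability by a fixed
#' amount per cycle, capped at 1.
#'
#' @param curve A `detection_curve`.
#' @param rate_per_cycle Absolute cumulative increase per appended cycle.
#' @param to_month Target final month; a no-op if not beyond the curve.
#' @param cycle_months Cycle length in months (default 3).
#' @return A `detection_curve`.
#' @export
extend_linear <- function(curve, rate_per_cycle, to_month, cycle_months = 3) {
  stopifnot(rate_per_cycle >= 0, rate_per_cycle <= 1)
  last <- max(curve$month)
  if (to_month <= last) return(curve)
  new_months <- seq(last + cycle_months, to_month, by = cycle_months)
  add <- pmin(1, curve$cumulative[length(curve$cumulative)] +
                rate_per_cycle * seq_along(new_months))
  detection_curve(c(curve$month, new_months), c(curve$cumulative, add))
}

#' Extend a detection curve with a fitted logarithmic tail
#'
#' @inheritParams extend_linear
#' @param coef Optional `c(a, b)` from [fit_log_extrapolation()];
#'   fitted from the curve when missing.
#' @return A `detection_curve`; appended values are clamped to remain
#'   monotone and within \[0,1\].
#' @export
extend_logarithmic <- function(curve, to_month, coef = NULL, cycle_months = 3) {
  last <- max(curve$month)
  if (to_month <= last) return(curve)
  if (is.null(coef)) coef <- fit_log_extrapolation(curve)
  new_months <- seq(last + cycle_months, to_month, by = cycle_months)
  pred <- coef[["a"]] * log(new_months) + coef[["b"]]
  out_c <- curve$cumulative
  for (p in pred) out_c <- c(out_c, min(1, max(p, out_c[length(out_c)])))
  detection_curve(c(curve$month, new_months), out_c)
}

#' Extend a detection curve flat (no further detection)
#' @inheritParams extend_linear
#' @return A `detection_curve`.
#' @export
extend_flat <- function(curve, to_month, cycle_months = 3) {
  extend_linear(curve, 0, to_month, cycle_months)
}

#' Underlying AF incidence from a detected curve
#'
#' The device misses a fraction of AF, so the underlying cumulative AF
#' incidence is the detected cumulative divided by device sensitivity,
#' capped at 1.
#'
#' @param icm_curve Detected cumulative curve (ICM).
#' @param sensitivity Device sensitivity in (0, 1\].
#' @return A `detection_curve` holding the incidence curve.
#' @export
derive_incidence <- function(icm_curve, sensitivity) {
  if (sensitivity <= 0 || sensitivity > 1) stop("sensitivity must be in (0, 1]")
  detection_curve(icm_curve$month, pmin(1, icm_curve$cumulative / sensitivity))
}

#' Per-cycle conditional probabilities from a cumulative curve
#'
#' `q_t = (C_t - C_{t-1}) / (1 - C_{t-1})`, with the conditional defined
#' as 0 once the cumulative reaches 1.
#'
#' @param curve A `detection_curve`.
#' @return Numeric vector, one probability per interval.
#' @export
cumulative_to_conditional <- function(curve) {
  C <- curve$cumulative
  prev <- C[-length(C)]
  ifelse(prev >= 1, 0, (C[-1] - prev) / (1 - prev))
}

#' Rebuild a cumulative curve from per-cycle conditionals
#' @param q Per-cycle conditional probabilities.
#' @param month Months for the rebuilt curve (length `length(q) + 1`,
#'   starting at 0); defaults to 3-month cycles.
#' @return A `detection_curve`.
#' @export
conditional_to_cumulative <- function(q, month = seq(0, by = 3, length.out = length(q) + 1)) {
  C <- cumsum(c(0, q * c(1, cumprod(1 - q))[seq_along(q)]))
  detection_curve(month, pmin(1, C))
}

#' Scale a conditional detection probability by a hazard ratio
#'
#' Converts the per-cycle conditional probability to a hazard
#' `h = -log(1 - q)`, divides by the hazard ratio, and converts back:
#' `1 - exp(-h / hr)`. Used to derive SoC detection from ICM detection.
#'
#' @param icm_conditional Per-cycle conditional probability (vectorised).
#' @param hr Hazard ratio (> 0) of ICM relative to SoC.
#' @return Per-cycle conditional probability for SoC.
#' @export
soc_hazard_from_hr <- function(icm_conditional, hr) {
  if (hr <= 0) stop("hazard ratio must be positive")
  if (any(icm_conditional >= 1)) stop("conditional probability of 1 is degenerate under hazard scaling")
  if (any(icm_conditional < 0)) stop("conditional probability below 0")
  1 - exp(log(1 - icm_conditional) / hr)
}

#' Build the full-horizon detection schedule
#'
#' From the trial-period ICM cumulative detection curve the schedule
#' derives, per 3-month cycle over the whole model horizon:
#' \itemize{
#'   \item the underlying conditional AF incidence (detected curve /
#'     device sensitivity),
#'   \item the conditional first-detection probability among patients
#'     with undetected AF, for an active ICM and for SoC (ICM hazard
#'     scaled down by the ICM-vs-SoC hazard ratio),
#'   \item battery-active flags and the surviving-device fraction under
#'     the unplanned-removal hazard; beyond battery expiry (or after
#'     removal) the ICM arm uses the SoC detection probability of the
#'     same calendar cycle.
#' }
#'
#' @param params An `icm_params` object.
#' @param icm_curve Optional `detection_curve`; defaults to the bundle's.
#' @param extrapolation `"logarithmic"`, `"linear"` or `"none"`;
#'   defaults to the bundle's `detection.extrapolation` setting.
#' @param n_cycles Number of model cycles to cover; defaults to the
#'   lifetime horizon implied by the bundle's terminal age.
#' @return A list of class `detection_schedule`.
#' @export
build_schedule <- function(params, icm_curve = NULL, extrapolation = NULL,
                           n_cycles = NULL) {
  cm <- param_value(params, "structural.cycle_months")
  if (is.null(icm_curve)) icm_curve <- params$tables$detection_curve
  if (is.null(icm_curve)) stop("no detection curve available")
  if (max(icm_curve$month) < 30) stop("detection curve must cover the 30-month trial follow-up")
  if (is.null(extrapolation)) extrapolation <- param_value(params, "detection.extrapolation")
  if (is.null(n_cycles)) {
    span <- param_value(params, "structural.terminal_age") -
      param_value(params, "structural.baseline_age")
    n_cycles <- ceiling(span * 12 / cm) + 1L
  }
  horizon_month <- n_cycles * cm
  battery_cycles <- round(param_value(params, "detection.battery_years") * 12 / cm)

  # AF accrual is extrapolated from the end of trial follow-up to the end
  # of the battery life, and held flat thereafter (under "none" it is
  # held flat straight after the trial data).
  ext_month <- min(max(max(icm_curve$month), battery_cycles * cm), horizon_month)
  ext <- switch(extrapolation,
    logarithmic = extend_logarithmic(icm_curve, ext_month, cycle_months = cm),
    linear = extend_linear(icm_curve,
                           param_value(params, "detection.linear_rate_per_cycle"),
                           ext_month, cycle_months = cm),
    none = icm_curve,
    stop("unknown extrapolation variant: ", extrapolation)
  )
  ext <- extend_flat(ext, horizon_month, cycle_months = cm)

  sens <- param_value(params, "detection.device_sensitivity")
  incidence <- derive_incidence(ext, sens)
  C <- ext$cumulative          # cumulative detected (ICM, device always on)
  I <- incidence$cumulative    # cumulative underlying AF
  # SoC detection: the same underlying AF, found at a hazard 1/hr of the
  # ICM's on the cumulative time-to-first-detection scale.
  hr <- param_value(params, "detection.hr_icm_vs_soc")
  Cs <- soc_hazard_from_hr(pmin(C, 1 - 1e-12), hr) *
    param_value(params, "detection.soc_detection_scale")

  n <- n_cycles
  p_inc <- cumulative_to_conditional(incidence)[seq_len(n)]
  # conditional detection among patients with undetected AF: the newly
  # detected mass over the pool that has AF but no detection yet in that
  # arm (incidence within the cycle is detectable in the same cycle).
  cond_pool <- function(Cd) {
    pool <- I[-1] - Cd[-length(Cd)]
    ifelse(pool <= 1e-12, 0,
           pmin(1, pmax(0, (Cd[-1] - Cd[-length(Cd)]) / pool)))[seq_len(n)]
  }
  q_icm <- cond_pool(C)
  q_soc <- cond_pool(Cs)
  battery_active <- seq_len(n) <= battery_cycles
  removal_cycle <- 1 - (1 - param_value(params, "detection.unplanned_removal_annual"))^(cm / 12)
  # device surviving at the start of each cycle (insertion at cycle 0)
  s_start <- ifelse(battery_active, (1 - removal_cycle)^(seq_len(n) - 1L), 0)
  s_end <- ifelse(battery_active, (1 - removal_cycle)^seq_len(n), 0)

  structure(list(
    n_cycles = n, cycle_months = cm,
    per_cycle_af_incidence = p_inc,
    per_cycle_conditional_detection_icm = q_icm,
    per_cycle_conditional_detection_soc = q_soc,
    battery_active = battery_active,
    battery_cycles = battery_cycles,
    removal_hazard_per_cycle = removal_cycle,
    device_surviving_start = s_start,
    device_surviving_end = s_end,
    cumulative_detected_icm = C[seq_len(n) + 1L],
    cumulative_incidence = I[seq_len(n) + 1L],
    extrapolation = extrapolation
  ), class = "detection_schedule")
}

#' Effective ICM-arm conditional detection probability per cycle
#'
#' Blends active-device and SoC detection by the surviving-device
#' fraction: after battery expiry or unplanned removal, undiagnosed
#' patients revert to the SoC detection probability of the same
#' calendar cycle.
#'
#' @param schedule A `detection_schedule`.
#' @return Numeric vector of per-cycle conditional probabilities.
#' @export
effective_icm_detection <- function(schedule) {
  s <- schedule$device_surviving_start
  s * schedule$per_cycle_conditional_detection_icm +
    (1 - s) * schedule$per_cycle_conditional_detection_soc
}
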