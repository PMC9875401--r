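#' @title Per-cycle event risks
#' @description Converts annual, stratified event risks into per-cycle
#'   transition probabilities: ischemic stroke (by CHADS2 score, AF
#'   status, treatment, age), stroke severity, bleeding events under
#'   anticoagulation, anticoagulant discontinuation rules, and
#'   cerebrovascular-deleted background mortality.
#' @name risks
#' @keywords internal
NULL

#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion `1 - (1 - p)^(1 / cycles_per_year)`;
#' compounding the result over a year reproduces the annual probability.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param cycles_per_year Number of model cycles per year (default 4).
#' @return Per-cycle probability (vectorised).
#' @export
annual_to_cycle <- function(p_annual, cycles_per_year = 4) {
  if (any(p_annual < 0 | p_annual > 1)) stop("annual probability outside [0, 1]")
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Per-cycle ischemic stroke probability for a risk context
#'
#' Grid lookup by CHADS2 score, AF status and treatment, adjusted by
#' the per-decade age factor relative to the cohort baseline age, then
#' converted from annual to cycle scale and capped at 1.
#'
#' @param chads2 Integer CHADS2 score present in the grid.
#' @param af_status `"noAF"` or `"subclinicalAF"`.
#' @param treatment `"none"`, `"aspirin"`, `"noac"` or `"warfarin"`.
#'   A paused NOAC course carries aspirin-level stroke risk.
#' @param age Current cohort age in years.
#' @param params An `icm_params` object.
#' @return Per-cycle probability.
#' @export
is_probability <- function(chads2, af_status, treatment, age, params) {
  grid <- params$tables$risk_grid
  row <- grid[grid$chads2 == chads2, ]
  if (nrow(row) != 1L) stop("CHADS2 score not in risk grid: ", chads2)
  col <- switch(af_status,
    noAF = switch(treatment, none = "noaf_none", aspirin = "noaf_aspirin",
                  stop("no-AF patients can only be untreated or on aspirin")),
    subclinicalAF = switch(treatment, none = "subaf_none", aspirin = "subaf_aspirin",
                           noac = "subaf_noac", warfarin = "subaf_warfarin",
                           stop("unknown treatment: ", treatment)),
    stop("unknown AF status: ", af_status))
  annual <- row[[col]] * age_adjustment(age, params)
  annual_to_cycle(min(annual, 1), 12 / param_value(params, "structural.cycle_months"))
}

#' @noRd
age_adjustment <- function(age, params) {
  param_value(params, "clinical.age_adjust_per_decade")^(
    (age - param_value(params, "structural.baseline_age")) / 10)
}

#' Split a stroke probability by severity
#'
#' Proportional allocation over (mild, moderate, severe, fatal); the
#' outputs sum back to the input probability.
#'
#' @param p_is Per-cycle stroke probability.
#' @param split Length-4 severity simplex.
#' @return Named length-4 vector.
#' @export
split_severity <- function(p_is, split) {
  if (length(split) != 4L || abs(sum(split) - 1) > 1e-6) {
    stop("severity split must be 4 probabilities summing to 1")
  }
  stats::setNames(p_is * split, c("mild", "moderate", "severe", "fatal"))
}

#' Per-cycle bleeding probabilities for a treatment
#'
#' Returns hemorrhagic stroke, other intracranial hemorrhage,
#' extracranial hemorrhage and clinically-relevant non-major bleed
#' probabilities from the parameter bundle's annual rates for the
#' treatment class, weighted by age and converted to the cycle scale.
#' A paused NOAC course carries untreated-level bleeding risk.
#'
#' @param treatment `"none"`, `"aspirin"`, `"noac"`, `"paused"` or `"warfarin"`.
#' @param age Current cohort age in years.
#' @param params An `icm_params` object.
#' @return Named vector `c(hs, other_ich, ech, crnm)` of per-cycle probabilities.
#' @export
bleed_probabilities <- function(treatment, age, params) {
  class_ <- if (treatment == "paused") "none" else treatment
  br <- params$clinical$bleed_risks[[class_]]
  if (is.null(br)) stop("no bleed risks for treatment class: ", class_)
  w <- param_value(params, "clinical.bleed_age_factor_per_decade")^(
    (age - param_value(params, "structural.baseline_age")) / 10)
  annual <- pmin(c(hs = br$hs$value, other_ich = br$other_ich$value,
                   ech = br$ech$value, crnm = br$crnm$value) * w, 1)
  annual_to_cycle(annual, 12 / param_value(params, "structural.cycle_months"))
}

#' Anticoagulant discontinuation rule after a bleeding event
#'
#' Returns the probability split over outcomes for a patient
#' experiencing the event: extracranial hemorrhage on OAC pauses
#' therapy for one cycle in 75% and stops it permanently in 25%; other
#' intracranial hemorrhage pauses in 44% and stops in 56%; hemorrhagic
#' stroke always stops permanently and bars all patients from future
#' OAC; CRNM bleeds never interrupt therapy. Patients not on OAC at an
#' ECH/ICH are barred from future OAC with probability 0.25/0.56.
#'
#' @param event `"ECH"`, `"otherICH"`, `"HS"`, `"CRNM"` or `"none"`.
#' @param on_oac Is the patient currently on (or paused from) OAC therapy?
#' @param params An `icm_params` object.
#' @return Named probabilities over
#'   `c(continue, pause, stop_permanent, barred_future)`; `barred_future`
#'   applies to patients not on OAC (state unchanged, future OAC barred).
#' @export
discontinuation_outcome <- function(event, on_oac, params) {
  p <- c(continue = 0, pause = 0, stop_permanent = 0, barred_future = 0)
  tmp <- function(path) param_value(params, path)
  if (event == "none" || event == "CRNM") {
    p["continue"] <- 1
  } else if (event == "HS") {
    if (on_oac) p["stop_permanent"] <- 1 else p["barred_future"] <- 1
  } else if (event == "ECH") {
    if (on_oac) {
      p["pause"] <- tmp("treatment.ech_temporary_share")
      p["stop_permanent"] <- 1 - p["pause"]
    } else {
      p["barred_future"] <- tmp("treatment.ech_barred_share")
      p["continue"] <- 1 - p["barred_future"]
    }
  } else if (event == "otherICH") {
    if (on_oac) {
      p["pause"] <- tmp("treatment.ich_temporary_share")
      p["stop_permanent"] <- 1 - p["pause"]
    } else {
      p["barred_future"] <- tmp("treatment.ich_barred_share")
      p["continue"] <- 1 - p["barred_future"]
    }
  } else stop("unknown event: ", event)
  p
}

#' Per-cycle background (non-cerebrovascular) death probability
#'
#' Life-table annual probability at the (floored) age, converted to the
#' cycle scale, multiplied by the post-stroke severity multiplier and
#' the anticoagulation-treatment factor. Ages beyond the table absorb
#' to probability 1 (terminal age).
#'
#' @param age Age in years.
#' @param health_state `"event_free"`, `"post_mild"`, `"post_moderate"`
#'   or `"post_severe"`.
#' @param treatment Current treatment class (for the mortality factor).
#' @param params An `icm_params` object.
#' @return Per-cycle probability.
#' @export
background_mortality <- function(age, health_state, treatment, params) {
  qx <- life_table_qx(age, params)
  mult <- if (health_state == "event_free") 1 else
    param_value(params, paste0("clinical.post_stroke_mortality_multiplier.",
                               sub("^post_", "", health_state)))
  fac <- param_value(params, paste0("clinical.post_stroke_mortality_treatment_factor.",
                                    treatment))
  if (health_state == "event_free") fac <- 1
  min(1, annual_to_cycle(min(1, qx),
                         12 / param_value(params, "structural.cycle_months")) * mult * fac)
}

#' @noRd
life_table_qx <- function(age, params) {
  lt <- params$tables$life_table
  if (age >= max(lt$age)) return(1)
  a <- floor(age)
  i <- findInterval(a, lt$age)
  if (i < 1L) stop("age below life-table range: ", age)
  lt$qx[i]
}
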