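---
title: "A lifetime Markov cohort model of insertable cardiac monitoring for atrial fibrillation detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cohort model of insertable cardiac monitoring for atrial fibrillation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmcea)
```

## The decision problem

Subclinical atrial fibrillation (AF) raises ischemic stroke (IS) risk, and
oral anticoagulation with a NOAC reduces that risk — but only once AF has
actually been diagnosed, and at the price of bleeding. An insertable
cardiac monitor (ICM) watches the rhythm continuously for the life of its
battery and therefore finds AF far sooner than standard of care (SoC:
occasional 24-h Holters and ECGs). `icmcea` asks whether, for a US cohort
at high stroke risk (CHADS2 ≥ 2, mean age 71.3, 73% on aspirin), paying
for the device and for the earlier anticoagulation it triggers is good
value per quality-adjusted life year (QALY).

The model is a discrete-time Markov cohort model with 3-month cycles run
to a terminal age of 100. Both strategies face the same underlying AF
incidence; they differ only in how fast AF is found, in monitoring costs,
and in everything downstream of a diagnosis.

## State space

States are factored tuples

> AF status (none / subclinical) × diagnosed × treatment
> (none / aspirin / NOAC / NOAC-paused / warfarin) × barred-from-OAC flag
> × health state (event-free / post-mild / post-moderate / post-severe)

plus one absorbing Dead state — 61 states after removing invalid tuples
(diagnosis implies AF; OAC implies diagnosis and an unbarred patient).
The cohort starts event-free, undiagnosed and AF-free, split 73%/27%
between aspirin and no therapy. The cohort's 20% prior-stroke share is
deliberately *not* seeded into post-stroke states: prior stroke already
enters through the CHADS2 score (where it counts double), and seeding it
would attach the heavy post-stroke cost stream to history the model does
not otherwise represent. `structural.prior_stroke_share` is retained in
the bundle as a population descriptor only.

Each cycle chains five stages, in this order: AF incidence → detection
(NOAC starts in the same cycle as diagnosis) → background death →
mutually exclusive clinical events → background OAC discontinuation. The
composition of the five stages is exposed as a single row-stochastic
matrix by `build_transition_matrix()` and checked to 1e-9; the
accumulation path uses the stage-resolved flows so that event costs and
disutilities attach to the transition that caused them.

## Detection machinery

One input curve drives everything: the cumulative fraction of the cohort
with ICM-detected AF over the 30 months of trial follow-up. From it:

* **Underlying incidence.** The device misses episodes with probability
  `1 − 0.961`, so cumulative AF incidence is the detected curve divided
  by the device sensitivity (capped at 1).
* **SoC detection.** The relative diagnostic yield of ICM over SoC is a
  hazard ratio of 33.9 (95% CI lower bound 13.2), applied on the
  cumulative time-to-first-detection scale:
  `C_soc = 1 − (1 − C_icm)^(1/33.9)`. Applying the ratio to the
  per-cycle conditional probability *among prevalent AF* instead would
  let SoC find ~9% of standing AF per cycle, which contradicts the
  few-percent 30-month SoC yield the trial comparison reports; the
  cumulative-scale reading reproduces it.
* **Per-cycle conditionals.** Both cumulative curves are converted to
  conditional detection probabilities against the pool that has AF but
  no diagnosis yet in that arm, so the cohort reproduces the curves
  exactly in the absence of differential mortality.
* **Extrapolation.** Beyond month 30 the curve is extended to the end of
  the battery life by a logarithmic fit `a·ln(month) + b` over the
  points after month 3 (the default, declared in the bundle as
  `detection.extrapolation`), or by a linear 3.9%-per-cycle rule, or not
  at all — and held flat afterwards. Holding accrual flat beyond the
  battery is what keeps the "no extrapolation" scenario a moderate
  rather than radical departure, matching how the scenario behaves in
  the source analysis.
* **Battery and removal.** The battery lasts 3 years (4.5 in scenario);
  unplanned removal occurs at 2.9%/year. Both are handled in
  expectation: the surviving-device fraction blends active-ICM and SoC
  detection for the ICM arm and scales device monitoring costs, which is
  exact for linear payoffs and avoids doubling the state space.

## Risks

* **Ischemic stroke.** Annual probabilities come from a CHADS2 (0–6) ×
  AF-status × treatment grid shipped as CSV; rows 0–1 are stored but the
  simulated population is CHADS2 ≥ 2. Risk is multiplied by
  1.46^((age − 71.3)/10) as the cohort ages, converted to cycle scale by
  `1 − (1 − p)^(1/4)`, and split 42/26/10/22% over
  mild/moderate/severe/fatal. CHADS2 strata are run as separate cohorts
  and aggregated by the bundle's score mix (mean 2.94).
* **Bleeds.** Hemorrhagic stroke (HS), other intracranial hemorrhage
  (ICH), extracranial hemorrhage (ECH, split GI/other for costing) and
  clinically relevant non-major (CRNM) bleeds occur at annual rates per
  treatment class, age-weighted per decade. HS severity reuses the
  stroke severity split.
* **Discontinuation.** ECH on OAC: 75% pause / 25% permanent stop; other
  ICH: 44%/56%; HS: permanent stop and a lifetime bar from OAC for
  everyone; CRNM: continue. Patients not on OAC at an ECH/ICH are barred
  with probability 0.25/0.56. A further 14.8%/year stop NOAC for
  non-bleed reasons. The 6-week pause is modelled as one full cycle in a
  tunnel state with aspirin-level stroke risk and untreated-level bleed
  risk, returning to the OAC the next cycle — the 3-month cycle cannot
  resolve 6 weeks. Patients who stop OAC permanently move to aspirin.
* **Mortality.** A life table (cerebrovascular-deleted) gives background
  death; post-stroke states multiply it by severity- and
  treatment-specific factors. Fatal strokes are modelled directly as
  event severities.
* **Competing risks.** Background death is applied first; the remaining
  event probabilities are treated as mutually exclusive and rescaled
  proportionally only if they sum above 1.

## Payoffs and discounting

State utilities (baseline 0.81; −0.014 while AF is present; 0.76 / 0.45
/ 0.34 in post-stroke states) accrue on end-of-cycle occupancy at 0.25
years per cycle, with no half-cycle correction — the source model is a
spreadsheet cohort model and the uncorrected convention is the natural
match. The acute cycle of a stroke replaces the destination state's
utility with the acute value (0.76 / 0.39 / 0.11), recurrent strokes add
a −0.150 acute decrement and move the patient to the worse of the
current and new severity states, and bleeds cost −0.181 for one cycle.
Event costs attach to flows in the cycle of occurrence; fatal events
carry the fatal event cost and no further utility. One-time ICM
insertion ($7042) is paid at cycle 0 and removal ($738) at unplanned or
battery-expiry explant. Costs and QALYs are discounted at 3%/year with
end-of-cycle factors `1.03^(−t/4)`; horizon scenarios truncate
accumulation at 5/10/25 years.

One printed input is stored but not applied: the −0.068 *post-acute*
recurrent-stroke decrement would require a persistent "has recurred"
state dimension; it is flagged in the bundle and listed under
limitations.

## Parameters, uncertainty and the PSA

Every scalar input lives in a YAML bundle with value, standard error (or
log-sd), distribution family, source tag and an optional review marker;
`flatten_parameters()` exports the provenance table. Four cells of the
printed cost table have ambiguous digit grouping (Holter $102/SE 16, ECG
$27.5/SE 4, aspirin $5/cycle, warfarin $18/cycle) and are flagged
`ambiguous-in-print`. Costs with no printed SE use the declared ±30%
interval convention, SE = 0.30·mean/1.96.

The PSA draws every non-fixed parameter jointly: beta (moment-matched)
for probabilities and utilities, gamma for costs, lognormal for ratios.
The detection hazard ratio's upper interval is not estimable, so its
log-sd comes from the lower bound alone (log-symmetric,
sd = ln(33.9/13.2)/1.96 ≈ 0.48) with a median-preserving location. Drawn
relative risks rescale the stroke-risk grid's subclinical columns
multiplicatively, which preserves the printed base grid exactly at the
central values. The mean ICER is the ratio of mean increments — per-draw
ICER ratios are unstable near ΔQALY = 0 and are stored but never
averaged. Failed draws are skipped and counted. n = 1000 by default.

## Synthetic stand-ins

Several calibration inputs of the source analysis are only published in
supplementary material that this package does not ship. They are
replaced by clearly labelled synthetic stand-ins, chosen once for
plausibility and frozen:

* **Life table** (`life_table_synthetic.csv`): Gompertz–Makeham
  `q(x) = 0.002 + 2×10⁻⁵·e^{0.1x}`, giving ~13.4 residual years at age
  71.3 — between the general-population value and what a multimorbid
  CHADS2 ≥ 2 cohort would see. The real cause-deleted table drops in
  through the same two-column CSV.
* **Detection curves**: the all-patient curve follows
  `0.155·ln(m) − 0.125` (≈ 40% at 30 months, mean slope 3.9%/cycle over
  months 3–30, matching the published anchors); the 5.5-h-episode
  variant is half of it; the heart-failure curve is steeper, reaching
  ~44% at 3 years. All are marked replaceable.
* **Bleed rates, age weights, post-stroke mortality multipliers,
  CHADS2 mix, GI share**: set to literature-typical magnitudes
  (bundle entries carry `review: synthetic`).

Because these stand-ins are not the authors' values, the model's
*absolute* levels differ from the published table (see the README): the
packaged inputs give more lifetime strokes and heavier post-stroke cost
streams, hence a lower base-case ICER. What the passing test suite does
show is that the machinery is right: occupancy is conserved to 1e-10,
the cohort algebra matches an independent patient-level microsimulation
within Monte-Carlo error, a point-mass PSA collapses onto the
deterministic run, equalising detection and monitoring nulls the
increments exactly, and every scenario moves the ICER in the published
direction. What it does not show is agreement with real-world cost and
event levels — that requires the genuine supplementary inputs.

## Numerical choices

* Cycle kernels are precomputed per CHADS2 stratum across all cycles and
  shared between arms; a full two-arm lifetime evaluation takes well
  under a second, a 1000-draw PSA a few minutes on one CPU.
* Propagation stops once the alive fraction drops below 1e-6 (the
  terminal-age absorption reaches it first in practice).
* Degenerate guards: conditional detection is 0 once a cumulative curve
  reaches 1; hazard scaling rejects q = 1; beta moment-matching aborts,
  naming the parameter, when SE² ≥ mean·(1 − mean).
* Validation test sizes: the microsimulation oracle uses a 12-cycle
  configuration with 30,000–50,000 patients (3 Monte-Carlo SEs); trial
  convergence uses 10⁵ patients; PSA property tests use 30–60 draws.

## Known limitations

* Post-acute recurrent-stroke disutility not applied (above).
* CHADS2 subgroups share the all-patient detection curve, so
  subgroup-specific detection differences (which drive the published
  counterintuitive CHADS2 4–6 result) are out of scope.
* No half-cycle correction (convention choice, documented above).
* AF, once incident, is permanent; AF burden/duration is represented
  only by swapping the input curve (6-min vs 5.5-h definitions).
* Device removal and battery expiry are expectations, not states; exact
  only for linear payoffs, which all payoffs here are.
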