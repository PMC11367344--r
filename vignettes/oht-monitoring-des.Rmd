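---
title: "Modelling OHT monitoring strategies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling OHT monitoring strategies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohtsim)
```

This vignette is the package's own account of its science: the model and its
assumptions, the parameters that matter and why their defaults look the way
they do, what the synthetic cohort does and does not emulate, and the main
numerical and design choices. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The decision problem

Ocular hypertension (raised intraocular pressure without glaucomatous damage)
is mostly asymptomatic, but unchecked it can convert to open-angle glaucoma
and progress to visual impairment. IOP is the only modifiable risk factor.
In a UK-style pathway, a secondary-care professional decides at diagnosis
whether to start IOP-lowering treatment; untreated patients are monitored
annually in primary care. We compare two initiation rules on lifetime
discounted costs (NHS perspective) and QALYs:

* **Standard care**: a decision table over IOP, age and CCT bands
  (`sc_decision_table()`), exhaustive by construction with a first-match-wins
  semantics.
* **Risk prediction**: treat when the calculator's 5-year conversion risk is
  ≥ 6% (`five_year_risk()`, `treat_decision_rp()`).

## Model structure

The engine (`simulate_patient()`, `run_strategy()`) is a continuous-time,
event-driven patient-level simulation. At every iteration exactly one of
three clocks fires — next check-up, next natural-history event, or death —
whichever is earliest. Between events nothing changes except the continuous
accrual of utility (at the *true* disease stage) and of annual medication
cost, both discounted with the continuous factor `exp(-ρt)`,
`ρ = log(1 + 0.035)`. Costs of visits and procedures are charged at event
times.

Key structural assumptions:

* **True vs observed state.** Conversion happens at the sampled event time
  but is acted on only when a check-up observes it; the engine stores both.
  Utility attaches to the true stage (vision loss lowers quality of life
  whether or not it has been measured yet). A configuration flip is not
  offered for this: the observed-stage alternative would make QALYs depend
  on monitoring frequency in a way the utility evidence does not support.
* **Perfect tests.** Check-ups observe the true state without error, so the
  "negative assessment, return to primary care" path of the referral logic
  is structurally present but unreachable.
* **No excess mortality.** Death ages are pre-sampled from a general
  population life table, independent of disease state — glaucoma is not a
  life-shortening condition at the horizon modelled.
* **Single effective eye, patient-level model.**

## Natural history and its calibration

Conversion is a proportional-hazards process
`h = h0 · exp(LP)` with the linear predictor shared with the risk
calculator; the IOP term uses current (treated) IOP and the age term the
attained age, so treatment lowers the hazard and ageing raises it. Times to
conversion are exponential given the current hazard and are re-drawn at
events — the memoryless property makes this piecewise-constant-hazard
approximation exact between events.

After conversion the visual-field mean deviation declines linearly at
`rate = f · max(0, b · (IOP − 13))` dB/year. The patient-level factor `f`
is lognormal with mean 1 (`prog_sdlog = 1`): progression-rate heterogeneity
(slow vs fast progressors) is a robust clinical observation, and without it
a cohort whose treated IOP clusters near 19–21 mmHg would almost never reach
the severe or visually impaired stages within a lifetime. MD at conversion is
drawn as minus a gamma variate moment-matched to mean −2.94, SD 2.67 dB; the
gamma tail means some patients enter directly at moderate or worse, which is
deliberately not clamped.

The constants cannot be estimated here — the cohort is synthetic — so they
are *calibrated*, once, to two published anchors: about 17% of an untreated
cohort converting within five years, and a standard-care arm in which a bit
over half convert over a lifetime with a few percent ending visually
impaired. The frozen defaults are `h0 = 0.0335`/year at the reference
covariates (cohort means), log-hazard-ratios 0.35 per decade of age, 0.05
per mmHg of IOP, 0.22 per 40 µm of corneal thinning, 0.08 per 0.2 dB of PSD
and 0.08 per 0.1 of cup-to-disc ratio, and `b = 0.15` dB/year/mmHg above a
13 mmHg progression reference. Two deliberate consequences:

* The risk calculator's baseline probability is `1 − exp(−5·h0)`, so the
  calculator is *perfectly calibrated* to the model's own natural history at
  baseline covariates. Its discrimination, however, is modest (the spread of
  the linear predictor is ≈ 0.47 log-hazard units), consistent with the
  limited discrimination reported for UK-validated OHT risk tools; this is
  why nearly the whole of this high-risk cohort crosses the 6% threshold.
* The age coefficient is the largest: conversions keep accruing late in
  life, which is what pushes lifetime conversion in the standard-care arm
  well above the 5-year figure.

## The synthetic cohort

`sample_cohort()` draws independent truncated-normal marginals (age, IOP,
CCT, PSD, vCD) and Bernoulli binaries matching the published baseline table
of a UK electronic-medical-record OHT cohort, with physiologic truncation
bounds (IOP ∈ [24, 40] mmHg — the lower bound is the inclusion criterion —
age ∈ [35, 95], CCT ∈ [400, 700] µm, PSD ∈ [0.3, 4] dB, vCD ∈ [0.05, 0.95]).
An optional Gaussian copula over the continuous block is exposed for
sensitivity exploration but defaults to independence: the source data's
joint correlations are not published, and inventing them would be less
honest than stating their absence. Consequences to keep in mind:

* truncation shifts the IOP mean up by ≈ 0.5 mmHg relative to the nominal
  26.51 (the tests compare against the truncated-normal mean, not the
  nominal one);
* real cohorts correlate age, IOP and CCT, so the tails of the joint risk
  distribution — and anything driven by them — are thinner here than in
  EMR data. Passing tests demonstrate internal consistency and calibrated
  reproduction, not external validity.

The bundled life table (`synthetic_life_table()`, also shipped as
`inst/extdata/life_table_synthetic.tsv`) is a Gompertz–Makeham law
`μ(x) = 2×10⁻⁴ + 2.5×10⁻⁵·e^{0.095x}` chosen to give UK-like annual death
probabilities (≈ 0.9% at 62, ≈ 5% at 80) and a remaining life expectancy of
about 21.6 years at age 62. It is labelled synthetic; any real two-column
table can be supplied.

## Care pathway, schedule and costs

The treatment sequence and its Table of effects/costs are in
`treatment_lines()`: PGA (29% mean IOP reduction, £149.76/yr), PGA+BB
(additional 14%, £171.84/yr for the combination product), SLT (31.2%, £151
once), trabeculectomy (44.7%, £1694 once). Effects are drawn once per
patient and line from normals truncated to [0, 0.9] and applied
multiplicatively to the *current* IOP; adherence multiplies the medication
effect only (base case 1.0, sensitivity value 0.75). "On target" means IOP
at or below 80% of the baseline IOP at entry, and off-target patients
escalate at most one line per visit, so a patient can escalate at most four
times.

The monitoring schedule (`monitoring_schedule()`) is a design decision
rather than published fact, and it is the single knob behind the
monitoring-cost sensitivity analyses:

* every patient is assessed once in secondary care at entry (£294) — the
  initiation decision is made there for treated and untreated alike;
* untreated OHT: annual primary-care IOP+VF check (£23.14);
* treated, on-target OHT: 6-monthly primary-care checks (medication
  reviews are more frequent than simple surveillance);
* off-target or newly referred OHT in secondary care: 6-monthly visits
  alternating IOP-only (£147) and IOP+VF (£294);
* confirmed glaucoma: 4-monthly secondary-care visits alternating IOP-only
  and IOP+VF.

These intervals are within guideline ranges (more frequent review for
treated and converted patients) and were fixed by calibrating the base-case
mean discounted costs of the two arms to their published values; they were
not re-tuned afterwards. With them, the cost difference between the arms is
dominated by medication, which is why a +50% PGA price moves the ICER far
more than a +50% primary-care test fee.

## Economics

`icer()` reports incremental cost and QALYs of RP versus SC with the usual
quadrant logic (dominance labels when signs disagree). The one-way
sensitivity driver re-runs both strategies on the same cohort with matched
per-patient seeds — common random numbers, so a scenario's effect is not
masked by sampling noise — perturbing exactly one parameter per scenario.
The PSA (`run_psa()`) draws second-order parameter sets per replicate:
treatment-effect means from truncated normals with the effectiveness table's
SDs, utilities from moment-matched Betas (absolute SD 0.04, re-sorted to
preserve the severity ordering), unit costs from moment-matched Gammas with
a 20% coefficient of variation. These families are standard health-economics
practice for bounded and positive quantities; the distributions were chosen
before the acceptance checks were run. CEACs are computed from net monetary
benefit, `λ·ΔQ − ΔC > 0`.

## Numerical choices and degenerate inputs

* Truncated normals are sampled by inverse transform (no rejection), so a
  fixed seed yields bitwise-identical cohorts and zero-SD marginals
  degenerate cleanly to point masses.
* Per-patient random substreams are derived deterministically from the
  master seed and patient id; the per-patient draw order is fixed
  (allocation split, four line effects, MD at conversion, progression
  factor, then in-loop exponential clocks), so the big variance components
  are common across strategies.
* Stage boundaries are upper-inclusive (an MD of exactly −6 dB is moderate)
  and a patient exactly at a boundary progresses toward the *following*
  cutpoint, never instantaneously.
* Zero hazard and zero decline rate map to infinite clocks; visual
  impairment is absorbing; an event loop guard (10,000 events) converts a
  structural bug into a loud error rather than a hang.
* Discounting uses the closed interval form
  `v·(e^{−ρt₀} − e^{−ρt₁})/ρ`, which the tests check against numerical
  quadrature; with ρ = 0 it reduces exactly to duration × value.

## Problem sizes

The packaged analyses use 50,000 patients for the base case (the published
design), 10,000–20,000 for one-way sensitivity analyses (the published
design uses 10,000) and 100 replicates × 2,000 patients for the PSA — a
reduced but unbiased version of the published 1,000 × 10,000 design chosen
as a sensible desk-scale default; the acceptance tolerance for the PSA
probability reflects that reduction.

## Known limitations

* No treatment discontinuation, intolerance or adverse events; adherence is
  a static effect multiplier, not a stopping process.
* No measurement error in IOP or visual fields, hence no false-positive
  referrals; monitoring frequency therefore matters only through cost and
  detection delay.
* No IOP drift or fluctuation: an on-target patient stays on target until
  conversion or death.
* The risk calculator's coefficients are calibrated configuration, not
  estimates from data, and the standard-care decision table is a plausible
  reconstruction calibrated to its published treated fraction — both are
  plain-text configuration that users with access to the real tools should
  replace.
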