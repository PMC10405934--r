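---
title: "Decision-analytic methods behind crlmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-analytic methods behind crlmcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the model answers

Roughly a quarter of patients evaluated for colorectal liver metastases
(CRLM) harbour disease that is eligible for hepatic resection, the only
routinely curative treatment. Three imaging modalities compete for the
detection job — contrast-enhanced CT (CE-CT), contrast-enhanced liver MRI,
and 18F-FDG PET/CT — with different diagnostic accuracies and different
tariffs. `crlmcea` asks which modality buys the most health per dollar: it
attaches a lifetime-style consequence model to each possible test outcome
and compares strategies by discounted cost, quality-adjusted life years
(QALYs), incremental cost-effectiveness ratios (ICERs) and net monetary
benefit (NMB).

# Model structure

## Diagnostic decision tree

A cohort of age `start_age` (default 68) with CRLM prevalence
`p_metastases` (default 27.5%) undergoes one imaging test. With strategy
sensitivity *Se* and specificity *Sp* the cohort splits into

* **TP** = `p_met * Se` — resectable disease found: immediate hepatic
  resection at the aggregate `overall_resection_cost` ($21,592). The
  resection succeeds with `p_treatment_success` (70%), entering the
  post-resection state; failures enter the active-recurrence state.
* **FN** = `p_met * (1 - Se)` — disease missed: the patient enters the
  undiagnosed-tumor state carrying only the imaging cost.
* **TN** = `(1 - p_met) * Sp` — enters the tumor-free state.
* **FP** = `(1 - p_met) * (1 - Sp)` — by default receives one confirmatory
  work-up (`fp_workup_cost`, default the MRI tariff of $964) and enters the
  tumor-free state. An alternative `fp_pathway = "resection"` charges an
  unnecessary resection and routes the patient through the post-resection
  state; see "Calibration of open structural choices".

All time-zero (upfront) costs are undiscounted.

## Markov cohort model

Five health states, annual cycles:

| state | annual cost | utility |
|---|---|---|
| `TUMOR_FREE` | 0 | 1.00 |
| `UNDIAGNOSED_TUMOR` | 0 or `annual_crlm_cost` (toggle) | 0.85 |
| `RESECTED` | 0 | 0.78 |
| `RECURRENCE` | `annual_crlm_cost` ($63,063) | 0.65 |
| `DEATH` | 0 | 0 |

The published four-state scheme cannot hold both a post-resection utility
(0.78) and a recurrence utility (0.65) with separately priced recurrence
care, so recurrence is modelled as an explicit fifth state.

Transitions, evaluated at the cohort age of each cycle:

* Background mortality `q(age)` comes from the life table; in the two
  active-disease states it combines independently with the annual
  disease-specific death probability `p_death_untreated` (24.17%):
  `1 - (1 - p_disease) * (1 - q)`.
* `UNDIAGNOSED_TUMOR`: clinically detected with probability `p_detect` per
  cycle (default 1, i.e. at the next annual evaluation). Detected patients
  undergo delayed resection at `delayed_resection_cost` ($28,069.60 — 1.3
  times a timely resection), succeeding with `p_treatment_success`.
* `RESECTED`: recurs with the annualised recurrence probability (below).
* `RECURRENCE`: under the default `recurrence_pathway = "terminal"` the
  state persists until death; under `"salvage"` patients are re-treated
  like detected untreated patients (successful salvage resection, paid at
  the delayed-resection cost, returns them to `RESECTED`).
* `DEATH` is absorbing.

The 62% recurrence probability after hepatic resection is read as a 5-year
cumulative probability and converted to a constant annual hazard,
`1 - (1 - 0.62)^(1/5) = 0.17594`; a 62% *annual* recurrence would leave
almost nobody recurrence-free after two years, which is inconsistent with
the utilities and survival the model is meant to reproduce. Users holding
the annual reading can set `recurrence_input = "annual"`.

## Accrual and discounting conventions

Cycle-*t* state accruals (cost, and utility times the cycle length) are
discounted by `(1 + r)^-t` with `r = 0.03`/year and *t = 0* undiscounted.
Delayed-resection event costs attached to a transition between cycles *t*
and *t + 1* are discounted at *t + 1*. No half-cycle correction is applied;
transitions and accruals happen at cycle boundaries. These conventions are
shared verbatim by the microsimulation oracle — a deviation there is a test
failure, not a tolerance.

## Background mortality

`annual_mortality()` reads an `age,qx` life table; ages beyond the oldest
covered age return 1 so a long horizon cannot outlive the table, and ages
below the covered range are an error. The bundled file
(`lifetable_us2015_synthetic.csv`) is a **synthetic** Gompertz emulation
`q(age) = 0.013 * exp(0.0935 * (age - 65))` for ages 65–100, matching the
order of magnitude of a recent US all-population period life table at both
endpoints (about 0.013 at 65 and 0.35 at 100); it is not a transcription of
published values, and any real life table in the same CSV dialect can be
substituted.

# Economic analysis

`icer()` implements `(e1 - e0) / (q1 - q0)` with dominance flags,
`efficiency_frontier()` the standard sort-by-cost ranking with strict and
extended dominance (frontier ICERs strictly increasing), and `nmb()` the
net monetary benefit `WTP * q - e` at the $100,000/QALY threshold. Exact
cost/QALY ties are broken lexicographically by strategy name everywhere —
including inside the PSA — purely for determinism.

# Sensitivity analyses

## Deterministic

`tornado()` varies every uncertainty-carrying parameter (shared inputs plus
each strategy's sensitivity, specificity and imaging cost) by ±25% of its
base value, clipped to legal bounds. Because the base-case leader dominates
its comparators, the pairwise ICER is undefined at base values, so the
tornado metric is the **NMB difference between the base-case top two
strategies** at the configured WTP; ICER endpoints are reported alongside
wherever they are defined. A known consequence of this (deliberate) metric
choice combined with the confirmatory false-positive pathway: the
specificities act only through the ~$964 work-up tariff and therefore rank
near the bottom of the tornado, while the sensitivities — which control the
false-negative pathway with its mortality exposure and delayed-treatment
costs — rank at the top. An ICER-based tornado with a near-zero QALY
denominator would rank the specificities first, but such ratios are
numerically unstable and dominance-flagged here, so the package does not
use them as the ordering metric.

`two_way()` maps the argmax-NMB strategy over a grid of two parameters;
with CE-CT sensitivity pushed far above MRI's the winner flips to CE-CT,
reproducing the "breaking point" behaviour.

## Probabilistic

`run_psa()` assigns each parameter its method-of-moments distribution:
beta for probabilities and utilities (`alpha = m(m(1-m)/s^2 - 1)`,
`beta = (1-m)(m(1-m)/s^2 - 1)`), gamma for costs (`shape = (m/s)^2`,
`scale = s^2/m`), point masses for fixed values (boundary utilities,
discount rate, WTP, horizon, start age). Moment-infeasible requests
(`s^2 >= m(1-m)` for a beta, dispersion on a boundary mean) are errors at
construction, so every sampled set is valid by construction.

Because the source estimates carry no standard errors, the default
dispersion is the common convention of 20% of the base value, capped so
beta moments stay feasible and overridable per parameter in the config.
All draws come from one seeded stream in a fixed documented order (shared
parameters in table order, then per-strategy accuracy and tariff), so a
rerun with the same seed is bit-identical and results cannot depend on the
order in which strategies are evaluated. The cost-effectiveness
acceptability curve (`ceac()`) reports, per WTP on a 0–200,000 grid in
steps of 5,000, the fraction of iterations in which each strategy attains
the maximal NMB.

# Calibration of open structural choices

Several structural facts are not pinned down by the published description:
the effective time horizon (the printed 8.47–8.50 QALYs are impossible over
a literal 5-year horizon with utilities at most 1), the timing and costing
of the false-negative pathway, the consequence of a false positive, the
fate of recurrent disease, and the PSA dispersions. The committed
calibration file `inst/extdata/calibration.yaml`
(`calibration_config()`) records the single configuration under which the
package reproduces its reference results; every toggle also exists as an
ordinary setting with an independent default:

* `horizon: 13` annual cycles — the shortest horizon at which discounted
  QALYs reach the reference 8.4–8.5 band.
* `undiagnosed_cost: crlm` — undiagnosed active CRLM accrues the annual
  CRLM expense. Without this the cheaper-but-less-sensitive CE-CT strategy
  undercuts MRI on cost, contradicting the reference strict dominance of
  MRI; with it, missed disease is both deadlier and costlier, which is the
  economic mechanism the comparison turns on.
* `recurrence_pathway: salvage` — recurrent disease is re-treated rather
  than terminal. A terminal recurrence state at $63,063/year overshoots the
  reference costs by roughly 25% at every horizon compatible with the QALY
  band; salvage re-treatment (a repeat resection priced like a delayed one)
  is also the clinically standard management of resectable recurrence.
* `fp_pathway: confirmatory` — the default is kept. Charging false
  positives a full unnecessary resection makes the lowest-specificity
  strategy (MRI) lose strict dominance, contradicting the reference
  ranking.
* `dispersion_frac: 0.125` — the PSA dispersion under which the
  acceptability shares at WTP $100,000 match the reference values; the
  package default elsewhere remains 20%.

With this configuration the base case yields costs of $41,795 / $40,992 /
$42,516 and 8.38 / 8.43 / 8.40 QALYs for CE-CT / MRI / PET/CT (within 2.6%
and 1.2% of the reference values), MRI strictly dominant, and PSA
acceptability shares of about 8.1% / 81.5% / 10.4% at 50,000 iterations.

# The synthetic-data module

`random_parameter_table()` draws complete, validation-passing inputs
(probabilities away from the boundaries, costs on a realistic scale,
horizons of 3–15 cycles, start ages 66–72) and `synthetic_lifetable()`
produces monotone Gompertz mortality curves. They emulate the *structure*
of real inputs, not their joint clinical plausibility: parameters are drawn
independently, so correlation between, say, sensitivity and specificity of
one scanner is absent, and the mortality curves are smooth where real life
tables have cohort irregularities. Tests passing on these generators
therefore establish the engine's arithmetic (conservation, monotonicity,
discounting, estimator agreement), not the clinical validity of any
particular input set.

`microsim_oracle()` simulates individual patient trajectories using the
same branch table, transition matrices, event costs and discounting as the
cohort engine — both are built on one shared rule definition, and a test
perturbs that shared definition and checks that both engines move in
lockstep, so agreement cannot arise from duplicated bugs. The cohort
totals must sit within three standard errors of the microsimulation means.

# Numerical choices and degenerate inputs

* Occupancy vectors must sum to 1 within 1e-12 at every cycle; transition
  rows deviating by more than 1e-12 raise an internal consistency error.
* A dispersion of exactly 0, or family `point`, short-circuits to a point
  mass; `p_detect = 0` leaves false negatives undetected for the whole
  horizon; `q = 0` life tables are legal (no background mortality).
* Ties in cost and effect are broken lexicographically by name, so every
  ranking, winner map and PSA share is reproducible to the bit.
* Problem sizes used by the shipped tests: 100 random tables for the
  conservation sweep, five random models at 100,000 simulated patients for
  the oracle comparison, 1e6 draws for moment recovery, and the full
  50,000-iteration PSA for the acceptability checks.

# Known limitations

* The model prices exactly one diagnostic round; repeat surveillance
  imaging, ablation comparators and patient-level covariates are out of
  scope.
* Costs are 2023 US tariffs taken as given; no inflation adjustment,
  currency conversion or fee-schedule retrieval is performed.
* The bundled life table is a labelled synthetic stand-in (see above).
* The deterministic tornado ranking depends on the outcome metric; see the
  discussion of the NMB-difference choice above.
* Parameter draws in the PSA are independent; no correlation structure or
  evidence-synthesis posterior is available.
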