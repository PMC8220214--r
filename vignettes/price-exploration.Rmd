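---
title: "Value-based price exploration with a diabetes outcomes microsimulation"
author: "dmcua"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-based price exploration with a diabetes outcomes microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

A new glucose-lowering drug enters a market where its price is not yet set.
Given a comparator with a known annual cost, a patient-level outcomes model,
and a willingness-to-pay (WTP) threshold `lambda` (here 1x GDP per capita,
$10,425.29 per QALY, with `3 lambda` as the secondary "cost-effective"
threshold), the value-based price is the annual drug cost at which the
incremental cost-utility ratio

    ICUR = (C_int - C_comp) / (E_int - E_comp) = dCost / dQALY

equals the threshold.  `dmcua` implements the full workflow: synthesize a
baseline type-2-diabetes cohort from published summary statistics, simulate
long-term complications and survival for both treatment arms, accrue
discounted costs and QALYs, and invert the price--ICUR relationship by
binary search, followed by one-way, probabilistic and scenario sensitivity
analyses.

```{r}
library(dmcua)
fit <- cua(default_config(n_patients = 1000, seed = 1))
print(fit)
ps <- find_price(fit, "lambda")
ow <- owsa(cua(default_config(), intervention_price = ps$price))
```

## Model structure and assumptions

The simulation is a semi-Markov annual-cycle patient-level model.  Each
simulated year, every alive patient:

1. has risk factors updated (treatment effects, ageing, optional drift);
2. is exposed to eight complications — ischaemic heart disease (IHD),
   myocardial infarction (MI), heart failure (CHF), stroke, amputation,
   blindness, renal failure, foot ulcer — evaluated as conditionally
   independent Bernoulli draws given the current state (no within-year
   state updates; this is the simplest defensible reading of an
   annual-cycle model);
3. is exposed to all-cause death, evaluated last.

A patient dying in year *t* accrues that year's events and costs in full;
there is no half-cycle correction, matching annual accounting.  When a
complication co-occurs with death in the same year its *fatal* cost variant
is booked (events without a fatal variant use the non-fatal cost); a death
year without a co-occurring complication is other-cause mortality.
Recurrence follows the cost-table structure: MI, stroke and ulcer can
recur; amputation, blindness and renal failure are absorbing comorbidity
states; IHD and CHF are modelled as first-event-only.  Simulated events
feed back into later-year risks through `prior_*` state flags.  Pre-existing
history flags (e.g. prior MI at baseline) act as risk-equation covariates
only; they do not block a first simulated occurrence and accrue no cost.

The default within-year evaluation order is the cost-table listing (IHD,
MI, CHF, stroke, amputation, blindness, renal failure, ulcer).  Because
each (patient, year, event) combination consumes a dedicated uniform draw
keyed by event *name*, reordering evaluation cannot change any outcome;
the order is nevertheless configurable and the property is tested.

### Common random numbers

Every stream derives from one master seed: the baseline sampler, and one
uniform per (patient, year, event) keyed only by `(seed, patient id)` with
a fixed 70-year-by-9-event layout.  Two arms, two prices, or two parameter
sets therefore replay identical randomness, and any outcome difference is
attributable to the inputs.  Consequences used throughout the package:
histories are a pure function of the risk-relevant inputs (drug prices
never enter them); `dQALY` is constant across prices; and `dCost(p)` is
*exactly* affine in the intervention's annual price `p`, with slope equal
to the mean discounted on-treatment person-years.

## Cohort synthesis

Baseline records are drawn from the published summary statistics: mean/SD
for age, diabetes duration, HbA1c, BMI, SBP/DBP, lipids, eGFR; proportions
for sex, race, smoking, and pre-existing events.  Continuous variables use
normal distributions truncated at mean +/- 4 SD and at hard physiological
floors (HbA1c >= 3%, eGFR >= 1 ml/min/1.73m^2, BMI >= 10 kg/m^2, non-negative
lipids and duration).  The underlying normal parameters are calibrated
(closed-form truncated moments + Nelder-Mead) so the *truncated*
distribution reproduces the published mean and SD; without this, a floor
close to the mean — diabetes duration 7 (5.9) years truncated at 0 — would
bias the sample mean upward by more than a year.

Two published proportions are given only verbally ("few" renal
complications, "less than 1%" microalbuminuria); both are encoded as 0.5%,
the midpoint of the stated bound.  Correlations between baseline risk
factors are not modelled (only marginals are published); this is a known
limitation, and cohorts should be interpreted as marginally — not
jointly — representative.  Race is carried as a categorical tag (dummy
columns in the state matrix) for equation files that consume it; the
shipped equations do not.

## Risk equations

Annual probabilities come from per-event equations with a functional-form
tag — `logistic`, `cloglog`, `weibull` (cumulative-hazard increment in
diabetes duration, floored at 1 year), or `gompertz` (log-hazard linear in
attained age) — and a named coefficient vector over patient-state fields.
Equation sets are plain-text files (one block per event, `coef name value`
lines, strict validation with line numbers); see
`inst/extdata/risk_equations_synthetic.txt`.

The published analysis uses the UKPDS Outcomes Model 2 risk equations,
whose coefficients are cited but not printed.  The package therefore treats
the equation set as user-supplied configuration and ships a clearly
labelled **synthetic stand-in** with plausible magnitudes (mortality rising
steeply with age, HbA1c-sensitive coronary risks).  All absolute outputs
under the synthetic set — life expectancy, QALYs, costs, PSA
percentages — are illustrative; the package's tested claims are the
arithmetic identities, invariants and procedure structure, which hold for
any valid equation set.

Treatment effects are applied as a one-time year-1 shift held constant
while on treatment (only 52-week changes are published).  After the preset
treatment time (default 5 years) therapy switches to basal insulin; the
risk-factor deltas default to `"hold"` (no reversion), with `"revert"`
available, since the published analysis is silent — as is any post-year-1
drift (default 0/year, configurable per factor).  Published lipid deltas
(e.g. total cholesterol −6.15) are implausible as mmol/L shifts and are
interpreted as *percent* changes from baseline; the profile records the
chosen interpretation (`lipid_delta_unit`) and `"absolute"` is available.

## Economics

Cycle *t* (first cycle t = 1) is discounted by `(1+r)^-(t-1)` — the first
year undiscounted, end-of-year accrual thereafter; the published analysis
states only "annual discount rate 5%", so the convention is ours and is
applied identically to costs and utilities.  Per alive year:

* **Utility** = `max(0, initial - sum of active decrements)`, decrements
  additive across complications (they are published as absolute
  decrements): the event-year decrement in an occurrence year, the
  subsequent-year decrement thereafter.
* **Therapy cost** = annual drug cost while on treatment, basal-insulin
  cost after.  The insulin price is not published; it defaults to the
  comparator-era annual therapy cost ($558.2/year) and is configurable.
* **Complication-bucket cost** = the $1,427.10/year management cost
  (booked here, not under therapy, which makes the published two-component
  total-cost additivity hold) + event-year costs + subsequent-year costs
  of prior events.

Life expectancy is reported undiscounted while QALYs are discounted — the
only reading consistent with the published per-arm values.  Arm summaries
are patient-level means with normal-approximation 95% CIs.  The ICUR
classification is a step function with breakpoints exactly at `lambda` and
`3 lambda`; dominance (`dQALY >= 0`, `dCost <= 0`, not both zero) is
reported instead of a ratio.  When both increments are negative the
intervention saves money at a QALY loss; the package classifies that
quadrant cost-effective only if the savings per QALY forgone exceed
`3 lambda`.  The secondary threshold may be supplied explicitly: the
published 3x value ($31,275.88) differs from `3 * 10,425.29 = 31,275.87`
by one cent, and the package keeps a supplied value within rounding
distance while noting the discrepancy.

## Price search

`find_price()` bisects the annual price on a bracket (default: comparator
price to four times it) until `|ICUR - target| <= tolerance`, with a
default tolerance of $1/QALY (the published analysis reports
"approximately equal" without one) and a hard cap of 60 iterations.
Bracketing is verified first; if the intervention dominates at the lower
bound the bracket test falls back to the sign of
`dCost - target * dQALY`, which is monotone in price.  Because `dCost(p)`
is exactly affine under common random numbers, a closed-form inversion
from two probe prices is exposed (`affine_price_inversion()`) as an
independent cross-check; bisection remains the headline method because it
is the published procedure.  The published analysis re-ran the search at
an 8% discount rate after the tornado identified the discount rate as the
most influential parameter; the re-search rate is a parameter here, not a
hard-coded 8%.

## Sensitivity analyses

**One-way (tornado).**  Twenty published rows: discount rate 5% [3%, 8%],
initial utility 0.876 [0.78, 0.92], treatment time 5 [4, 6] years, horizon
40 [30, 50] years, eight per-year complication costs and eight
disutilities (ranges are the published 95% CIs; +/-20% for costs and
+/-10% for disutilities where no CI was reported).  Each row re-runs the
frozen-seed pipeline with exactly one input at its low and high value;
where one published number feeds two config keys (a disutility applied in
both event and subsequent years) the paths move together.  Bars are ICUR
widths, sorted descending; a perturbation that produces dominance records
endpoint 0 with a flag.

**Probabilistic.**  Second-order Monte Carlo (published setting: 1,000
iterations): per-year complication costs ~ Gamma (mean at baseline, SD
from the published range where one exists, else 20% of the mean), utility
decrements ~ Beta scaled to `[0, 2 x baseline]` (SD from the range, else
10%), initial utility ~ Beta, treatment-effect deltas ~ Normal with their
published SDs.  Which inputs entered the published PSA is unstated; the
default samples costs, utilities and treatment effects, with an inclusion
argument and fully overridable assignments.  The baseline cohort is held
fixed across draws (the event streams are common random numbers), so the
spread isolates parameter uncertainty; cohort heterogeneity is first-order
noise and is visible instead through `simulate()` replicates.  A draw
counts as cost-effective when `wtp * dQALY - dCost >= 0`; dominant draws
count as cost-effective (standard cost-effectiveness-plane convention).

**Scenario.**  The comparator's drug acquisition component is multiplied
(published scenario: 0.8); the accounting identity — the comparator total
falls by exactly `(1 - multiplier)` times its discounted drug-cost
component — is exact and tested.

## Numerical choices

* Seeds: sub-streams derive from `(master seed, labels)` via a modular
  hash; R's global RNG is seeded per stream, never consumed implicitly.
  All results are bit-reproducible from the master seed.
* Currency is accumulated unrounded in floating point; rounding to cents
  happens only at presentation.
* Uniform draws are always generated on a 70-year grid so horizon changes
  (30/50-year sensitivity runs) keep every retained year's draw identical.
* Degenerate inputs: zero-SD cohorts collapse to the means; `sd = 0`
  distributions become point masses; empty histories accrue management and
  therapy costs only; equation evaluation is pure and clamped to [0, 1].
* Problem sizes in the test-suite: the bundled checks run cohorts of
  10–1,000 patients (10^5 for moment recovery), a 5,000-patient reference
  run for rate convergence, and a full 1,000-patient, 1,000-iteration PSA
  pipeline; these sizes give stable assertions at interactive runtimes.

## What passing tests do and do not show

The suite verifies the published arithmetic identities (ICUR ratios,
component additivity, scenario re-pricing), closed-form economic limits,
equivalence of the simulation loop with an independent straight-line
reimplementation, the affine/bisection price contract, PSA calibration
against an analytic toy, and end-to-end reproducibility.  It does **not**
validate the synthetic risk equations against observed diabetes outcomes:
absolute life expectancy, QALY and cost levels, and therefore the specific
price solutions and PSA percentages, would require the unpublished UKPDS
OM2 coefficient set.  Users with access to a validated coefficient file
can drop it in via `equations: file:` without touching any other input.

## Known limitations

* Baseline risk factors are sampled independently (marginals only).
* No treatment discontinuation or adherence modelling beyond the fixed
  treatment time; no within-year event interactions.
* The semi-Markov duration dependence enters only through covariates
  (age, diabetes duration, prior-event flags) supplied to the equations.
* No cost-effectiveness acceptability curves or value-of-information
  analysis; single-threshold probabilities only.
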