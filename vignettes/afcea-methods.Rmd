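---
title: "Model and methods: the AF mHealth cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the AF mHealth cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcea)
```

## The decision problem

`afcea` implements a discrete-time Markov cohort model comparing two
management strategies for patients with atrial fibrillation (AF) in
China, from the public health-care provider perspective:

* **usual care** — guideline-based anticoagulation and follow-up;
* **mHealth-based care** — integrated management along the Atrial
  fibrillation Better Care (ABC) pathway delivered through a mobile app
  (anticoagulation monitoring, symptom management with a
  photoplethysmography device, comorbidity management), on top of usual
  care, at a one-time setup cost and a monthly subscription.

The cohort enters well with AF at age 68 and is propagated through
monthly cycles for 30 years (360 cycles). Outcomes are discounted
direct medical costs (2021 US $) and quality-adjusted life years
(QALYs); strategies are compared by the incremental cost-effectiveness
ratio (ICER) against a willingness-to-pay (WTP) threshold of US
$33,438/QALY (three times GDP per capita).

## State space

Three event types are modelled: ischemic stroke (IS) and intracranial
hemorrhage (ICH) as persistent neurological events with minor/major
severity, and gastrointestinal bleeding (GIB) as a transient
within-cycle toll. A health state records

* the worst severity reached for each stroke type (`none`, `minor`,
  `major`),
* which type occurred most recently (this keys the recurrence inputs),
* the antithrombotic (`OAC` = oral anticoagulation, `ASA` = aspirin),
* or death (one absorbing state).

Structural rules, isolated in a single routing function:

* a second minor event of the *same* type escalates that type to major;
* a cross-type event creates the combined "IS and ICH" states
  (minor+minor, minor+major, major+minor) rather than escalating;
* a major-class event — new or by escalation — in a patient who already
  carries a major severity of either type is fatal, so two-major
  combinations are unreachable;
* a fatal-class event goes directly to death;
* the first ICH or GIB switches the patient from OAC to aspirin
  permanently. The switch affects costs only (the anticoagulation cost
  stops; aspirin is costed at US $0, as no price input exists): no
  on/off-anticoagulant event rates are available, so event
  probabilities do not depend on the antithrombotic.

This yields 15 states (`enumerate_states()`). GIB is deliberately *not*
a persistent column: an episode charges its cost, a 14-day utility
decrement, and a within-cycle mortality adjustment, and triggers the
aspirin switch, while the persistent state is otherwise unchanged.

## Transition probabilities

**First events.** The monthly probabilities of first IS, ICH and GIB
under usual care (0.244%, 0.024%, 0.034%) are taken directly from the
shipped input table. (The table's own 18-month-to-monthly conversion
for these three rows is not exactly recoverable with any standard
rate-to-probability identity, so the printed monthly values are used
as-is; the conversion function is validated against the recurrence
rows, which do reproduce exactly.)

**Rate conversions.** `monthly_prob_from_cumulative(C, T)` implements
`p = 1 - exp(-(C/T))`, i.e. the event rate is approximated by the
cumulative incidence divided by the observation period, applied over
one monthly cycle. This is the convention that exactly reproduces the
published recurrence conversions (5-year 41% → 0.68%/month for IS,
44% → 0.73%/month for ICH); the alternative `-ln(1-C)/T` does not.

**Recurrence.** Post-stroke states use the monthly recurrence
probability keyed by the most recent event type, split into IS/ICH by
the recurrent-type proportions (91/9 after IS, 44/56 after ICH).
Severity classes of recurrent events use the same minor/major/fatal
splits as first events (no separate severity data exist for
recurrences).

**Treatment effect and compliance.** Hazard ratios act on the rate
scale: `apply_hazard_ratio(p, hr) = 1 - (1 - p)^hr`, which satisfies
the exact composition law `hr1` then `hr2` = `hr1 * hr2`. Non-adherence
is a per-cycle probability mixture: with compliance `c`, each mHealth
event probability is `c * apply_hazard_ratio(p, hr) + (1 - c) * p`.
The mixture is memoryless — non-adherent patients experience usual-care
risks in that cycle and may adhere again later — and the hazard ratios
apply to recurrent as well as first events. A persistent non-compliance
sub-state was considered and rejected: it has the same expectation for
event accrual and would double the state space.

**Mortality.** Background monthly mortality comes from seven age bands
(65–69 through >95); the cohort's attained age is `start_age +
cycle/12`, truncated to the band table, with ages beyond 95 staying in
the terminal band. The AF-vs-no-AF all-cause mortality hazard ratio
(1.87) applies on the rate scale; in a GIB cycle the relative risk of
death with GIB (3.5) applies the same way, weighted by the state's GIB
probability. Fatal event classes are additional to background
mortality, as the state diagram implies.

**Competing risks within a cycle** are resolved in a fixed order:
background death first; then at most one neurological event (IS and ICH
are treated as mutually exclusive within a month — their monthly
magnitudes make the joint probability ~10^-6); then the GIB toll in
event-free survivors. No joint stroke+GIB cycle is modelled. Row sums
are asserted to 1 within 1e-10.

## Accrual conventions

* No half-cycle correction; state membership is evaluated at cycle end,
  and the tolls of the transition into cycle *t* are discounted with
  cycle *t*.
* Discounting: `(1 + 0.035)^(-cycle/12)` applied identically to costs
  and QALYs.
* State utilities: well-with-AF 0.9; single-type states per the input
  table; **combined states take the minimum of the component
  utilities** (the conservative choice; the sum of decrements was
  rejected as it can push utilities negative).
* GIB subtracts `0.16 * 14/30.4375 / 12` QALYs per episode (a 14-day
  decrement with a 30.4375-day month, i.e. 365.25/12).
* Monthly costs: anticoagulation (US $249) in OAC states only;
  per-state follow-up costs, with **combined states charging the sum of
  the component follow-up costs**; the mHealth subscription (US $15)
  for every alive mHealth-arm patient **regardless of compliance** (the
  service is provisioned even if under-used), plus the one-time US $80
  setup at entry.
* Event episode costs per toll; fatal events charge the all-cause death
  cost (US $5,849) only, which is charged once for every death, event
  or background.

## Sampling distributions

Each varied input carries a base value, a range and a family:

* **uniform / triangular**: support equals the printed range exactly;
  triangular mode at the base value (used for the assumed ICH hazard
  ratio, range 0–1, and the mortality bands).
* **lognormal** (ratios and costs): log-mean `ln(base)` — the base case
  is the sampled median — and log-sd `(ln(high) - ln(low))/3.92`,
  reading the range as a 95% interval even when asymmetric.
* **beta** (probabilities): mean at base, sd `= (high - low)/3.92`,
  shapes by method of moments.
* **Dirichlet** (severity triples): concentration `base × 100`; the
  effective sample size 100 is a calibration choice making the marginal
  spreads comparable to the printed per-category ranges.
* The two text-sourced ratios (AF mortality HR 1.87, CI 1.09–3.20; GIB
  death RR 3.5, range 2.8–4.2) have no stated family and are assigned
  lognormal, the convention used for every other ratio.
* Recurrent-type pairs must sum to one, so the IS-after-* member is
  sampled from its Beta and the complement is implied.

## Sensitivity analyses

**One-way (tornado).** Every distributed parameter is evaluated at its
published range bounds (±20% is the fallback where no range exists);
a severity-triple member is moved with the remaining two members
rescaled proportionally; the seven mortality bands move jointly through
a single 0.8–1.2 multiplier (per-band variation by flag, since their
printed ranges are all ±20%). Parameters are ordered by the absolute
ICER swing. `threshold_search()` bisects a parameter's domain for an
ICER = WTP or incremental-cost = 0 crossing (default tolerance 1e-4 of
the domain width) after a 9-point scan that warns on non-monotone
criteria; no sign change at the bounds returns no threshold.

**Probabilistic.** `run_psa()` draws every varied input jointly
(independent across parameters, joint within a Dirichlet triple) with
one seeded base-R generator and a fixed draw order — the order of the
distribution list, iterations sequential — so a seed fully determines
the result; per-iteration sub-streams were not needed for
reproducibility and would complicate the draw accounting. Invalid draws
(violating any parameter invariant) are rejected and redrawn, with a
bounded retry count. The cost-effectiveness acceptability curve is the
fraction of iterations with positive net monetary benefit at each WTP;
ties favour usual care, and the two-strategy curves sum to one by
construction.

## Synthetic scenarios

`synth_params()` generates randomised, internally consistent parameter
sets: probabilities and costs in realistic magnitude ranges,
proportions normalised, mortality non-decreasing in age, and utilities
ordered (major ≤ minor ≤ event-free — imposed so property tests reflect
clinically coherent inputs; switchable off for adversarial testing).
Degeneracy switches (zero mortality, zero events, identity hazard
ratios, point-mass distributions) produce analytically known behaviour:
identity transition matrices, full survival, closed-form annuity QALYs,
and PSAs that reproduce the base case bit-exactly. The generator
emulates the *structure* of the real input table — it does not emulate
correlations between inputs (all draws are independent), calendar
trends, or patient-level heterogeneity, so passing property tests
establishes engine correctness, not clinical realism.

## Verification strategy and problem sizes

The cohort engine is cross-checked against an independent per-patient
microsimulation that walks 20,000 individual patients through the same
monthly transition matrices; occupancy must agree within three
Monte-Carlo standard errors at several checkpoints over the full
360-cycle horizon, for both strategies. Closed-form limits (annuity
QALYs under zero mortality/events, zero-discount life years) are
checked to 1e-10. The test suite runs the PSA at 2,000 iterations and
the reproduction script at the full 10,000; at 2,000 iterations the
Monte-Carlo standard error of the mean QALY difference is already below
1% of its value.

## Reproduction of the original analysis

The package recomputes every headline quantity of the original analysis
from the shipped inputs (`scripts/acceptance.R`). Two groups emerge:

* Quantities driven by the **usual-care arm and the input table** are
  recovered closely: total usual-care QALYs (7.209 here vs 7.202
  published), total mHealth-arm cost (35,342 vs 35,691), the usual-care
  trial-window IS incidence (4.43% vs 3.86%), and the probability
  conversions (exactly).
* Quantities driven by the **size of the intervention effect** are not:
  with the stated hazard ratios (IS 0.11, ICH 0.5, GIB 0.37) and 70.8%
  compliance, the model avoids roughly 63% of strokes, and because each
  avoided stroke saves both permanent utility decrements and lifelong
  monthly follow-up costs, mHealth-based care gains ~0.45 QALYs and
  *saves* ~US $2,800 — it dominates usual care — whereas the original
  analysis reported a gain of 0.073 QALYs at an extra cost of US $1,090
  (ICER US $14,936/QALY). The original report itself describes its QALY
  gain as driven by a small survival improvement, which is difficult to
  reconcile with permanent post-stroke utilities and an ~89% reduction
  in window IS incidence in its own validation table. We found no
  defensible convention for compliance, hazard-ratio application or
  cost accrual that closes this gap, and chose not to distort the
  documented conventions to force agreement; the discrepancies are
  reported as-is by the reproduction script and the acceptance tests.
* The published 5-year survival (73.5%) is likewise not recoverable
  from the stated mortality bands and AF hazard ratio under any age-band
  lookup we tried (floor, ceiling, ±1 band); the model yields 78.3%.

## Known limitations

* Aggregate cohort model: no patient-level heterogeneity (CHA₂DS₂-VASc
  distribution, sex, region) and no treatment sequencing beyond the
  OAC→aspirin switch.
* The aspirin price, combined-state utility/cost rules, and
  subscription billing for non-compliers are assumptions (documented
  above) exposed through the parameter schema.
* PSA draws are independent across parameters; correlated uncertainty
  (e.g. between event costs) is not modelled.
* No EVPI or multi-way scenario analysis.
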