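---
title: "Trigger-based prescribing surveillance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger-based prescribing surveillance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxalert)
```

## The problem and the rule

Opioids and benzodiazepines drive most pharmaceutical overdose deaths,
and prescribers are often blind to risk signals scattered through a
patient's record — an open prescription written elsewhere, repeated
emergency visits treated onsite with opioids, a past overdose, a
positive drug screen. `rxalert` implements the decision-support pattern
used to surface exactly those signals: a **rule** that executes at every
opioid/benzodiazepine prescription initiation, searches the record for
five objective **triggers**, and — once live — interrupts the prescriber
with an **alert** when one or more are met. Before going live, the same
rule runs **silently**, logging what would have fired; the resulting
surveillance data are what you tune the thresholds on.

The unit of evaluation is the prescription initiation (the rule runs
once per prescription, at its `written_at`). Encounter-level statistics
— a *prescribing encounter* is any encounter in which at least one
opioid/benzodiazepine prescription is initiated — are derived
downstream by unioning the criteria met across an encounter's
evaluations. Keeping the two units separate matters: real silent-phase
data gave us reason to expose both, because an EMR's own alert count
need not equal either the flagged-prescription or the
flagged-encounter tally.

## Trigger semantics and their parameters

All five evaluators are pure functions of `(store, t_eval, config)`.

* **Early refill** (`remaining_fraction_threshold`, default 0.50,
  dimensionless in (0,1)). A prior prescription with days of supply $d$
  and elapsed time $e$ (in days, continuous) qualifies when
  $0 \le e < d$ and $1 - e/d >$ threshold, strictly. Strictness is
  deliberate: the criterion is phrased as an excess (">50 % remaining"),
  so a prescription at exactly half supply does not fire. Either drug
  class counts — both classes are the rule's subject and cross-class
  early refill carries the same risk; restricting to same-class refills
  would be a one-line config extension. Prescriptions with missing or
  non-positive duration are skipped and surfaced as a warning in the
  evidence, never silently dropped at load time.
* **ED/urgent-care visits with onsite opioid treatment**
  (`min_ed_uc_visits`, default 2 visits; `ed_uc_window_days`, default
  30 days). Distinct encounters with facility type ED or urgent care,
  disposition not ADMITTED (visits leading to admission are excluded by
  definition), started within the window, and carrying at least one
  onsite opioid administration. The index encounter never counts: the
  criterion reads on history, and counting the visit being billed would
  let a single ED visit trip a two-visit threshold.
* **Prescription history** (`min_prescriptions`, default 3;
  `rx_window_days`, default 30 days). Either class, each prescription
  counted once. Prescriptions written earlier in the *same* encounter
  do count — they are prior events at evaluation time — which is the
  package's resolution of a genuinely open point; it is the
  interpretation consistent with per-prescription execution.
* **Overdose history** and **positive toxicology screen** have lifetime
  lookbacks ("within the record", no window stated) and no tunable
  parameters. Tox evidence carries the analytes, since a patient can be
  positive for several and the report's analyte sub-rows overlap.

**Window convention.** "Previous $W$ days" is the half-open interval
$[t - W\,\mathrm{d},\, t)$ with one day fixed at 86,400 s: closed at
the old edge, open at the evaluation instant, so nothing happening *at*
$t$ counts as history and daylight-saving shifts cannot move a
boundary. All timestamps are normalised to UTC on input. The early
refill criterion is the one place the instant $e = 0$ is allowed — a
second prescription written at the same moment as a still-full one is
precisely the situation the trigger describes.

The defaults are the final production thresholds. The initial
surveillance profile (`trigger_config(profile = "initial")`, also
shipped as `inst/extdata/triggers_initial.yaml`) differs in two places:
early-refill threshold 0.30 and visit minimum 3. Those two moves — up
for early refill, down for visits — are the canonical tuning outcome:
the lower refill threshold mostly caught routine primary-care refills
(noise), while the three-visit minimum missed patients worth capturing
at a trivial alert-burden cost.

## One arithmetic wrinkle

The classic worked example for early refill — a 10-day supply written 3
days ago — has remaining fraction 0.7 and fires at both thresholds. But
as a *boundary* illustration of ">30 % remaining" the phrase "at least
3 days ago" is arithmetically inconsistent: for a 10-day supply any
elapsed time under 7 days leaves more than 30 % remaining. The package
implements the remaining-fraction formula, not the phrase; the tests
pin the formula's boundary behaviour (elapsed 4, 5, 6 days against the
0.50 threshold) instead.

## The surveillance report

`build_report()` produces the standard characteristics table over
prescribing encounters: age bands (<18, 18–64, ≥65, computed at the
encounter date with a 365.25-day year), facility buckets (ED/urgent
care; inpatient discharge; outpatient including phone calls; other),
drug-class buckets (opioid only / benzodiazepine only / both), the
criteria-count distribution (0–5), per-criterion prevalences with
analyte sub-rows, and alert rates.

Percentages are rounded **half-up** at two decimals — the convention
that reproduces published surveillance tables cell-for-cell, where
round-half-even does not (e.g. 2314/61747 prints 3.75) — with a
$10^{-9}$ nudge guarding against binary representation of exact decimal
halves.

Denominators are explicit because alert-rate claims are
denominator-sensitive. The report exposes: the share of prescribing
encounters with ≥1 criterion; the share of *all* in-period encounters,
with phone encounters excluded from that denominator (phone contacts
are too inconsistently documented to yield an accurate total, though
prescribing phone encounters still count as prescribing encounters);
and per-facility-bucket rates.

`summaries_from_counts()` inverts the aggregation for checking
purposes: given printed marginal counts it reconstructs an
encounter-level table with exactly those marginals (a deterministic
greedy allocation assigns each $k$-criteria encounter the $k$ criteria
with the largest remaining totals; analytes are laid cyclically over
the tox-positive rows). The joint assignment is not identified by the
marginals, but every reconstruction with the right marginals yields the
same report — which is the point: it lets the report formatter be
validated against published numbers without patient-level data.

## The synthetic cohort generator

`generate_cohort()` emulates a mixed-risk population with four
archetypes — baseline utilizers, frequent utilizers (elevated encounter
and prescription rates, hence early-refill and prescription-history
signal), substance-use patients (positive screens), and
overdose-history patients (one flagged encounter predating the
surveillance period). Encounters are a homogeneous Poisson process per
patient over the 30-day period plus a 90-day pre-period (so 30-day
lookbacks have history at the period start); facility, disposition,
onsite administration and prescribing are conditionally independent
draws given the encounter; prescriptions are written at the encounter
start.

Default rates were chosen once so the five criterion prevalences among
prescribing encounters land in the same order of magnitude as a large
mixed health system's silent-phase profile (≈14 %, 2 %, 5 %, 7 %, 1 %);
with the shipped defaults a 2,000-patient cohort gives ≈19 %, 7 %, 4 %,
0.8 %, 8 %. Exact marginal matching is deliberately *not* a contract:
the published joint distribution of criteria is unknown, and archetype
correlations here are a modelling choice.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: diagnoses and comorbidity-driven risk,
demographic risk gradients, realistic drug names/doses or
morphine-equivalents, seasonal or weekday utilisation structure,
multi-prescriber/multi-pharmacy behaviour, and record fragmentation
across health systems (every simulated event is visible to the rule,
which inflates lifetime-lookback triggers relative to a real, partial
record).

Determinism is a hard contract: one seeded RNG stream is consumed in a
fixed order (patient attributes first, then each patient's event stream
in patient order), generation runs under an isolated RNG state so it
neither perturbs nor is perturbed by the caller's stream, and equal
configurations yield byte-identical serialized logs. Durations are
drawn on a 0.1-day grid and event times at whole seconds so that
round-trips through the text formats are exact.

## Threshold tuning

`sweep_thresholds()` re-runs surveillance and reporting per
configuration and tabulates per-criterion rates, the ≥1-criterion rate
and flagged encounter/patient counts; `compare_configs()` reports rate
deltas and the distinct patients flagged under one configuration but
not the other — the "additional at-risk patients captured" when a
threshold relaxes. For nested thresholds the flagged sets nest
(relaxing can only add), which the tests assert as a property. No
target alert rate is built in: the module produces the trade-off table;
choosing a point on it is a consensus decision, not an optimisation.

## Numerical and degenerate-input choices

* Half-open windows everywhere; ties at a window's old edge are *in*,
  at the evaluation instant *out*.
* Strict inequalities for the remaining-fraction threshold; `>=` for
  count minima (the "2+" reading).
* Unknown enum values in input are rejected, not coerced — silent
  coercion would corrupt surveillance denominators.
* Empty inputs are ordinary: an empty store yields an empty log, an
  empty log an all-zero report (percentages rendered `0.00`).
* Surveillance logs are sorted by evaluation time with `rx_id` as the
  deterministic tie-break.
* Age bands use floor(days/365.25); the half-day error this admits is
  irrelevant at band edges measured in years.

## Problem sizes

The test suite exercises hand-built micro-fixtures for every boundary,
a 300-patient cohort for oracle and engine checks, 1,200 patients for
the brute-force equivalence sweep, and 5,000 patients (≈1,300 in-period
evaluations) for marginal-recovery and threshold-nestedness properties
— sizes at which binomial sampling error (3 standard errors) is tight
enough to be informative while the full suite stays comfortably fast.
`scripts/acceptance.R` uses the default 2,000-patient configuration.

## Known limitations

* The rule sees only what is in the store; cross-system prescription
  history (the problem a prescription drug monitoring program solves)
  is out of scope, as are pop-up UI, EMR write-back and prescriber
  behaviour analysis.
* `duration_days` is taken at face value as days of supply; no
  morphine-equivalent dosing or quantity/sig parsing.
* The generator's archetypes induce simple, known correlations between
  criteria; real criterion co-occurrence is richer, so absolute alert
  rates on synthetic cohorts should be read as engine checks, not
  epidemiology.
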