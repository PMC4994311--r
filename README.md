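# rxalert

Clinical decision support for controlled-substance prescribing: a
five-trigger risk rule evaluated at every opioid or benzodiazepine
prescription initiation, a silent-surveillance mode that logs
would-have-fired alerts without interrupting anyone, aggregate
surveillance reporting over prescribing encounters, and a
threshold-tuning sweep — all exercisable on a built-in synthetic EMR
cohort simulator, so the whole pipeline runs without real patient data.

It is written for informaticists and clinical researchers who want to
prototype, tune and audit EMR alert logic for opioid/benzodiazepine
misuse, abuse and diversion risk before anything touches a production
system.

## The rule

Every time a prescription for an opioid or benzodiazepine is initiated
at time *t*, the rule searches the record for five objective triggers:

1. **Early refill** — some prior prescription (either class, the index
   prescription excluded) with days of supply *d* and elapsed time
   *e = t − t_written* satisfies *0 ≤ e < d* and a remaining fraction
   *r = 1 − e/d* strictly above a threshold (default **r > 0.50**; the
   initial surveillance profile used 0.30).
2. **Repeated ED/urgent-care visits with onsite opioid treatment** —
   at least **2** distinct ED/urgent-care encounters (3 in the initial
   profile) in the previous 30 days, excluding visits that led to
   admission and the index encounter, each with an onsite opioid
   administration.
3. **Prescription history** — at least **3** opioid/benzodiazepine
   prescriptions written in the previous 30 days (index excluded).
4. **Overdose history** — any previous overdose presentation in the
   record (lifetime lookback).
5. **Positive toxicology screen** — any prior positive screen for blood
   alcohol, cocaine, or marijuana (lifetime lookback).

"Previous 30 days" is the half-open window *[t − 30 d, t)* with one day
= 86,400 s. An alert fires when **≥ 1** trigger is met; in silent mode
the outcome is logged but no payload is rendered.

## Worked example

```r
library(rxalert)

store <- generate_cohort(cohort_config(n_patients = 2000, seed = 7))
period <- attr(store, "period")           # 30-day surveillance window

log <- run_surveillance(store, period[1], period[2], trigger_config())
summ <- collect_prescribing_encounters(log, store)
report <- build_report(summ, store, period[1], period[2],
                       n_prescriptions = nrow(log))
report$criteria
#> # A tibble: 5 × 3
#>   criterion        n pct
#>   <chr>        <int> <chr>
#> 1 EARLY_REFILL    95 19.31
#> 2 ED_UC_ONSITE    36 7.32
#> 3 RX_HISTORY      18 3.66
#> 4 OVERDOSE         4 0.81
#> 5 TOX_SCREEN      38 7.72
report$alert_rate_prescribing_pct
#> [1] "31.30"
```

Of the 492 prescribing encounters this cohort produces, 31.30 % meet at
least one criterion; the per-criterion rows give each trigger's
prevalence among prescribing encounters (early refill is the most
common, prior overdose the rarest — the usual shape for a mixed
outpatient/ED population).

Tuning contrast between the initial and final threshold profiles:

```r
cmp <- compare_configs(store, period[1], period[2],
                       trigger_config(profile = "initial"),
                       trigger_config(profile = "final"))
cmp$rates          # per-criterion rate deltas (final minus initial)
cmp$n_additional_patients  # distinct patients captured only by the final profile
```

A thin command-line front end over the same functions lives at
`inst/cli/rxalert.R` (`simulate`, `evaluate`, `report`, `sweep`
subcommands).

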