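# Default synthetic cohort: a mixed-risk population over a 30-day
# surveillance period with 90 days of generated history.
n_patients: 2000
period_days: 30
pre_period_days: 90
archetype_mixture:
  BASELINE: 0.72
  FREQUENT_UTILIZER: 0.12
  SUBSTANCE_USE: 0.15
  OVERDOSE_HISTORY: 0.01
encounter_rate_per_30d:
  BASELINE: 0.6
  FREQUENT_UTILIZER: 4.0
  SUBSTANCE_USE: 0.9
  OVERDOSE_HISTORY: 1.0
facility_mix:
  ED: 0.15
  URGENT_CARE: 0.10
  INPATIENT: 0.05
  OUTPATIENT: 0.55
  PHONE: 0.10
  OTHER: 0.05
p_prescribe_given_encounter:
  ED: 0.35
  URGENT_CARE: 0.30
  INPATIENT: 0.40
  OUTPATIENT: 0.20
  PHONE: 0.10
  OTHER: 0.05
drug_class_mix:
  OPIOID_ONLY: 0.73
  BENZO_ONLY: 0.23
  BOTH: 0.04
duration_days_distribution:
  kind: uniform
  lo: 5
  hi: 30
p_onsite_opioid_admin_ED_UC: 0.6
p_admitted_given_ED: 0.15
tox_positive_rates:
  BLOOD_ALCOHOL: 0.30
  COCAINE: 0.25
  MARIJUANA: 0.50
age_band_mix:
  UNDER_18: 0.03
  MID: 0.73
  OVER_65: 0.24
seed: 1
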