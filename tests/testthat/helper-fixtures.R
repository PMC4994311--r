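# Shared fixtures and independent brute-force oracles. The oracles scan
# full tables with explicit loops and never share code with the package's
# evaluators.

T0 <- parse_utc("2015-04-01T00:00:00Z")

at_days <- function(days) T0 + days * 86400

# A small hand-built store with one patient of each risk pattern.
tiny_store <- function() {
  patients <- tibble::tibble(
    patient_id = c("clean", "refill", "visits", "od", "tox"),
    date_of_birth = as.Date(c("1980-06-15", "1990-01-01", "1955-03-02",
                              "2000-11-30", "1948-07-04")))
  enc <- tibble::tibble(
    encounter_id = c("c1",
                     "r1", "r2",
                     "v1", "v2", "v3", "v4",
                     "o0", "o1",
                     "t1"),
    patient_id = c("clean",
                   "refill", "refill",
                   "visits", "visits", "visits", "visits",
                   "od", "od",
                   "tox"),
    start_at = c(at_days(10),
                 at_days(-3), at_days(10),
                 at_days(-20), at_days(-5), at_days(-2), at_days(10),
                 at_days(-400), at_days(10),
                 at_days(10)),
    facility_type = c("OUTPATIENT",
                      "OUTPATIENT", "OUTPATIENT",
                      "ED", "URGENT_CARE", "ED", "OUTPATIENT",
                      "ED", "OUTPATIENT",
                      "OUTPATIENT"),
    disposition = c("NOT_APPLICABLE",
                    "NOT_APPLICABLE", "NOT_APPLICABLE",
                    "DISCHARGED", "DISCHARGED", "ADMITTED", "NOT_APPLICABLE",
                    "DISCHARGED", "NOT_APPLICABLE",
                    "NOT_APPLICABLE"),
    is_overdose_presentation = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                                 FALSE, TRUE, FALSE, FALSE))
  rx <- tibble::tibble(
    rx_id = c("rx-clean", "rx-prior", "rx-index-refill", "rx-visits",
              "rx-od", "rx-tox"),
    patient_id = c("clean", "refill", "refill", "visits", "od", "tox"),
    encounter_id = c("c1", "r1", "r2", "v4", "o1", "t1"),
    written_at = c(at_days(10), at_days(-3), at_days(10), at_days(10),
                   at_days(10), at_days(10)),
    drug_class = c("OPIOID", "OPIOID", "OPIOID", "OPIOID", "BENZODIAZEPINE",
                   "OPIOID"),
    duration_days = c(5, 30, 10, 5, 5, 5),
    prescriber_id = sprintf("prc%02d", 1:6),
    drug_name = NA_character_)
  ma <- tibble::tibble(
    patient_id = c("visits", "visits", "visits"),
    encounter_id = c("v1", "v2", "v3"),
    administered_at = c(at_days(-20) + 600, at_days(-5) + 600, at_days(-2) + 600),
    drug_class = c("OPIOID", "OPIOID", "OPIOID"))
  tx <- tibble::tibble(
    patient_id = c("tox", "tox", "clean"),
    collected_at = c(at_days(-700), at_days(-1), at_days(-1)),
    analyte = c("MARIJUANA", "BLOOD_ALCOHOL", "COCAINE"),
    positive = c(TRUE, TRUE, FALSE))
  event_store(patients, enc, rx, ma, tx)
}

# Brute-force five-flag oracle: full-history scan, explicit loops.
oracle_flags <- function(store, rx_id, cfg = trigger_config()) {
  rx <- as.data.frame(store$prescriptions)
  enc <- as.data.frame(store$encounters)
  ma <- as.data.frame(store$med_admins)
  tx <- as.data.frame(store$tox_screens)
  i <- which(rx$rx_id == rx_id)
  t <- rx$written_at[i]; pid <- rx$patient_id[i]; enc_id <- rx$encounter_id[i]

  early <- FALSE
  n_hist <- 0L
  for (j in seq_len(nrow(rx))) {
    if (rx$patient_id[j] != pid || rx$rx_id[j] == rx_id) next
    el <- (as.numeric(t) - as.numeric(rx$written_at[j])) / 86400
    if (!is.na(rx$duration_days[j]) && rx$duration_days[j] > 0 &&
        el >= 0 && el < rx$duration_days[j] &&
        1 - el / rx$duration_days[j] > cfg$remaining_fraction_threshold) {
      early <- TRUE
    }
    if (el > 0 && el <= cfg$rx_window_days) n_hist <- n_hist + 1L
  }

  n_visits <- 0L; overdose <- FALSE
  for (j in seq_len(nrow(enc))) {
    if (enc$patient_id[j] != pid) next
    el <- (as.numeric(t) - as.numeric(enc$start_at[j])) / 86400
    if (enc$is_overdose_presentation[j] && el > 0) overdose <- TRUE
    if (enc$encounter_id[j] == enc_id) next
    if (enc$facility_type[j] %in% c("ED", "URGENT_CARE") &&
        enc$disposition[j] != "ADMITTED" &&
        el > 0 && el <= cfg$ed_uc_window_days) {
      has_opioid <- FALSE
      for (k in seq_len(nrow(ma))) {
        if (ma$encounter_id[k] == enc$encounter_id[j] &&
            ma$drug_class[k] == "OPIOID") has_opioid <- TRUE
      }
      if (has_opioid) n_visits <- n_visits + 1L
    }
  }

  tox <- FALSE
  for (j in seq_len(nrow(tx))) {
    if (tx$patient_id[j] == pid && tx$positive[j] &&
        as.numeric(tx$collected_at[j]) < as.numeric(t)) tox <- TRUE
  }

  c(EARLY_REFILL = early,
    ED_UC_ONSITE = n_visits >= cfg$min_ed_uc_visits,
    RX_HISTORY = n_hist >= cfg$min_prescriptions,
    OVERDOSE = overdose,
    TOX_SCREEN = tox)
}

# Alert-log met flags as a matrix, via the oracle, for every in-period rx.
oracle_log_flags <- function(store, period_start, period_end,
                             cfg = trigger_config()) {
  rx <- store$prescriptions
  keep <- rx$written_at >= period_start & rx$written_at < period_end
  ids <- rx$rx_id[keep][order(rx$written_at[keep], rx$rx_id[keep])]
  t(vapply(ids, function(id) oracle_flags(store, id, cfg), logical(5)))
}

# Cohorts are expensive to simulate; build each size once per test run.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed = 42) {
  key <- sprintf("n%d_s%d", n, seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(cohort_config(n_patients = n, seed = seed))
  }
  .cohort_cache[[key]]
}

cohort_period <- function(store) attr(store, "period")
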