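test_that("percentages are rounded half-up at two decimals", {
  expect_equal(format_percent(8358, 61747), "13.54")
  expect_equal(format_percent(2314, 61747), "3.75")
  expect_equal(format_percent(0, 10), "0.00")
  expect_equal(format_percent(1, 8), "12.50")
  expect_equal(format_percent(1, 800), "0.13")   # 0.125: half rounds up
  expect_equal(format_percent(10, 10), "100.00")
  expect_error(format_percent(1, 0), "positive")
  expect_error(format_percent(5, 4), "count")
})

test_that("encounter summaries union criteria across an encounter's prescriptions", {
  # one encounter, two prescriptions: one trips early refill, the other
  # tox screen -> a single summary with both criteria
  enc_start <- at_days(0)
  store <- event_store(
    patients = tibble::tibble(patient_id = "p",
                              date_of_birth = as.Date("1970-01-01")),
    encounters = tibble::tibble(
      encounter_id = c("e-old", "e-now"), patient_id = "p",
      start_at = c(at_days(-3), enc_start),
      facility_type = c("OUTPATIENT", "ED"),
      disposition = c("NOT_APPLICABLE", "DISCHARGED"),
      is_overdose_presentation = FALSE),
    prescriptions = tibble::tibble(
      rx_id = c("rx-old", "rx-a", "rx-b"), patient_id = "p",
      encounter_id = c("e-old", "e-now", "e-now"),
      written_at = c(at_days(-3), enc_start, enc_start + 3600),
      drug_class = c("OPIOID", "OPIOID", "BENZODIAZEPINE"),
      duration_days = c(10, 7, 7), prescriber_id = "prc",
      drug_name = NA_character_),
    tox_screens = tibble::tibble(
      patient_id = "p", collected_at = enc_start + 1800,
      analyte = "COCAINE", positive = TRUE))
  log <- run_surveillance(store, at_days(-1), at_days(1))
  expect_equal(nrow(log), 2)  # rx-a and rx-b
  summ <- collect_prescribing_encounters(log, store)
  expect_equal(nrow(summ), 1)
  expect_true(summ$early_refill)   # rx-old: 3 of 10 days elapsed
  expect_true(summ$tox_screen)     # positive screen before rx-b only
  expect_equal(summ$n_criteria, 2L)
  expect_equal(summ$drug_class_bucket, "BOTH")
  expect_equal(summ$facility_bucket, "ED_URGENT_CARE")
  expect_equal(summ$patient_age_band, "18_64")
  expect_true(summ$cocaine)
  expect_false(summ$bac)
})

test_that("summary conservation: one row per distinct encounter", {
  expect_equal(nrow(collect_prescribing_encounters(
    run_surveillance(event_store(), at_days(0), at_days(1)), event_store())), 0)

  store <- cached_cohort(300, seed = 21)
  period <- cohort_period(store)
  log <- run_surveillance(store, period[1], period[2])
  summ <- collect_prescribing_encounters(log, store)
  expect_equal(nrow(summ), length(unique(log$encounter_id)))
  expect_gt(nrow(log), nrow(summ))  # some encounters carry several rx

  # an encounter flags iff at least one of its records fired
  fired_enc <- unique(log$encounter_id[log$fired])
  expect_setequal(summ$encounter_id[summ$n_criteria >= 1], fired_enc)

  bad_log <- log
  bad_log$encounter_id[1] <- "ghost"
  expect_error(collect_prescribing_encounters(bad_log, store), "ghost")
})

test_that("report sections are conserved and internally consistent", {
  store <- cached_cohort(300, seed = 21)
  period <- cohort_period(store)
  log <- run_surveillance(store, period[1], period[2])
  summ <- collect_prescribing_encounters(log, store)
  rep <- build_report(summ, store, period[1], period[2],
                      n_prescriptions = nrow(log))
  n <- rep$n_prescribing_encounters
  expect_equal(sum(rep$criteria_count$n), n)
  expect_equal(sum(rep$age$n), n)
  expect_equal(sum(rep$facility$n), n)
  expect_equal(sum(rep$drug_class$n), n)
  expect_equal(rep$n_encounters_flagged, sum(rep$criteria_count$n[-1]))
  # >=1-criterion rate complements the zero-criteria share within rounding
  expect_lt(abs(as.numeric(rep$alert_rate_prescribing_pct) -
                  (100 - as.numeric(rep$criteria_count$pct[1]))), 0.011)
  # per-facility alert rates cover all in-period non-phone encounters
  in_period <- store$encounters$start_at >= period[1] &
    store$encounters$start_at < period[2]
  expect_equal(sum(rep$facility_alert_rates$n_encounters),
               sum(in_period & store$encounters$facility_type != "PHONE"))
})

test_that("a hand-built criteria distribution yields the expected alert rate", {
  n_by_crit <- c(`0` = 39L, `1` = 8L, `2` = 3L)
  summ <- tibble::tibble(
    encounter_id = sprintf("e%02d", 1:50),
    patient_id = sprintf("p%02d", 1:50),
    patient_age_band = "18_64", facility_bucket = "ED_URGENT_CARE",
    drug_class_bucket = "OPIOID_ONLY",
    early_refill = rep(c(FALSE, TRUE, TRUE), n_by_crit),
    ed_uc_onsite = FALSE,
    rx_history = rep(c(FALSE, FALSE, TRUE), n_by_crit),
    overdose = FALSE, tox_screen = FALSE,
    n_criteria = rep(c(0L, 1L, 2L), n_by_crit),
    bac = FALSE, cocaine = FALSE, marijuana = FALSE)
  rep <- build_report(summ)
  expect_equal(rep$alert_rate_prescribing_pct, "22.00")  # 11 of 50
  expect_equal(rep$criteria_count$n[1:3], c(39L, 8L, 3L))
})

test_that("empty summaries give an all-zero report", {
  rep <- build_report(collect_prescribing_encounters(
    run_surveillance(event_store(), at_days(0), at_days(1)), event_store()))
  expect_equal(rep$n_prescribing_encounters, 0)
  expect_true(all(rep$criteria$n == 0))
  expect_equal(rep$alert_rate_prescribing_pct, "0.00")
  expect_equal(unique(rep$age$pct), "0.00")
})

test_that("report exports round-trip (JSON) and keep structure (CSV, text)", {
  store <- cached_cohort(100, seed = 11)
  period <- cohort_period(store)
  log <- run_surveillance(store, period[1], period[2])
  rep <- build_report(collect_prescribing_encounters(log, store),
                      store, period[1], period[2], n_prescriptions = nrow(log))
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".txt")
  export_report(rep, fj, "JSON")
  export_report(rep, fc, "CSV")
  export_report(rep, ft, "TEXT_TABLE")

  back <- jsonlite::fromJSON(fj)
  expect_equal(back$n_prescribing_encounters, rep$n_prescribing_encounters)
  expect_equal(back$criteria_count$n, rep$criteria_count$n)
  expect_equal(back$criteria$pct, rep$criteria$pct)
  expect_equal(back$facility$n, rep$facility$n)

  csv <- readr::read_csv(fc, show_col_types = FALSE)
  # one row per statistic: totals + 3 age + 4 facility + 3 class + 6
  # criteria-count + 5 criteria + 3 analytes + alert rate
  expect_equal(nrow(csv), 2 + 3 + 4 + 3 + 6 + 5 + 3 + 1)

  txt <- readLines(ft)
  expect_true(any(grepl("Number of criteria met", txt)))
  expect_true(any(grepl("Positive tox screen", txt)))
})
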