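# One-patient store with a single prior prescription, for refill arithmetic.
refill_story <- function(prior_duration, prior_days_ago, t_eval_days = 0) {
  event_store(
    patients = tibble::tibble(patient_id = "p",
                              date_of_birth = as.Date("1970-01-01")),
    encounters = tibble::tibble(
      encounter_id = c("e-prior", "e-index"), patient_id = "p",
      start_at = c(at_days(t_eval_days - prior_days_ago), at_days(t_eval_days)),
      facility_type = "OUTPATIENT", disposition = "NOT_APPLICABLE",
      is_overdose_presentation = FALSE),
    prescriptions = tibble::tibble(
      rx_id = c("rx-prior", "rx-index"), patient_id = "p",
      encounter_id = c("e-prior", "e-index"),
      written_at = c(at_days(t_eval_days - prior_days_ago), at_days(t_eval_days)),
      drug_class = "OPIOID", duration_days = c(prior_duration, 7),
      prescriber_id = "prc", drug_name = NA_character_))
}

test_that("a 10-day supply written 3 days ago has 0.7 remaining and fires at both thresholds", {
  store <- refill_story(prior_duration = 10, prior_days_ago = 3)
  for (thr in c(0.30, 0.50)) {
    d <- eval_early_refill(store, "p", at_days(0),
                           trigger_config(remaining_fraction_threshold = thr),
                           index_rx_id = "rx-index")
    expect_true(d$met)
    expect_equal(d$evidence$remaining_fraction, 0.7)
  }
})

test_that("early refill honors the strict remaining-fraction inequality", {
  # duration 10, elapsed 6 -> remaining 0.4: not > 0.5
  expect_false(eval_early_refill(refill_story(10, 6), "p", at_days(0),
                                 trigger_config(), "rx-index")$met)
  # elapsed 4 -> remaining 0.6 > 0.5
  expect_true(eval_early_refill(refill_story(10, 4), "p", at_days(0),
                                trigger_config(), "rx-index")$met)
  # exactly at the threshold is not strict excess: elapsed 5 -> 0.5
  expect_false(eval_early_refill(refill_story(10, 5), "p", at_days(0),
                                 trigger_config(), "rx-index")$met)
  # exhausted supply never qualifies
  expect_false(eval_early_refill(refill_story(10, 12), "p", at_days(0),
                                 trigger_config(), "rx-index")$met)
  # no prior prescriptions
  expect_false(eval_early_refill(tiny_store(), "clean", at_days(10),
                                 trigger_config(), "rx-clean")$met)
})

test_that("prescriptions without usable duration are skipped with a warning note", {
  store <- refill_story(10, 3)
  store$prescriptions$duration_days[1] <- NA
  d <- eval_early_refill(store, "p", at_days(0), trigger_config(), "rx-index")
  expect_false(d$met)
  expect_match(d$warnings, "rx-prior")
})

test_that("ED/UC visit counting excludes admissions and the index encounter", {
  store <- tiny_store()
  cfg <- trigger_config()
  # v1 (t-20d) and v2 (t-5d) qualify; v3 is ADMITTED
  d <- eval_ed_uc_onsite(store, "visits", at_days(10), cfg, "v4")
  expect_true(d$met)
  expect_setequal(d$evidence$encounter_id, c("v1", "v2"))
  # with minimum 3 the same history does not fire
  expect_false(eval_ed_uc_onsite(store, "visits", at_days(10),
                                 trigger_config(min_ed_uc_visits = 3), "v4")$met)
  # zero history
  expect_false(eval_ed_uc_onsite(store, "clean", at_days(10), cfg, "c1")$met)
  # window boundary: visit exactly 30 days back is in; at t_eval it is not
  d30 <- eval_ed_uc_onsite(store, "visits", at_days(10), cfg, "none")
  expect_setequal(d30$evidence$encounter_id, c("v1", "v2"))
  d_at_v1 <- eval_ed_uc_onsite(store, "visits", at_days(-20) + 30 * 86400,
                               cfg, "none")
  expect_true("v1" %in% d_at_v1$evidence$encounter_id)  # exactly t-30d
  d_at_now <- eval_ed_uc_onsite(store, "visits", at_days(-20), cfg, "none")
  expect_false("v1" %in% d_at_now$evidence$encounter_id)  # at t_eval
})

test_that("prescription-history counting respects the window and the index exclusion", {
  mk <- function(days_ago) {
    n <- length(days_ago)
    event_store(
      patients = tibble::tibble(patient_id = "p",
                                date_of_birth = as.Date("1970-01-01")),
      encounters = tibble::tibble(
        encounter_id = c(sprintf("e%d", seq_len(n)), "e-ix"), patient_id = "p",
        start_at = c(at_days(-days_ago), at_days(0)),
        facility_type = "OUTPATIENT", disposition = "NOT_APPLICABLE",
        is_overdose_presentation = FALSE),
      prescriptions = tibble::tibble(
        rx_id = c(sprintf("rx%d", seq_len(n)), "rx-ix"), patient_id = "p",
        encounter_id = c(sprintf("e%d", seq_len(n)), "e-ix"),
        written_at = c(at_days(-days_ago), at_days(0)),
        drug_class = rep(c("OPIOID", "BENZODIAZEPINE"), length.out = n + 1),
        duration_days = 5, prescriber_id = "prc", drug_name = NA_character_))
  }
  expect_false(eval_rx_history(mk(numeric(0)), "p", at_days(0),
                               trigger_config(), "rx-ix")$met)
  expect_true(eval_rx_history(mk(c(1, 10, 29)), "p", at_days(0),
                              trigger_config(), "rx-ix")$met)
  # one of the three falls just outside the 30-day window
  expect_false(eval_rx_history(mk(c(1, 10, 31)), "p", at_days(0),
                               trigger_config(), "rx-ix")$met)
  # exactly 30 days back is inside the closed lower bound
  expect_true(eval_rx_history(mk(c(1, 10, 30)), "p", at_days(0),
                              trigger_config(), "rx-ix")$met)
})

test_that("overdose and tox-screen lookbacks are lifetime and one-sided", {
  store <- tiny_store()
  expect_true(eval_overdose_history(store, "od", at_days(10))$met)   # 410 d back
  expect_false(eval_overdose_history(store, "clean", at_days(10))$met)
  expect_false(eval_overdose_history(store, "od", at_days(-500))$met) # future only

  d <- eval_tox_screen(store, "tox", at_days(10))
  expect_true(d$met)
  expect_setequal(d$evidence$analyte, c("MARIJUANA", "BLOOD_ALCOHOL"))
  expect_false(eval_tox_screen(store, "clean", at_days(10))$met)  # negative only
  expect_false(eval_tox_screen(store, "tox", at_days(-800))$met)  # before screens
})

test_that("evaluate_triggers composes the five evaluators and counts them", {
  store <- tiny_store()
  res <- evaluate_triggers(store, "rx-clean")
  expect_equal(res$n_criteria_met, 0L)

  res <- evaluate_triggers(store, "rx-tox")
  expect_equal(unname(criteria_met(res)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))

  for (id in store$prescriptions$rx_id) {
    res <- evaluate_triggers(store, id)
    rx <- store$prescriptions[store$prescriptions$rx_id == id, ]
    singles <- c(
      eval_early_refill(store, rx$patient_id, rx$written_at,
                        trigger_config(), id)$met,
      eval_ed_uc_onsite(store, rx$patient_id, rx$written_at,
                        trigger_config(), rx$encounter_id)$met,
      eval_rx_history(store, rx$patient_id, rx$written_at,
                      trigger_config(), id)$met,
      eval_overdose_history(store, rx$patient_id, rx$written_at)$met,
      eval_tox_screen(store, rx$patient_id, rx$written_at)$met)
    expect_equal(unname(criteria_met(res)), singles)
    expect_equal(res$n_criteria_met, sum(singles))
  }
  expect_error(evaluate_triggers(store, "rx-nonexistent"), "not in store")
})

test_that("the index prescription never serves as its own evidence", {
  store <- refill_story(10, 3)
  d <- eval_early_refill(store, "p", at_days(0), trigger_config(), "rx-index")
  expect_false("rx-index" %in% d$evidence$rx_id)
  d <- eval_rx_history(store, "p", at_days(0), trigger_config(), "rx-index")
  expect_false("rx-index" %in% d$evidence$rx_id)
})

test_that("evaluators match the brute-force oracle on random cohorts", {
  store <- cached_cohort(300, seed = 21)
  period <- cohort_period(store)
  for (cfg in list(trigger_config(), trigger_config(profile = "initial"))) {
    log <- run_surveillance(store, period[1], period[2], cfg)
    want <- oracle_log_flags(store, period[1], period[2], cfg)
    got <- as.matrix(log[, c("early_refill", "ed_uc_onsite", "rx_history",
                             "overdose", "tox_screen")])
    dimnames(got) <- dimnames(want)
    expect_equal(got, want)
  }
})

test_that("relaxing any threshold never unmakes a met trigger", {
  store <- cached_cohort(300, seed = 21)
  period <- cohort_period(store)
  strict <- run_surveillance(store, period[1], period[2], trigger_config(
    remaining_fraction_threshold = 0.5, min_ed_uc_visits = 3,
    min_prescriptions = 4))
  relaxed <- run_surveillance(store, period[1], period[2], trigger_config(
    remaining_fraction_threshold = 0.3, min_ed_uc_visits = 2,
    min_prescriptions = 3))
  expect_true(all(relaxed$early_refill >= strict$early_refill))
  expect_true(all(relaxed$ed_uc_onsite >= strict$ed_uc_onsite))
  expect_true(all(relaxed$rx_history >= strict$rx_history))
  expect_identical(relaxed$overdose, strict$overdose)
  expect_identical(relaxed$tox_screen, strict$tox_screen)
})

test_that("trigger profiles load from the shipped YAML files", {
  final <- read_trigger_config(system.file("extdata", "triggers_final.yaml",
                                           package = "rxalert"))
  initial <- read_trigger_config(system.file("extdata", "triggers_initial.yaml",
                                             package = "rxalert"))
  expect_equal(final$remaining_fraction_threshold, 0.50)
  expect_equal(final$min_ed_uc_visits, 2L)
  expect_equal(initial$remaining_fraction_threshold, 0.30)
  expect_equal(initial$min_ed_uc_visits, 3L)
  expect_equal(final$min_prescriptions, initial$min_prescriptions)
})
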