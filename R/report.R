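AGE_BANDS <- c("UNDER_18", "18_64", "65_PLUS")
FACILITY_BUCKETS <- c("ED_URGENT_CARE", "INPATIENT_DISCHARGE",
                      "OUTPATIENT_INCL_PHONE", "OTHER")
CLASS_BUCKETS <- c("OPIOID_ONLY", "BENZO_ONLY", "BOTH")

facility_bucket_of <- function(facility_type) {
  dplyr::case_match(facility_type,
    c("ED", "URGENT_CARE") ~ "ED_URGENT_CARE",
    "INPATIENT" ~ "INPATIENT_DISCHARGE",
    c("OUTPATIENT", "PHONE") ~ "OUTPATIENT_INCL_PHONE",
    "OTHER" ~ "OTHER")
}

age_band_of <- function(dob, at) {
  age <- floor(elapsed_days(as.POSIXct(as.character(dob), tz = "UTC"), at) / 365.25)
  dplyr::case_when(age < 18 ~ "UNDER_18", age >= 65 ~ "65_PLUS",
                   .default = "18_64")
}

#' Format a percentage the way surveillance tables print it
#'
#' `100 * count / denom`, rounded half-up to two decimals (so e.g.
#' 3.7475 prints as `"3.75"`, not the round-half-even `"3.74"`).
#'
#' @param count Non-negative integer, `count <= denom`.
#' @param denom Positive integer denominator.
#' @return Character scalar like `"13.54"`.
#' @export
#' @examples
#' format_percent(8358, 61747)  # "13.54"
format_percent <- function(count, denom) {
  stopifnot(length(count) == length(denom) || length(denom) == 1)
  if (any(denom == 0)) stop("denominator must be positive", call. = FALSE)
  if (any(count < 0 | count > denom)) {
    stop("count must be in [0, denom]", call. = FALSE)
  }
  sprintf("%.2f", round_half_up(100 * count / denom, 2))
}

# Half-up decimal rounding; the 1e-9 nudge guards against binary
# representation of exact decimal halves (e.g. 12.5 stored as 12.4999...).
round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Summarise prescribing encounters from an alert log
#'
#' A prescribing encounter is any encounter in which at least one opioid
#' or benzodiazepine prescription was initiated. This collapses a
#' per-prescription alert log to one row per distinct encounter:
#' criteria met are the union over the encounter's evaluations, the drug
#' class bucket reflects all classes prescribed at the encounter, age is
#' computed at the encounter start, and positive-analyte flags are
#' unioned likewise.
#'
#' @param alert_log An `alert_log` from [run_surveillance()].
#' @param store The [event_store()] the log was computed from.
#' @return Tibble with one row per encounter: `encounter_id`,
#'   `patient_id`, `patient_age_band`, `facility_bucket`,
#'   `drug_class_bucket`, the five criterion flags, `n_criteria`, and
#'   `bac`/`cocaine`/`marijuana` analyte flags.
#' @export
collect_prescribing_encounters <- function(alert_log, store) {
  stopifnot(inherits(store, "event_store"))
  unknown <- setdiff(alert_log$encounter_id, store$encounters$encounter_id)
  if (length(unknown) > 0) {
    stop("alert log references unknown encounter(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(alert_log) == 0) return(encounter_summary_prototype())
  grp <- dplyr::group_by(tibble::as_tibble(alert_log), .data$encounter_id)
  summ <- dplyr::summarise(grp,
    patient_id = dplyr::first(.data$patient_id),
    early_refill = any(.data$early_refill),
    ed_uc_onsite = any(.data$ed_uc_onsite),
    rx_history = any(.data$rx_history),
    overdose = any(.data$overdose),
    tox_screen = any(.data$tox_screen),
    drug_class_bucket = class_bucket(.data$drug_class),
    analytes = paste(.data$tox_analytes[nzchar(.data$tox_analytes)], collapse = ";"),
    .groups = "drop")
  enc <- store$encounters[match(summ$encounter_id, store$encounters$encounter_id), ]
  dob <- store$patients$date_of_birth[match(summ$patient_id, store$patients$patient_id)]
  tibble::tibble(
    encounter_id = summ$encounter_id,
    patient_id = summ$patient_id,
    patient_age_band = age_band_of(dob, enc$start_at),
    facility_bucket = facility_bucket_of(enc$facility_type),
    drug_class_bucket = summ$drug_class_bucket,
    early_refill = summ$early_refill, ed_uc_onsite = summ$ed_uc_onsite,
    rx_history = summ$rx_history, overdose = summ$overdose,
    tox_screen = summ$tox_screen,
    n_criteria = as.integer(summ$early_refill + summ$ed_uc_onsite +
                              summ$rx_history + summ$overdose + summ$tox_screen),
    bac = grepl("BLOOD_ALCOHOL", summ$analytes),
    cocaine = grepl("COCAINE", summ$analytes),
    marijuana = grepl("MARIJUANA", summ$analytes))
}

class_bucket <- function(classes) {
  has_op <- any(classes == "OPIOID"); has_bz <- any(classes == "BENZODIAZEPINE")
  if (has_op && has_bz) "BOTH" else if (has_bz) "BENZO_ONLY" else "OPIOID_ONLY"
}

encounter_summary_prototype <- function() {
  tibble::tibble(encounter_id = character(), patient_id = character(),
                 patient_age_band = character(), facility_bucket = character(),
                 drug_class_bucket = character(), early_refill = logical(),
                 ed_uc_onsite = logical(), rx_history = logical(),
                 overdose = logical(), tox_screen = logical(),
                 n_criteria = integer(), bac = logical(), cocaine = logical(),
                 marijuana = logical())
}

#' Build the surveillance report
#'
#' Aggregates prescribing-encounter summaries into the standard
#' surveillance table: age-band, facility and drug-class breakdowns, the
#' criteria-count distribution (0-5), per-criterion prevalences with
#' toxicology analyte sub-rows (sub-rows may overlap, so they need not
#' sum to the parent row), and alert rates. All percentages are
#' round-half-up at two decimals over the prescribing-encounter
#' denominator.
#'
#' Because the alert-counting unit of an EMR can be ambiguous, the report
#' exposes every candidate rate with its denominator explicitly: the
#' share of prescribing encounters with at least one criterion met, and —
#' when `store` and `period` are supplied — the share of all in-period
#' encounters (phone encounters excluded from that denominator, since
#' phone contacts are too inconsistently documented to give an accurate
#' total) plus per-facility-bucket alert rates.
#'
#' @param summaries Tibble from [collect_prescribing_encounters()].
#' @param store Optional [event_store()] for all-encounter denominators.
#' @param period_start,period_end Optional period bounds for the
#'   all-encounter denominator.
#' @param n_prescriptions Optional count of prescriptions behind the
#'   summaries (carried into the report header).
#' @return Object of class `surveillance_report`: a list of tibbles
#'   (`age`, `facility`, `drug_class`, `criteria_count`, `criteria`,
#'   `analytes`) plus scalar totals and rates.
#' @export
build_report <- function(summaries, store = NULL, period_start = NULL,
                         period_end = NULL, n_prescriptions = NA_integer_) {
  n_enc <- nrow(summaries)
  count_tab <- function(values, levels) {
    cnt <- table(factor(values, levels = levels))
    tibble::tibble(level = levels, n = as.integer(cnt),
                   pct = if (n_enc > 0) format_percent(as.integer(cnt), n_enc)
                         else "0.00")
  }
  crit_cols <- c(early_refill = "EARLY_REFILL", ed_uc_onsite = "ED_UC_ONSITE",
                 rx_history = "RX_HISTORY", overdose = "OVERDOSE",
                 tox_screen = "TOX_SCREEN")
  crit_n <- vapply(names(crit_cols), function(cl) sum(summaries[[cl]]), integer(1))
  crit <- tibble::tibble(
    criterion = unname(crit_cols), n = as.integer(crit_n),
    pct = if (n_enc > 0) format_percent(as.integer(crit_n), n_enc) else "0.00")
  analyte_n <- c(BLOOD_ALCOHOL = sum(summaries$bac),
                 COCAINE = sum(summaries$cocaine),
                 MARIJUANA = sum(summaries$marijuana))
  analytes <- tibble::tibble(
    analyte = names(analyte_n), n = as.integer(analyte_n),
    pct = if (n_enc > 0) format_percent(as.integer(analyte_n), n_enc) else "0.00")
  n_flagged <- sum(summaries$n_criteria >= 1)

  report <- list(
    n_prescribing_encounters = n_enc,
    n_prescriptions = n_prescriptions,
    age = count_tab(summaries$patient_age_band, AGE_BANDS),
    facility = count_tab(summaries$facility_bucket, FACILITY_BUCKETS),
    drug_class = count_tab(summaries$drug_class_bucket, CLASS_BUCKETS),
    criteria_count = {
      cnt <- table(factor(summaries$n_criteria, levels = 0:5))
      tibble::tibble(n_criteria = 0:5, n = as.integer(cnt),
                     pct = if (n_enc > 0) format_percent(as.integer(cnt), n_enc)
                           else "0.00")
    },
    criteria = crit,
    analytes = analytes,
    n_encounters_flagged = as.integer(n_flagged),
    n_patients_flagged = length(unique(summaries$patient_id[summaries$n_criteria >= 1])),
    alert_rate_prescribing_pct = if (n_enc > 0) format_percent(n_flagged, n_enc) else "0.00",
    alert_rate_all_encounters_pct = NA_character_,
    facility_alert_rates = NULL
  )

  if (!is.null(store) && !is.null(period_start) && !is.null(period_end)) {
    period_start <- parse_utc(period_start); period_end <- parse_utc(period_end)
    enc <- store$encounters
    in_period <- enc$start_at >= period_start & enc$start_at < period_end
    # phone encounters lack a reliable denominator; exclude them from the
    # all-encounter rate (prescribing phone encounters still count above)
    denom_all <- sum(in_period & enc$facility_type != "PHONE")
    flagged_enc <- summaries$encounter_id[summaries$n_criteria >= 1]
    flagged_nonphone <- sum(enc$encounter_id %in% flagged_enc &
                              enc$facility_type != "PHONE")
    report$n_all_encounters <- as.integer(denom_all)
    report$alert_rate_all_encounters_pct <-
      if (denom_all > 0) format_percent(flagged_nonphone, denom_all) else NA_character_
    bucket <- facility_bucket_of(enc$facility_type[in_period])
    bucket[enc$facility_type[in_period] == "PHONE"] <- NA  # separated out
    fl <- enc$encounter_id[in_period] %in% flagged_enc
    report$facility_alert_rates <- dplyr::bind_rows(lapply(
      FACILITY_BUCKETS, function(b) {
        idx <- which(!is.na(bucket) & bucket == b)
        tibble::tibble(facility_bucket = b,
                       n_encounters = length(idx),
                       n_alerts = sum(fl[idx]),
                       pct = if (length(idx) > 0)
                         format_percent(sum(fl[idx]), length(idx)) else NA_character_)
      }))
  }
  structure(report, class = "surveillance_report")
}

#' @export
print.surveillance_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

format_report_text <- function(x) {
  row <- function(label, n, pct) sprintf("  %-38s %8s (%s %%)", label,
                                         format(n, big.mark = ","), pct)
  lines <- c(
    sprintf("Controlled substance prescribing encounters: n = %s",
            format(x$n_prescribing_encounters, big.mark = ",")),
    if (!is.na(x$n_prescriptions))
      sprintf("Prescriptions written: %s", format(x$n_prescriptions, big.mark = ",")),
    "Age of patient",
    row("< 18", x$age$n[1], x$age$pct[1]),
    row("18-64", x$age$n[2], x$age$pct[2]),
    row("65+", x$age$n[3], x$age$pct[3]),
    "Facility type",
    row("ED/Urgent Care", x$facility$n[1], x$facility$pct[1]),
    row("Inpatient Discharge", x$facility$n[2], x$facility$pct[2]),
    row("Outpatient including phone calls", x$facility$n[3], x$facility$pct[3]),
    row("Other", x$facility$n[4], x$facility$pct[4]),
    "Class of drug",
    row("Opiate", x$drug_class$n[1], x$drug_class$pct[1]),
    row("Benzodiazepine", x$drug_class$n[2], x$drug_class$pct[2]),
    row("Both", x$drug_class$n[3], x$drug_class$pct[3]),
    "Number of criteria met (of any combination)",
    unlist(lapply(1:6, function(i) row(as.character(i - 1L),
                                       x$criteria_count$n[i],
                                       x$criteria_count$pct[i]))),
    "Criteria met",
    row("Prescription with >50 % remaining", x$criteria$n[1], x$criteria$pct[1]),
    row("2+ visits with onsite administration", x$criteria$n[2], x$criteria$pct[2]),
    row("3+ prescriptions in past 30 days", x$criteria$n[3], x$criteria$pct[3]),
    row("Positive tox screen", x$criteria$n[5], x$criteria$pct[5]),
    row("  BAC", x$analytes$n[1], x$analytes$pct[1]),
    row("  Cocaine", x$analytes$n[2], x$analytes$pct[2]),
    row("  Marijuana", x$analytes$n[3], x$analytes$pct[3]),
    row("Previous presentation for overdose", x$criteria$n[4], x$criteria$pct[4]),
    sprintf("Alert rate among prescribing encounters: %s %%",
            x$alert_rate_prescribing_pct))
  if (!is.na(x$alert_rate_all_encounters_pct)) {
    lines <- c(lines, sprintf(
      "Alert rate among all encounters (phone excluded): %s %%",
      x$alert_rate_all_encounters_pct))
  }
  lines
}

#' Export a surveillance report
#'
#' `JSON` is loss-free (reloadable with [jsonlite::fromJSON()]); `CSV` is
#' a long table of one statistic per row; `TEXT_TABLE` mirrors the
#' printed surveillance-table row structure.
#'
#' @param report A `surveillance_report`.
#' @param path Output file.
#' @param format `"JSON"`, `"CSV"`, or `"TEXT_TABLE"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("JSON", "CSV", "TEXT_TABLE")) {
  format <- match.arg(format)
  if (format == "JSON") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (format == "CSV") {
    readr::write_csv(report_long(report), path, progress = FALSE)
  } else {
    writeLines(format_report_text(report), path)
  }
  invisible(path)
}

report_long <- function(x) {
  sect <- function(section, level, n, pct) {
    tibble::tibble(section = section, level = as.character(level),
                   n = as.integer(n), pct = as.character(pct))
  }
  dplyr::bind_rows(
    sect("total", "prescribing_encounters", x$n_prescribing_encounters, NA),
    if (!is.na(x$n_prescriptions)) sect("total", "prescriptions", x$n_prescriptions, NA),
    sect("age", x$age$level, x$age$n, x$age$pct),
    sect("facility", x$facility$level, x$facility$n, x$facility$pct),
    sect("drug_class", x$drug_class$level, x$drug_class$n, x$drug_class$pct),
    sect("criteria_count", x$criteria_count$n_criteria, x$criteria_count$n,
         x$criteria_count$pct),
    sect("criteria", x$criteria$criterion, x$criteria$n, x$criteria$pct),
    sect("tox_analyte", x$analytes$analyte, x$analytes$n, x$analytes$pct),
    sect("alert_rate", "prescribing_encounters_pct", x$n_encounters_flagged,
         x$alert_rate_prescribing_pct))
}
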