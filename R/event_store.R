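#' Construct an EMR event store
#'
#' An `event_store` is the package's canonical container for patient-level
#' EMR events: patients, encounters, prescriptions, in-facility medication
#' administrations, and toxicology screens, held as five tibbles with
#' cross-references validated on construction. All timestamps are UTC
#' `POSIXct`; per-patient event retrieval is always time-ordered.
#'
#' @param patients Tibble with columns `patient_id` (character, unique) and
#'   `date_of_birth` (`Date`).
#' @param encounters Tibble with `encounter_id` (unique), `patient_id`,
#'   `start_at` (`POSIXct`), `facility_type` (one of ED, URGENT_CARE,
#'   INPATIENT, OUTPATIENT, PHONE, OTHER), `disposition` (DISCHARGED,
#'   ADMITTED, NOT_APPLICABLE; ADMITTED only for ED/URGENT_CARE), and
#'   `is_overdose_presentation` (logical).
#' @param prescriptions Tibble with `rx_id` (unique), `patient_id`,
#'   `encounter_id`, `written_at` (`POSIXct`), `drug_class` (OPIOID or
#'   BENZODIAZEPINE), `duration_days` (positive days of supply; `NA`
#'   permitted but flagged with a warning — the early-refill trigger skips
#'   such prescriptions), `prescriber_id`, and optional `drug_name`.
#' @param med_admins Tibble with `patient_id`, `encounter_id`,
#'   `administered_at` (`POSIXct`), `drug_class` (OPIOID, BENZODIAZEPINE,
#'   OTHER).
#' @param tox_screens Tibble with `patient_id`, `collected_at` (`POSIXct`),
#'   `analyte` (BLOOD_ALCOHOL, COCAINE, MARIJUANA), `positive` (logical).
#' @return A validated object of class `event_store`.
#' @export
#' @examples
#' store <- event_store(
#'   patients = tibble::tibble(patient_id = "p1",
#'                             date_of_birth = as.Date("1980-01-01")),
#'   encounters = tibble::tibble(
#'     encounter_id = "e1", patient_id = "p1",
#'     start_at = parse_utc("2015-04-01T09:00:00Z"),
#'     facility_type = "OUTPATIENT", disposition = "NOT_APPLICABLE",
#'     is_overdose_presentation = FALSE))
#' store
event_store <- function(patients = NULL, encounters = NULL,
                        prescriptions = NULL, med_admins = NULL,
                        tox_screens = NULL) {
  store <- structure(
    list(
      patients = canonize(patients, patient_cols()),
      encounters = canonize(encounters, encounter_cols()),
      prescriptions = canonize(prescriptions, prescription_cols()),
      med_admins = canonize(med_admins, med_admin_cols()),
      tox_screens = canonize(tox_screens, tox_screen_cols())
    ),
    class = "event_store"
  )
  validate_event_store(store)
}

patient_cols <- function() {
  list(patient_id = character(), date_of_birth = as.Date(character()))
}
encounter_cols <- function() {
  list(encounter_id = character(), patient_id = character(),
       start_at = parse_utc(character()), facility_type = character(),
       disposition = character(), is_overdose_presentation = logical())
}
prescription_cols <- function() {
  list(rx_id = character(), patient_id = character(),
       encounter_id = character(), written_at = parse_utc(character()),
       drug_class = character(), duration_days = numeric(),
       prescriber_id = character(), drug_name = character())
}
med_admin_cols <- function() {
  list(patient_id = character(), encounter_id = character(),
       administered_at = parse_utc(character()), drug_class = character())
}
tox_screen_cols <- function() {
  list(patient_id = character(), collected_at = parse_utc(character()),
       analyte = character(), positive = logical())
}

# Coerce an entity table to the canonical column set and types; optional
# columns absent from the input are filled with NA.
canonize <- function(df, proto) {
  if (is.null(df)) {
    return(tibble::as_tibble(proto))
  }
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(names(proto), names(df))
  required <- setdiff(missing_cols, c("drug_name", "duration_days"))
  if (length(required) > 0 && nrow(df) > 0) {
    stop("missing required column(s): ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  for (nm in missing_cols) {
    df[[nm]] <- proto[[nm]][NA_integer_][rep(1L, nrow(df))]
  }
  for (nm in names(proto)) {
    if (inherits(proto[[nm]], "POSIXct")) {
      df[[nm]] <- parse_utc(df[[nm]])
    } else if (inherits(proto[[nm]], "Date")) {
      df[[nm]] <- as.Date(df[[nm]])
    } else if (is.logical(proto[[nm]])) {
      df[[nm]] <- as.logical(df[[nm]])
    } else if (is.numeric(proto[[nm]])) {
      df[[nm]] <- as.numeric(df[[nm]])
    } else {
      df[[nm]] <- as.character(df[[nm]])
    }
  }
  df[names(proto)]
}

check_enum <- function(values, allowed, what, where) {
  bad <- setdiff(unique(values[!is.na(values)]), allowed)
  if (length(bad) > 0) {
    stop(sprintf("%s: invalid %s value(s): %s (allowed: %s)",
                 where, what, paste(bad, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
}

check_resolves <- function(ids, universe, what, where) {
  bad <- unique(ids[!is.na(ids) & !(ids %in% universe)])
  if (length(bad) > 0) {
    stop(sprintf("%s: dangling %s reference(s): %s", where, what,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
}

#' Validate an event store
#'
#' Checks id uniqueness, cross-reference resolution, enum membership and
#' temporal sanity (no event precedes its patient's birth; prescriptions
#' and administrations do not precede their encounter's start; admission
#' dispositions only at ED/urgent care). Prescriptions with missing or
#' non-positive days of supply raise a warning, not an error: they remain
#' in the store but are skipped by the early-refill trigger.
#'
#' @param store An `event_store`.
#' @return The store, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_event_store <- function(store) {
  stopifnot(inherits(store, "event_store"))
  p <- store$patients; e <- store$encounters; rx <- store$prescriptions
  ma <- store$med_admins; tx <- store$tox_screens

  check_unique(p$patient_id, "patient_id")
  check_unique(e$encounter_id, "encounter_id")
  check_unique(rx$rx_id, "rx_id")

  check_resolves(e$patient_id, p$patient_id, "patient_id", "encounters")
  check_resolves(rx$patient_id, p$patient_id, "patient_id", "prescriptions")
  check_resolves(ma$patient_id, p$patient_id, "patient_id", "med_admins")
  check_resolves(tx$patient_id, p$patient_id, "patient_id", "tox_screens")
  bad_rx_enc <- rx$rx_id[!(rx$encounter_id %in% e$encounter_id)]
  if (length(bad_rx_enc) > 0) {
    stop("prescriptions: dangling encounter_id reference for rx_id: ",
         paste(utils::head(bad_rx_enc, 5), collapse = ", "), call. = FALSE)
  }
  check_resolves(ma$encounter_id, e$encounter_id, "encounter_id", "med_admins")

  check_enum(e$facility_type, FACILITY_TYPES, "facility_type", "encounters")
  check_enum(e$disposition, DISPOSITIONS, "disposition", "encounters")
  check_enum(rx$drug_class, RX_CLASSES, "drug_class", "prescriptions")
  check_enum(ma$drug_class, ADMIN_CLASSES, "drug_class", "med_admins")
  check_enum(tx$analyte, TOX_ANALYTES, "analyte", "tox_screens")

  bad_adm <- e$encounter_id[e$disposition == "ADMITTED" &
                              !(e$facility_type %in% c("ED", "URGENT_CARE"))]
  if (length(bad_adm) > 0) {
    stop("encounters: ADMITTED disposition outside ED/URGENT_CARE: ",
         paste(utils::head(bad_adm, 5), collapse = ", "), call. = FALSE)
  }

  # temporal sanity
  dob <- setNames(p$date_of_birth, p$patient_id)
  born <- function(ids) as.POSIXct(as.character(dob[ids]), tz = "UTC")
  if (nrow(e) > 0 && any(e$start_at < born(e$patient_id), na.rm = TRUE)) {
    stop("encounters precede the patient's date of birth", call. = FALSE)
  }
  if (nrow(rx) > 0) {
    enc_start <- setNames(e$start_at, e$encounter_id)
    if (any(rx$written_at < enc_start[rx$encounter_id], na.rm = TRUE)) {
      stop("prescription written before its encounter started", call. = FALSE)
    }
    bad_dur <- rx$rx_id[is.na(rx$duration_days) | rx$duration_days <= 0]
    if (length(bad_dur) > 0) {
      warning("prescriptions with missing or non-positive duration_days ",
              "(skipped by the early-refill trigger): ",
              paste(utils::head(bad_dur, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(ma) > 0) {
    enc_start <- setNames(e$start_at, e$encounter_id)
    if (any(ma$administered_at < enc_start[ma$encounter_id], na.rm = TRUE)) {
      stop("medication administered before its encounter started", call. = FALSE)
    }
  }
  invisible(store)
}

#' @export
print.event_store <- function(x, ...) {
  cat("<event_store>\n")
  cat(sprintf("  patients:       %6d\n", nrow(x$patients)))
  cat(sprintf("  encounters:     %6d\n", nrow(x$encounters)))
  cat(sprintf("  prescriptions:  %6d\n", nrow(x$prescriptions)))
  cat(sprintf("  med_admins:     %6d\n", nrow(x$med_admins)))
  cat(sprintf("  tox_screens:    %6d\n", nrow(x$tox_screens)))
  invisible(x)
}

#' Count events of every kind
#'
#' @param store An `event_store`.
#' @return Named integer vector over the five entity types.
#' @export
event_counts <- function(store) {
  vapply(store[c("patients", "encounters", "prescriptions",
                 "med_admins", "tox_screens")], nrow, integer(1))
}

#' Retrieve a patient's events in a half-open time window
#'
#' Returns events of one kind for one patient with timestamp in
#' `[t_start, t_end)` — closed below, open above, the convention every
#' windowed trigger uses ("previous 30 days" means `[t - 30d, t)`, so
#' events at the evaluation instant itself are excluded). Results are in
#' non-decreasing time order. An unknown patient yields an empty result,
#' not an error.
#'
#' @param store An `event_store`.
#' @param patient_id Patient identifier.
#' @param kind One of `"encounter"`, `"prescription"`, `"med_admin"`,
#'   `"tox_screen"`.
#' @param t_start,t_end Window bounds (`POSIXct` or ISO-8601 strings),
#'   `t_start <= t_end`.
#' @return Tibble of matching events, time-ordered.
#' @export
query_window <- function(store, patient_id, kind, t_start, t_end) {
  stopifnot(inherits(store, "event_store"))
  t_start <- parse_utc(t_start)
  t_end <- parse_utc(t_end)
  if (t_start > t_end) stop("t_start must not exceed t_end", call. = FALSE)
  kind <- match.arg(kind, c("encounter", "prescription", "med_admin", "tox_screen"))
  tab <- switch(kind,
    encounter = store$encounters,
    prescription = store$prescriptions,
    med_admin = store$med_admins,
    tox_screen = store$tox_screens
  )
  tcol <- switch(kind,
    encounter = "start_at", prescription = "written_at",
    med_admin = "administered_at", tox_screen = "collected_at"
  )
  hit <- tab$patient_id == patient_id & tab[[tcol]] >= t_start & tab[[tcol]] < t_end
  out <- tab[which(hit), , drop = FALSE]
  out[order(out[[tcol]]), , drop = FALSE]
}
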