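#' Evaluate the rule for a single prescription initiation
#'
#' Runs the five-trigger rule at the prescription's `written_at` and
#' packages the outcome as an alert record. `fired` is true iff at least
#' one criterion is met. In `SILENT` mode no alert payload is rendered —
#' the evaluation is logged only; trigger evaluation itself is identical
#' between modes.
#'
#' @param store An [event_store()].
#' @param rx_id Prescription being initiated (must be in the store).
#' @param config A [trigger_config()].
#' @param mode `"SILENT"` or `"LIVE"`.
#' @return Object of class `alert_record`: prescription context, the full
#'   `trigger_result`, `fired`, `mode`, and (LIVE mode, fired only) the
#'   rendered `payload` text.
#' @export
process_prescription <- function(store, rx_id, config = trigger_config(),
                                 mode = c("SILENT", "LIVE")) {
  mode <- match.arg(mode)
  i <- match(rx_id, store$prescriptions$rx_id)
  if (is.na(i)) stop("prescription not in store: ", rx_id, call. = FALSE)
  rx <- store$prescriptions[i, ]
  result <- evaluate_triggers(store, rx_id, config)
  enc <- store$encounters[match(rx$encounter_id, store$encounters$encounter_id), ]
  rec <- structure(list(
    rx_id = rx$rx_id, patient_id = rx$patient_id,
    encounter_id = rx$encounter_id, prescriber_id = rx$prescriber_id,
    evaluated_at = rx$written_at, facility_type = enc$facility_type,
    drug_class = rx$drug_class, trigger_result = result,
    fired = result$n_criteria_met >= 1L, mode = mode,
    prescriber_response = NA_character_
  ), class = "alert_record")
  if (mode == "LIVE" && rec$fired) rec$payload <- render_alert_text(rec)
  rec
}

#' @export
print.alert_record <- function(x, ...) {
  cat(sprintf("<alert_record> rx %s (%s, %s) %s mode: %s\n",
              x$rx_id, x$drug_class, x$facility_type, x$mode,
              if (x$fired) sprintf("FIRED (%d criteria)",
                                   x$trigger_result$n_criteria_met)
              else "no alert"))
  invisible(x)
}

#' Render the alert payload for a fired record
#'
#' Produces the interruption text a prescriber would see: one block per
#' met criterion (canonical order), each with its supporting quantities;
#' unmet criteria never appear. Closes with the two dispositions the
#' prescriber must choose between.
#'
#' @param record An `alert_record` with `fired = TRUE`.
#' @return Single character string.
#' @export
render_alert_text <- function(record) {
  stopifnot(inherits(record, "alert_record"))
  if (!record$fired) stop("cannot render an alert for an unfired record", call. = FALSE)
  blocks <- character()
  for (crit in CRITERIA) {
    d <- record$trigger_result$details[[crit]]
    if (!d$met) next
    blocks <- c(blocks, render_block(crit, d))
  }
  paste0(
    "CONTROLLED SUBSTANCE RISK ALERT\n",
    sprintf("Patient %s | %s prescription at %s\n\n", record$patient_id,
            record$drug_class, record$facility_type),
    paste(blocks, collapse = "\n"),
    "\n\n[ CONTINUE PRESCRIPTION ]   [ CANCEL PRESCRIPTION ]"
  )
}

render_block <- function(crit, d) {
  switch(crit,
    EARLY_REFILL = sprintf(
      "* EARLY_REFILL: active prescription(s) with supply remaining: %s",
      paste(sprintf("%s (%.0f%% remaining)", d$evidence$rx_id,
                    100 * d$evidence$remaining_fraction), collapse = ", ")),
    ED_UC_ONSITE = sprintf(
      "* ED_UC_ONSITE: %d ED/Urgent Care visit(s) with onsite opioid treatment in window: %s",
      d$quantities$n_visits, paste(d$evidence$encounter_id, collapse = ", ")),
    RX_HISTORY = sprintf(
      "* RX_HISTORY: %d opioid/benzodiazepine prescription(s) in window: %s",
      d$quantities$n_prescriptions, paste(d$evidence$rx_id, collapse = ", ")),
    OVERDOSE = sprintf(
      "* OVERDOSE: previous overdose presentation(s): %s",
      paste(d$evidence$encounter_id, collapse = ", ")),
    TOX_SCREEN = sprintf(
      "* TOX_SCREEN: positive screen(s) for %s",
      paste(unique(d$evidence$analyte), collapse = ", "))
  )
}

#' Run the rule over every prescription initiation in a period
#'
#' Evaluates the five-trigger rule once per opioid/benzodiazepine
#' prescription with `written_at` in `[period_start, period_end)` — the
#' rule executes at every prescription initiation, so the log length
#' always equals the in-period prescription count. The log is a pure
#' function of `(store, period, config)`; in `SILENT` mode it is the
#' would-have-fired record of a silent surveillance phase.
#'
#' @param store An [event_store()].
#' @param period_start,period_end Half-open period bounds (`POSIXct` or
#'   ISO-8601 strings).
#' @param config A [trigger_config()].
#' @param mode `"SILENT"` or `"LIVE"` (recorded per record; evaluation is
#'   mode-independent).
#' @return An `alert_log`: a tibble with one row per prescription
#'   initiation (identifiers, context, the five met flags, supporting
#'   quantities, `n_criteria_met`, `fired`), sorted by evaluation time,
#'   with the period attached as an attribute.
#' @export
run_surveillance <- function(store, period_start, period_end,
                             config = trigger_config(),
                             mode = c("SILENT", "LIVE")) {
  mode <- match.arg(mode)
  stopifnot(inherits(store, "event_store"))
  period_start <- parse_utc(period_start)
  period_end <- parse_utc(period_end)
  if (period_start > period_end) stop("invalid period", call. = FALSE)

  rx_all <- store$prescriptions
  in_period <- rx_all$written_at >= period_start & rx_all$written_at < period_end
  rx <- rx_all[in_period, , drop = FALSE]
  rx <- rx[order(rx$written_at, rx$rx_id), , drop = FALSE]
  n <- nrow(rx)

  # pre-slice per patient once; each evaluation then touches only that
  # patient's events
  rx_by_p <- split(as.data.frame(rx_all), rx_all$patient_id)
  enc_by_p <- split(as.data.frame(store$encounters), store$encounters$patient_id)
  tox_by_p <- split(as.data.frame(store$tox_screens), store$tox_screens$patient_id)
  opioid_enc <- unique(store$med_admins$encounter_id[
    store$med_admins$drug_class == "OPIOID"])
  empty_rx <- as.data.frame(rx_all[0, ]); empty_enc <- as.data.frame(store$encounters[0, ])
  empty_tox <- as.data.frame(store$tox_screens[0, ])

  met <- matrix(FALSE, n, 5, dimnames = list(NULL, CRITERIA))
  max_remaining <- rep(NA_real_, n)
  n_visits <- integer(n); n_rx_window <- integer(n)
  analytes <- character(n)
  facility <- store$encounters$facility_type[
    match(rx$encounter_id, store$encounters$encounter_id)]

  for (k in seq_len(n)) {
    p <- rx$patient_id[k]; t_eval <- rx$written_at[k]
    p_rx <- rx_by_p[[p]]; if (is.null(p_rx)) p_rx <- empty_rx
    p_enc <- enc_by_p[[p]]; if (is.null(p_enc)) p_enc <- empty_enc
    p_tox <- tox_by_p[[p]]; if (is.null(p_tox)) p_tox <- empty_tox

    d1 <- refill_worker(p_rx, t_eval, config, rx$rx_id[k])
    d2 <- ed_uc_worker(p_enc, opioid_enc, t_eval, config, rx$encounter_id[k])
    d3 <- rx_history_worker(p_rx, t_eval, config, rx$rx_id[k])
    d4 <- overdose_worker(p_enc, t_eval)
    d5 <- tox_worker(p_tox, t_eval)

    met[k, ] <- c(d1$met, d2$met, d3$met, d4$met, d5$met)
    max_remaining[k] <- d1$quantities$max_remaining_fraction
    n_visits[k] <- d2$quantities$n_visits
    n_rx_window[k] <- d3$quantities$n_prescriptions
    analytes[k] <- paste(sort(unique(d5$evidence$analyte)), collapse = ";")
  }

  n_met <- as.integer(rowSums(met))
  log <- tibble::tibble(
    rx_id = rx$rx_id, patient_id = rx$patient_id,
    encounter_id = rx$encounter_id, prescriber_id = rx$prescriber_id,
    evaluated_at = rx$written_at, facility_type = facility,
    drug_class = rx$drug_class,
    early_refill = met[, "EARLY_REFILL"], ed_uc_onsite = met[, "ED_UC_ONSITE"],
    rx_history = met[, "RX_HISTORY"], overdose = met[, "OVERDOSE"],
    tox_screen = met[, "TOX_SCREEN"],
    max_remaining_fraction = max_remaining, n_ed_uc_visits = n_visits,
    n_rx_window = n_rx_window, tox_analytes = analytes,
    n_criteria_met = n_met, fired = n_met >= 1L, mode = mode)
  structure(log, period = c(period_start, period_end),
            class = c("alert_log", class(log)))
}

#' @export
print.alert_log <- function(x, ...) {
  period <- attr(x, "period")
  cat(sprintf("<alert_log> %d prescription evaluation(s), %d fired (%s to %s)\n",
              nrow(x), sum(x$fired), format_utc(period[1]), format_utc(period[2])))
  NextMethod()
}

#' Write an alert log as JSONL or CSV
#'
#' @param log An `alert_log`.
#' @param path Output file.
#' @param format `"JSONL"` (one record per line) or `"CSV"`.
#' @return `path`, invisibly.
#' @export
write_alert_log <- function(log, path, format = c("JSONL", "CSV")) {
  format <- match.arg(format)
  out <- serialize_table(tibble::as_tibble(log))
  if (format == "CSV") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      rec <- as.list(out[i, ])
      rec <- rec[!vapply(rec, is.na, logical(1))]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read an alert log written by [write_alert_log()]
#'
#' @param path JSONL or CSV file.
#' @param format `"JSONL"` or `"CSV"`.
#' @return An `alert_log` tibble (period attribute restored from the
#'   record range).
#' @export
read_alert_log <- function(path, format = c("JSONL", "CSV")) {
  format <- match.arg(format)
  if (format == "CSV") {
    log <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    log <- dplyr::bind_rows(lapply(lines, function(l) {
      tibble::as_tibble(lapply(jsonlite::fromJSON(l),
                               function(v) if (is.null(v)) NA else v))
    }))
  }
  log$evaluated_at <- parse_utc(log$evaluated_at)
  if (!"max_remaining_fraction" %in% names(log)) {
    log$max_remaining_fraction <- NA_real_
  }
  for (nm in c("early_refill", "ed_uc_onsite", "rx_history", "overdose",
               "tox_screen", "fired")) {
    log[[nm]] <- as.logical(log[[nm]])
  }
  for (nm in c("max_remaining_fraction")) log[[nm]] <- as.numeric(log[[nm]])
  for (nm in c("n_ed_uc_visits", "n_rx_window", "n_criteria_met")) {
    log[[nm]] <- as.integer(log[[nm]])
  }
  if (!"tox_analytes" %in% names(log)) log$tox_analytes <- character(nrow(log))
  log$tox_analytes[is.na(log$tox_analytes)] <- ""
  structure(log, period = if (nrow(log) > 0) range(log$evaluated_at) else NULL,
            class = c("alert_log", class(log)))
}
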