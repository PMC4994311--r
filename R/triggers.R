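#' Trigger threshold configuration
#'
#' Tunable parameters of the five-trigger risk rule. Defaults are the
#' final production thresholds; the rule's initial (first silent
#' surveillance phase) profile is available via
#' `trigger_config(profile = "initial")` and differed in two places: an
#' early-refill remaining-fraction threshold of 0.30 (final 0.50) and a
#' minimum of 3 ED/urgent-care visits (final 2).
#'
#' @param remaining_fraction_threshold Strict lower bound on the fraction
#'   of a prior prescription's days of supply still expected to remain at
#'   evaluation time for the early-refill trigger to fire. In (0, 1);
#'   default 0.50.
#' @param min_ed_uc_visits Minimum count of distinct prior ED/urgent-care
#'   visits with onsite opioid treatment (admissions excluded) inside the
#'   lookback window. Default 2.
#' @param ed_uc_window_days Lookback window (days) for the visit trigger.
#'   Default 30.
#' @param min_prescriptions Minimum count of prior opioid/benzodiazepine
#'   prescriptions inside the lookback window. Default 3.
#' @param rx_window_days Lookback window (days) for the prescription-count
#'   trigger. Default 30.
#' @param profile Shorthand: `"final"` (the defaults) or `"initial"`.
#'   Explicit arguments override the profile.
#' @return Object of class `trigger_config`.
#' @export
#' @examples
#' trigger_config()                     # final thresholds
#' trigger_config(profile = "initial")  # 0.30 remaining, 3+ visits
trigger_config <- function(remaining_fraction_threshold = NULL,
                           min_ed_uc_visits = NULL,
                           ed_uc_window_days = NULL,
                           min_prescriptions = NULL,
                           rx_window_days = NULL,
                           profile = c("final", "initial")) {
  profile <- match.arg(profile)
  base <- list(remaining_fraction_threshold = 0.50, min_ed_uc_visits = 2L,
               ed_uc_window_days = 30, min_prescriptions = 3L,
               rx_window_days = 30)
  if (profile == "initial") {
    base$remaining_fraction_threshold <- 0.30
    base$min_ed_uc_visits <- 3L
  }
  override <- list(remaining_fraction_threshold = remaining_fraction_threshold,
                   min_ed_uc_visits = min_ed_uc_visits,
                   ed_uc_window_days = ed_uc_window_days,
                   min_prescriptions = min_prescriptions,
                   rx_window_days = rx_window_days)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) base[[nm]] <- override[[nm]]
  }
  cfg <- base
  stopifnot(
    cfg$remaining_fraction_threshold > 0, cfg$remaining_fraction_threshold < 1,
    cfg$min_ed_uc_visits >= 1, cfg$ed_uc_window_days > 0,
    cfg$min_prescriptions >= 1, cfg$rx_window_days > 0
  )
  cfg$min_ed_uc_visits <- as.integer(cfg$min_ed_uc_visits)
  cfg$min_prescriptions <- as.integer(cfg$min_prescriptions)
  structure(cfg, class = "trigger_config")
}

#' Read a trigger configuration from YAML or JSON
#'
#' The file carries any subset of the [trigger_config()] fields; absent
#' fields take the final-threshold defaults.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return A `trigger_config`.
#' @export
read_trigger_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::fromJSON(path)
  do.call(trigger_config, vals[intersect(names(vals),
    c("remaining_fraction_threshold", "min_ed_uc_visits", "ed_uc_window_days",
      "min_prescriptions", "rx_window_days"))])
}

#' @export
print.trigger_config <- function(x, ...) {
  cat("<trigger_config>\n")
  cat(sprintf("  early refill:  remaining fraction > %.2f\n",
              x$remaining_fraction_threshold))
  cat(sprintf("  ED/UC onsite:  >= %d visits in previous %g days\n",
              x$min_ed_uc_visits, x$ed_uc_window_days))
  cat(sprintf("  rx history:    >= %d prescriptions in previous %g days\n",
              x$min_prescriptions, x$rx_window_days))
  cat("  overdose:      any prior presentation (lifetime)\n")
  cat("  tox screen:    any prior positive (lifetime)\n")
  invisible(x)
}

trigger_detail <- function(criterion, met, evidence, quantities = list(),
                           warnings = character()) {
  stopifnot(criterion %in% CRITERIA, !met || nrow(evidence) > 0)
  structure(list(criterion = criterion, met = met, evidence = evidence,
                 quantities = quantities, warnings = warnings),
            class = "trigger_detail")
}

#' @export
print.trigger_detail <- function(x, ...) {
  cat(sprintf("<trigger_detail> %s: %s\n", x$criterion,
              if (x$met) "MET" else "not met"))
  if (nrow(x$evidence) > 0) print(x$evidence)
  invisible(x)
}

# ---- per-criterion evaluators ------------------------------------------

# Each evaluator is a pure function of (store, t_eval, config); the public
# wrappers below accept the full store, while run_surveillance() feeds the
# same workers pre-sliced per-patient tables for speed.

refill_worker <- function(rx_tab, t_eval, config, index_rx_id) {
  keep <- rx_tab$rx_id != index_rx_id
  rx_tab <- rx_tab[keep, , drop = FALSE]
  bad_dur <- is.na(rx_tab$duration_days) | rx_tab$duration_days <= 0
  warn <- if (any(bad_dur)) {
    paste0("skipped prescriptions with missing/non-positive duration: ",
           paste(rx_tab$rx_id[bad_dur], collapse = ", "))
  } else character()
  rx_tab <- rx_tab[!bad_dur, , drop = FALSE]
  elapsed <- elapsed_days(rx_tab$written_at, t_eval)
  remaining <- 1 - elapsed / rx_tab$duration_days
  qual <- elapsed >= 0 & elapsed < rx_tab$duration_days &
    remaining > config$remaining_fraction_threshold
  ev <- tibble::tibble(rx_id = rx_tab$rx_id[qual],
                       written_at = rx_tab$written_at[qual],
                       duration_days = rx_tab$duration_days[qual],
                       elapsed_days = elapsed[qual],
                       remaining_fraction = remaining[qual])
  trigger_detail("EARLY_REFILL", any(qual), ev,
                 quantities = list(
                   max_remaining_fraction = if (any(qual)) max(ev$remaining_fraction) else NA_real_),
                 warnings = warn)
}

ed_uc_worker <- function(enc_tab, opioid_admin_enc, t_eval, config,
                         index_encounter_id) {
  w0 <- days_before(t_eval, config$ed_uc_window_days)
  qual <- enc_tab$facility_type %in% c("ED", "URGENT_CARE") &
    enc_tab$disposition != "ADMITTED" &
    enc_tab$start_at >= w0 & enc_tab$start_at < t_eval &
    enc_tab$encounter_id != index_encounter_id &
    enc_tab$encounter_id %in% opioid_admin_enc
  ev <- tibble::tibble(encounter_id = enc_tab$encounter_id[qual],
                       start_at = enc_tab$start_at[qual],
                       facility_type = enc_tab$facility_type[qual])
  n <- nrow(ev)
  trigger_detail("ED_UC_ONSITE", n >= config$min_ed_uc_visits, ev,
                 quantities = list(n_visits = n))
}

rx_history_worker <- function(rx_tab, t_eval, config, index_rx_id) {
  w0 <- days_before(t_eval, config$rx_window_days)
  qual <- rx_tab$rx_id != index_rx_id &
    rx_tab$written_at >= w0 & rx_tab$written_at < t_eval
  ev <- tibble::tibble(rx_id = rx_tab$rx_id[qual],
                       written_at = rx_tab$written_at[qual],
                       drug_class = rx_tab$drug_class[qual])
  n <- nrow(ev)
  trigger_detail("RX_HISTORY", n >= config$min_prescriptions, ev,
                 quantities = list(n_prescriptions = n))
}

overdose_worker <- function(enc_tab, t_eval) {
  qual <- enc_tab$is_overdose_presentation & enc_tab$start_at < t_eval
  ev <- tibble::tibble(encounter_id = enc_tab$encounter_id[qual],
                       start_at = enc_tab$start_at[qual])
  trigger_detail("OVERDOSE", any(qual), ev,
                 quantities = list(n_presentations = nrow(ev)))
}

tox_worker <- function(tox_tab, t_eval) {
  qual <- tox_tab$positive & tox_tab$collected_at < t_eval
  ev <- tibble::tibble(analyte = tox_tab$analyte[qual],
                       collected_at = tox_tab$collected_at[qual])
  trigger_detail("TOX_SCREEN", any(qual), ev,
                 quantities = list(analytes = unique(ev$analyte)))
}

patient_slice <- function(tab, patient_id) {
  tab[tab$patient_id == patient_id, , drop = FALSE]
}

#' Early-refill trigger
#'
#' Fires when some prior opioid or benzodiazepine prescription (either
#' class; the index prescription itself excluded) is still "open" at the
#' evaluation instant with more than the configured fraction of its days
#' of supply expected to remain: with `elapsed = t_eval - written_at` in
#' days, the prescription qualifies iff `0 <= elapsed < duration_days` and
#' `1 - elapsed / duration_days > remaining_fraction_threshold` (strict).
#' For example, a 10-day supply written 3 days ago has remaining fraction
#' 0.7 and fires at both the 0.30 and the 0.50 threshold. Prescriptions
#' with missing or non-positive duration are skipped and noted in the
#' detail's `warnings`.
#'
#' @param store An [event_store()].
#' @param patient_id Patient identifier.
#' @param t_eval Evaluation instant (`POSIXct` or ISO-8601 string).
#' @param config A [trigger_config()].
#' @param index_rx_id Prescription being initiated; never counts as its
#'   own evidence.
#' @return A `trigger_detail` with qualifying prescriptions and their
#'   remaining fractions as evidence.
#' @export
eval_early_refill <- function(store, patient_id, t_eval,
                              config = trigger_config(), index_rx_id = "") {
  refill_worker(patient_slice(store$prescriptions, patient_id),
                parse_utc(t_eval), config, index_rx_id)
}

#' Repeated ED/urgent-care visits with onsite opioid treatment
#'
#' Fires when the number of distinct prior emergency-department or
#' urgent-care encounters that (a) did not lead to admission, (b) started
#' within the lookback window `[t_eval - ed_uc_window_days, t_eval)` and
#' (c) involved at least one onsite opioid administration reaches
#' `min_ed_uc_visits`. The encounter at which the index prescription is
#' being written never counts: the criterion reads on history.
#'
#' @inheritParams eval_early_refill
#' @param index_encounter_id Encounter of the prescription being
#'   initiated, excluded from the count.
#' @return A `trigger_detail` listing qualifying encounters.
#' @export
eval_ed_uc_onsite <- function(store, patient_id, t_eval,
                              config = trigger_config(),
                              index_encounter_id = "") {
  opioid_enc <- unique(store$med_admins$encounter_id[
    store$med_admins$drug_class == "OPIOID"])
  ed_uc_worker(patient_slice(store$encounters, patient_id), opioid_enc,
               parse_utc(t_eval), config, index_encounter_id)
}

#' Recent controlled-substance prescription history
#'
#' Fires when the patient accumulated at least `min_prescriptions`
#' opioid/benzodiazepine prescriptions (either class, each counted once,
#' the index prescription excluded) written within
#' `[t_eval - rx_window_days, t_eval)`.
#'
#' @inheritParams eval_early_refill
#' @return A `trigger_detail` listing in-window prescriptions.
#' @export
eval_rx_history <- function(store, patient_id, t_eval,
                            config = trigger_config(), index_rx_id = "") {
  rx_history_worker(patient_slice(store$prescriptions, patient_id),
                    parse_utc(t_eval), config, index_rx_id)
}

#' Previous overdose presentation
#'
#' Fires when any encounter flagged as an overdose presentation precedes
#' the evaluation instant. The lookback is lifetime: the whole record, no
#' window.
#'
#' @inheritParams eval_early_refill
#' @return A `trigger_detail` listing overdose encounters.
#' @export
eval_overdose_history <- function(store, patient_id, t_eval) {
  overdose_worker(patient_slice(store$encounters, patient_id), parse_utc(t_eval))
}

#' Positive toxicology screen
#'
#' Fires when any prior screen for blood alcohol, cocaine, or marijuana is
#' positive. Lifetime lookback. The evidence lists every positive analyte
#' (a patient can contribute to several analyte tallies in the
#' surveillance report).
#'
#' @inheritParams eval_early_refill
#' @return A `trigger_detail` listing positive screens by analyte.
#' @export
eval_tox_screen <- function(store, patient_id, t_eval) {
  tox_worker(patient_slice(store$tox_screens, patient_id), parse_utc(t_eval))
}

#' Evaluate the full five-trigger rule for one prescription initiation
#'
#' Runs all five criteria at the index prescription's `written_at`, with
#' the index prescription (and its encounter, for the visit criterion)
#' excluded where the criteria read on history. The result composes the
#' five single-criterion evaluators exactly.
#'
#' @param store An [event_store()].
#' @param index_rx_id `rx_id` of the prescription being initiated; must be
#'   in the store.
#' @param config A [trigger_config()].
#' @return Object of class `trigger_result`: the five `trigger_detail`s
#'   (canonical order: early refill, ED/UC onsite, rx history, overdose,
#'   tox screen), `n_criteria_met`, and `evaluated_at`.
#' @export
evaluate_triggers <- function(store, index_rx_id, config = trigger_config()) {
  stopifnot(inherits(store, "event_store"))
  i <- match(index_rx_id, store$prescriptions$rx_id)
  if (is.na(i)) stop("index prescription not in store: ", index_rx_id, call. = FALSE)
  rx <- store$prescriptions[i, ]
  t_eval <- rx$written_at
  details <- list(
    EARLY_REFILL = eval_early_refill(store, rx$patient_id, t_eval, config, rx$rx_id),
    ED_UC_ONSITE = eval_ed_uc_onsite(store, rx$patient_id, t_eval, config, rx$encounter_id),
    RX_HISTORY = eval_rx_history(store, rx$patient_id, t_eval, config, rx$rx_id),
    OVERDOSE = eval_overdose_history(store, rx$patient_id, t_eval),
    TOX_SCREEN = eval_tox_screen(store, rx$patient_id, t_eval)
  )
  new_trigger_result(details, t_eval)
}

new_trigger_result <- function(details, evaluated_at) {
  met <- vapply(details, function(d) d$met, logical(1))
  structure(list(details = details,
                 n_criteria_met = as.integer(sum(met)),
                 evaluated_at = evaluated_at),
            class = "trigger_result")
}

#' @export
print.trigger_result <- function(x, ...) {
  cat(sprintf("<trigger_result> %d of 5 criteria met at %s\n",
              x$n_criteria_met, format_utc(x$evaluated_at)))
  for (d in x$details) {
    cat(sprintf("  %-13s %s\n", d$criterion, if (d$met) "MET" else "-"))
  }
  invisible(x)
}

#' Met flags of a trigger result
#'
#' @param result A `trigger_result`.
#' @return Named logical vector over the five criteria, canonical order.
#' @export
criteria_met <- function(result) {
  vapply(result$details, function(d) d$met, logical(1))[CRITERIA]
}
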