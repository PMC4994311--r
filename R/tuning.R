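#' Sweep trigger configurations over a cohort
#'
#' Re-runs silent surveillance and the aggregate report once per
#' configuration in a grid and tabulates the alert-burden trade-off: each
#' row carries the configuration's thresholds, the per-criterion
#' encounter rates, the at-least-one-criterion rate, and how many
#' encounters and distinct patients were flagged. No target alert rate is
#' built in — the table informs a consensus decision, it does not make
#' one.
#'
#' @param store An [event_store()].
#' @param period_start,period_end Surveillance period (half-open).
#' @param config_grid Non-empty list of [trigger_config()]s.
#' @return Tibble with one row per configuration, in grid order.
#' @export
sweep_thresholds <- function(store, period_start, period_end, config_grid) {
  if (!is.list(config_grid) || length(config_grid) == 0 ||
      inherits(config_grid, "trigger_config")) {
    stop("config_grid must be a non-empty list of trigger_config objects",
         call. = FALSE)
  }
  rows <- lapply(config_grid, function(cfg) {
    stopifnot(inherits(cfg, "trigger_config"))
    log <- run_surveillance(store, period_start, period_end, cfg)
    summ <- collect_prescribing_encounters(log, store)
    rep <- build_report(summ)
    pct <- setNames(as.numeric(rep$criteria$pct), rep$criteria$criterion)
    tibble::tibble(
      remaining_fraction_threshold = cfg$remaining_fraction_threshold,
      min_ed_uc_visits = cfg$min_ed_uc_visits,
      ed_uc_window_days = cfg$ed_uc_window_days,
      min_prescriptions = cfg$min_prescriptions,
      rx_window_days = cfg$rx_window_days,
      n_prescribing_encounters = rep$n_prescribing_encounters,
      early_refill_pct = pct[["EARLY_REFILL"]],
      ed_uc_onsite_pct = pct[["ED_UC_ONSITE"]],
      rx_history_pct = pct[["RX_HISTORY"]],
      overdose_pct = pct[["OVERDOSE"]],
      tox_screen_pct = pct[["TOX_SCREEN"]],
      any_criterion_pct = as.numeric(rep$alert_rate_prescribing_pct),
      n_encounters_flagged = rep$n_encounters_flagged,
      n_patients_flagged = rep$n_patients_flagged)
  })
  dplyr::bind_rows(rows)
}

#' Compare two trigger configurations on the same cohort
#'
#' Quantifies what changing thresholds buys and costs: per-criterion rate
#' deltas (b minus a), the change in flagged encounters, and the distinct
#' patients flagged under `config_b` but not under `config_a` — the
#' "additional at-risk patients captured" when b relaxes a. For nested
#' thresholds the flagged sets nest, so that count is non-negative in the
#' relaxing direction.
#'
#' @param store An [event_store()].
#' @param period_start,period_end Surveillance period.
#' @param config_a,config_b Two [trigger_config()]s.
#' @return List with `rates` (per-criterion and overall rates under each
#'   config plus `delta`), `delta_encounters_flagged`,
#'   `n_additional_patients` and `additional_patient_ids` (flagged under
#'   b only), and `n_lost_patients` (flagged under a only).
#' @export
compare_configs <- function(store, period_start, period_end,
                            config_a, config_b) {
  flagged_patients <- function(cfg) {
    log <- run_surveillance(store, period_start, period_end, cfg)
    list(log = log,
         row = sweep_thresholds(store, period_start, period_end, list(cfg)))
  }
  a <- flagged_patients(config_a)
  b <- flagged_patients(config_b)
  pa <- unique(a$log$patient_id[a$log$fired])
  pb <- unique(b$log$patient_id[b$log$fired])
  rate_cols <- c("early_refill_pct", "ed_uc_onsite_pct", "rx_history_pct",
                 "overdose_pct", "tox_screen_pct", "any_criterion_pct")
  rates <- tibble::tibble(
    statistic = rate_cols,
    config_a = as.numeric(a$row[1, rate_cols]),
    config_b = as.numeric(b$row[1, rate_cols]))
  rates$delta <- rates$config_b - rates$config_a
  extra <- setdiff(pb, pa)
  list(rates = rates,
       delta_encounters_flagged = b$row$n_encounters_flagged - a$row$n_encounters_flagged,
       n_additional_patients = length(extra),
       additional_patient_ids = extra,
       n_lost_patients = length(setdiff(pa, pb)))
}
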