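#' Published silent-surveillance aggregate counts
#'
#' The aggregate characteristics of controlled-substance prescribing
#' encounters observed during a one-month system-wide silent surveillance
#' phase (final trigger thresholds; 61,747 prescribing encounters,
#' 81,841 prescriptions). These printed counts serve as reference input
#' for [summaries_from_counts()], which reconstructs an encounter-level
#' table with exactly these marginals so the report formatter can be
#' checked against the printed percentages.
#'
#' @return Named list of count vectors: `n_encounters`,
#'   `n_prescriptions`, `age`, `facility`, `drug_class`,
#'   `criteria_count` (0 through 5), `criteria`, `analytes`.
#' @export
silent_surveillance_counts <- function() {
  list(
    n_encounters = 61747L,
    n_prescriptions = 81841L,
    age = c(UNDER_18 = 1552L, `18_64` = 45571L, `65_PLUS` = 14624L),
    facility = c(ED_URGENT_CARE = 18267L, INPATIENT_DISCHARGE = 4656L,
                 OUTPATIENT_INCL_PHONE = 38310L, OTHER = 514L),
    drug_class = c(OPIOID_ONLY = 45165L, BENZO_ONLY = 14268L, BOTH = 2314L),
    criteria_count = c(`0` = 48164L, `1` = 10517L, `2` = 2654L,
                       `3` = 369L, `4` = 43L, `5` = 0L),
    criteria = c(EARLY_REFILL = 8358L, ED_UC_ONSITE = 1208L,
                 RX_HISTORY = 2873L, OVERDOSE = 500L, TOX_SCREEN = 4165L),
    analytes = c(BLOOD_ALCOHOL = 1444L, COCAINE = 1248L, MARIJUANA = 2440L)
  )
}

#' Reconstruct encounter summaries from aggregate counts
#'
#' Builds a prescribing-encounter summary table (same shape as
#' [collect_prescribing_encounters()] output) whose marginals match a set
#' of printed aggregate counts exactly: age-band, facility and drug-class
#' breakdowns, the criteria-count distribution, the per-criterion totals,
#' and the toxicology analyte sub-row totals. The joint assignment of
#' criteria to encounters is not identified by the marginals, so a
#' deterministic greedy allocation is used (each encounter with k
#' criteria receives the k criteria with the largest remaining totals);
#' any reconstruction with the right marginals yields the same report.
#'
#' Fails if the marginals are arithmetically infeasible (e.g. the
#' per-criterion totals do not sum to the total flag count implied by the
#' criteria-count distribution).
#'
#' @param counts List shaped like [silent_surveillance_counts()].
#' @return Tibble of encounter summaries reproducing the counts.
#' @export
#' @examples
#' rep <- build_report(summaries_from_counts(silent_surveillance_counts()))
#' rep$criteria$pct  # matches the printed percentages
summaries_from_counts <- function(counts) {
  n <- counts$n_encounters
  stopifnot(sum(counts$age) == n, sum(counts$facility) == n,
            sum(counts$drug_class) == n, sum(counts$criteria_count) == n)
  dist <- counts$criteria_count
  total_flags <- sum(as.integer(names(dist)) * dist)
  if (total_flags != sum(counts$criteria)) {
    stop("infeasible marginals: per-criterion totals (", sum(counts$criteria),
         ") != flags implied by the criteria-count distribution (",
         total_flags, ")", call. = FALSE)
  }

  # flag matrix: rows in descending number of criteria so the greedy
  # allocation can always place k distinct criteria
  k_per_row <- rep(as.integer(names(dist)), dist)
  k_per_row <- sort(k_per_row, decreasing = TRUE)
  flags <- matrix(FALSE, n, 5, dimnames = list(NULL, CRITERIA))
  rem <- counts$criteria[CRITERIA]
  for (i in seq_len(n)) {
    k <- k_per_row[i]
    if (k == 0) break  # remaining rows all zero-criteria
    pick <- order(rem, decreasing = TRUE)[seq_len(k)]
    if (any(rem[pick] <= 0)) {
      stop("infeasible marginals: cannot place ", k,
           " distinct criteria on an encounter", call. = FALSE)
    }
    flags[i, pick] <- TRUE
    rem[pick] <- rem[pick] - 1L
  }
  if (any(rem != 0)) stop("infeasible marginals: leftover criterion flags",
                          call. = FALSE)

  # analyte flags among tox-screen encounters: lay each analyte along the
  # tox rows in turn, wrapping, so every tox row gets >= 1 analyte and
  # totals match exactly (each analyte total must be <= the tox total)
  tox_rows <- which(flags[, "TOX_SCREEN"])
  n_tox <- length(tox_rows)
  an <- sort(counts$analytes, decreasing = TRUE)
  if (n_tox > 0) {
    if (any(an > n_tox) || sum(an) < n_tox) {
      stop("infeasible analyte sub-row totals", call. = FALSE)
    }
    amat <- matrix(FALSE, n_tox, length(an), dimnames = list(NULL, names(an)))
    pos <- 0L
    for (a in names(an)) {
      idx <- ((pos + seq_len(an[[a]]) - 1L) %% n_tox) + 1L
      amat[idx, a] <- TRUE
      pos <- pos + an[[a]]
    }
  } else if (sum(an) > 0) {
    stop("analyte totals positive but no tox-screen encounters", call. = FALSE)
  }

  block <- function(counts_vec) rep(names(counts_vec), counts_vec)
  out <- tibble::tibble(
    encounter_id = sprintf("enc%06d", seq_len(n)),
    patient_id = sprintf("pat%06d", seq_len(n)),
    patient_age_band = block(counts$age),
    facility_bucket = block(counts$facility),
    drug_class_bucket = block(counts$drug_class),
    early_refill = flags[, "EARLY_REFILL"],
    ed_uc_onsite = flags[, "ED_UC_ONSITE"],
    rx_history = flags[, "RX_HISTORY"],
    overdose = flags[, "OVERDOSE"],
    tox_screen = flags[, "TOX_SCREEN"],
    n_criteria = as.integer(rowSums(flags)),
    bac = FALSE, cocaine = FALSE, marijuana = FALSE)
  if (n_tox > 0) {
    out$bac[tox_rows] <- amat[, "BLOOD_ALCOHOL"]
    out$cocaine[tox_rows] <- amat[, "COCAINE"]
    out$marijuana[tox_rows] <- amat[, "MARIJUANA"]
  }
  out
}
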