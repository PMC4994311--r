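#' Synthetic cohort configuration
#'
#' Parameters of the seeded synthetic EMR cohort generator. The generator
#' emulates a mixed-risk population through four patient archetypes:
#' `BASELINE` (occasional care), `FREQUENT_UTILIZER` (elevated encounter
#' and prescription rates, hence early-refill and prescription-history
#' risk), `SUBSTANCE_USE` (positive toxicology screens), and
#' `OVERDOSE_HISTORY` (at least one overdose presentation predating the
#' surveillance period). Encounters arise as a homogeneous Poisson process
#' per patient over the surveillance period plus a pre-period (so 30-day
#' lookback triggers have history); prescriptions are written at the
#' encounter start.
#'
#' Defaults are chosen so that, over the default 30-day surveillance
#' period, the five criterion prevalences among prescribing encounters
#' fall in the same order of magnitude as a large mixed inpatient /
#' ED-urgent-care / outpatient health system (roughly 14%, 2%, 5%, 7%, 1%
#' for early refill, repeated ED/UC visits, prescription history,
#' positive tox screen and prior overdose respectively). Exact marginal
#' matching is not a generator contract.
#'
#' @param n_patients Number of patients.
#' @param period_days Length of the surveillance period, days.
#' @param pre_period_days History window generated before the period so
#'   lookback triggers can fire at its start. Default 90.
#' @param archetype_mixture Named probabilities over the four archetypes;
#'   must sum to 1.
#' @param encounter_rate_per_30d Named per-archetype expected encounters
#'   per 30 days.
#' @param facility_mix Named probabilities over facility types; sums to 1.
#' @param p_prescribe_given_encounter Named per-facility probability that
#'   an encounter initiates at least one opioid/benzodiazepine
#'   prescription.
#' @param drug_class_mix Probabilities for opioid-only / benzodiazepine-
#'   only / both at a prescribing encounter; sums to 1.
#' @param duration_days_distribution Days-of-supply distribution: either
#'   `list(kind = "fixed", value = v)` or
#'   `list(kind = "uniform", lo = a, hi = b)` (values rounded to 0.1 day).
#' @param p_onsite_opioid_admin_ED_UC Probability an ED/urgent-care
#'   encounter includes an onsite opioid administration.
#' @param p_admitted_given_ED Probability an ED/urgent-care encounter
#'   leads to admission.
#' @param tox_positive_rates Named per-analyte probability that a
#'   `SUBSTANCE_USE` patient's history holds a positive screen for that
#'   analyte (applied once per patient).
#' @param age_band_mix Probabilities that a patient is under 18, 18-64, or
#'   65+, in that order.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration including the seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 2000,
    period_days = 30,
    pre_period_days = 90,
    archetype_mixture = c(BASELINE = 0.72, FREQUENT_UTILIZER = 0.12,
                          SUBSTANCE_USE = 0.15, OVERDOSE_HISTORY = 0.01),
    encounter_rate_per_30d = c(BASELINE = 0.6, FREQUENT_UTILIZER = 4.0,
                               SUBSTANCE_USE = 0.9, OVERDOSE_HISTORY = 1.0),
    facility_mix = c(ED = 0.15, URGENT_CARE = 0.10, INPATIENT = 0.05,
                     OUTPATIENT = 0.55, PHONE = 0.10, OTHER = 0.05),
    p_prescribe_given_encounter = c(ED = 0.35, URGENT_CARE = 0.30,
                                    INPATIENT = 0.40, OUTPATIENT = 0.20,
                                    PHONE = 0.10, OTHER = 0.05),
    drug_class_mix = c(OPIOID_ONLY = 0.73, BENZO_ONLY = 0.23, BOTH = 0.04),
    duration_days_distribution = list(kind = "uniform", lo = 5, hi = 30),
    p_onsite_opioid_admin_ED_UC = 0.6,
    p_admitted_given_ED = 0.15,
    tox_positive_rates = c(BLOOD_ALCOHOL = 0.30, COCAINE = 0.25,
                           MARIJUANA = 0.50),
    age_band_mix = c(UNDER_18 = 0.03, MID = 0.73, OVER_65 = 0.24),
    seed = 1L) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk_probs <- function(p, nm) {
    if (any(p < 0 | p > 1)) stop(nm, ": probabilities must be in [0,1]", call. = FALSE)
  }
  chk_sum1 <- function(p, nm) {
    chk_probs(p, nm)
    if (abs(sum(p) - 1) > 1e-9) stop(nm, " must sum to 1", call. = FALSE)
  }
  if (cfg$n_patients < 0) stop("n_patients must be non-negative", call. = FALSE)
  if (cfg$period_days <= 0 || cfg$pre_period_days < 0) {
    stop("period_days must be positive, pre_period_days non-negative", call. = FALSE)
  }
  if (!setequal(names(cfg$archetype_mixture), ARCHETYPES) &&
      !all(names(cfg$archetype_mixture) %in% ARCHETYPES)) {
    stop("archetype_mixture names must be archetypes", call. = FALSE)
  }
  chk_sum1(cfg$archetype_mixture, "archetype_mixture")
  chk_sum1(cfg$facility_mix, "facility_mix")
  chk_sum1(cfg$drug_class_mix, "drug_class_mix")
  chk_sum1(cfg$age_band_mix, "age_band_mix")
  chk_probs(cfg$p_prescribe_given_encounter, "p_prescribe_given_encounter")
  chk_probs(cfg$tox_positive_rates, "tox_positive_rates")
  chk_probs(cfg$p_onsite_opioid_admin_ED_UC, "p_onsite_opioid_admin_ED_UC")
  chk_probs(cfg$p_admitted_given_ED, "p_admitted_given_ED")
  if (any(cfg$encounter_rate_per_30d < 0)) {
    stop("encounter_rate_per_30d must be non-negative", call. = FALSE)
  }
  dd <- cfg$duration_days_distribution
  ok <- is.list(dd) && ((identical(dd$kind, "fixed") && dd$value > 0) ||
    (identical(dd$kind, "uniform") && dd$lo > 0 && dd$hi >= dd$lo))
  if (!ok) stop("duration_days_distribution must be fixed(value>0) or uniform(0<lo<=hi)",
                call. = FALSE)
  invisible(cfg)
}

#' Read a cohort configuration from YAML or JSON
#'
#' @param path YAML or JSON file mirroring the [cohort_config()] field
#'   names; absent fields take the defaults.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::fromJSON(path)
  vals <- vals[intersect(names(vals), names(formals(cohort_config)))]
  for (nm in c("archetype_mixture", "encounter_rate_per_30d", "facility_mix",
               "p_prescribe_given_encounter", "drug_class_mix",
               "tox_positive_rates", "age_band_mix")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(cohort_config, vals)
}

#' Assign patient archetypes
#'
#' Deterministic given `(n, mixture, seed)`; label frequencies converge to
#' the mixture as `n` grows.
#'
#' @param n Number of patients.
#' @param mixture Named archetype probabilities summing to 1.
#' @param seed Integer seed.
#' @return Character vector of `n` archetype labels.
#' @export
assign_archetypes <- function(n, mixture = cohort_config()$archetype_mixture,
                              seed = 1L) {
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture must sum to 1", call. = FALSE)
  if (!all(names(mixture) %in% ARCHETYPES)) {
    stop("mixture names must be archetypes", call. = FALSE)
  }
  if (n == 0) return(character())
  with_local_seed(seed, sample(names(mixture), n, replace = TRUE, prob = mixture))
}

# Run code under a temporary RNG state so generation never perturbs (or is
# perturbed by) the caller's random stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Generate a synthetic EMR cohort
#'
#' Draws a full [event_store()] from a [cohort_config()]. One seeded RNG
#' stream is consumed in a fixed documented order — patient-level
#' attributes first (archetype, age band, birth date), then each patient's
#' event stream in patient order — so equal configurations yield
#' byte-identical serialized logs.
#'
#' The surveillance period starts at `t0` (default 2015-04-01T00:00:00Z)
#' and spans `period_days`; encounters are also generated over the
#' `pre_period_days` before `t0` so that lookback triggers have history.
#'
#' @param config A [cohort_config()].
#' @param t0 Period start (`POSIXct` or ISO-8601 string).
#' @return A validated [event_store()].
#' @export
generate_cohort <- function(config = cohort_config(),
                            t0 = "2015-04-01T00:00:00Z") {
  validate_cohort_config(config)
  t0 <- parse_utc(t0)
  n <- config$n_patients
  if (n == 0) return(event_store())
  with_local_seed(config$seed, generate_cohort_impl(config, t0))
}

generate_cohort_impl <- function(cfg, t0) {
  n <- cfg$n_patients
  horizon_days <- cfg$pre_period_days + cfg$period_days
  gen_start <- days_before(t0, cfg$pre_period_days)

  # --- patient-level draws (fixed order: archetype, age band, age) ------
  archetype <- sample(names(cfg$archetype_mixture), n, replace = TRUE,
                      prob = cfg$archetype_mixture)
  band <- sample(c("UNDER_18", "MID", "OVER_65"), n, replace = TRUE,
                 prob = cfg$age_band_mix)
  age_years <- numeric(n)
  age_years[band == "UNDER_18"] <- runif(sum(band == "UNDER_18"), 2, 18)
  age_years[band == "MID"] <- runif(sum(band == "MID"), 18, 65)
  age_years[band == "OVER_65"] <- runif(sum(band == "OVER_65"), 65, 95)
  pid <- sprintf("p%05d", seq_len(n))
  dob <- as.Date(t0) - round(age_years * 365.25)

  patients <- tibble::tibble(patient_id = pid, date_of_birth = dob)

  # --- per-patient event streams, in patient order ----------------------
  enc_l <- vector("list", n); rx_l <- vector("list", n)
  ma_l <- vector("list", n); tox_l <- vector("list", n)
  duration_draw <- function(k) {
    dd <- cfg$duration_days_distribution
    if (dd$kind == "fixed") rep(dd$value, k) else round(runif(k, dd$lo, dd$hi), 1)
  }
  for (i in seq_len(n)) {
    rate <- cfg$encounter_rate_per_30d[[archetype[i]]]
    n_enc <- rpois(1, rate * horizon_days / 30)
    enc_t <- gen_start + sort(round(runif(n_enc, 0, horizon_days * SECONDS_PER_DAY)))
    facility <- if (n_enc > 0) {
      sample(names(cfg$facility_mix), n_enc, replace = TRUE, prob = cfg$facility_mix)
    } else character()
    is_ed_uc <- facility %in% c("ED", "URGENT_CARE")
    disposition <- rep("NOT_APPLICABLE", n_enc)
    admitted_draw <- runif(n_enc) < cfg$p_admitted_given_ED
    disposition[is_ed_uc] <- ifelse(admitted_draw[is_ed_uc], "ADMITTED", "DISCHARGED")
    overdose <- rep(FALSE, n_enc)
    eid <- sprintf("%s-e%03d", pid[i], seq_len(n_enc))

    # overdose-history patients get one flagged ED encounter predating the
    # surveillance period (before even the generated pre-period)
    if (archetype[i] == "OVERDOSE_HISTORY") {
      od_t <- days_before(gen_start, round(runif(1, 30, 365)))
      enc_t <- c(od_t, enc_t)
      facility <- c("ED", facility)
      disposition <- c("DISCHARGED", disposition)
      overdose <- c(TRUE, overdose)
      is_ed_uc <- c(FALSE, is_ed_uc)  # no onsite-admin draw for this one
      eid <- c(sprintf("%s-eod", pid[i]), eid)
      n_enc <- n_enc + 1L
    }

    enc_l[[i]] <- tibble::tibble(
      encounter_id = eid, patient_id = pid[i], start_at = enc_t,
      facility_type = facility, disposition = disposition,
      is_overdose_presentation = overdose)

    # onsite opioid administrations at ED/UC encounters
    admin_here <- is_ed_uc & runif(n_enc) < cfg$p_onsite_opioid_admin_ED_UC
    if (any(admin_here)) {
      ma_l[[i]] <- tibble::tibble(
        patient_id = pid[i], encounter_id = eid[admin_here],
        administered_at = enc_t[admin_here] + 1800,
        drug_class = "OPIOID")
    }

    # prescriptions: Bernoulli per encounter given facility, class mix,
    # written at the encounter start
    p_rx <- cfg$p_prescribe_given_encounter[facility]
    prescribes <- runif(n_enc) < p_rx & !overdose
    if (any(prescribes)) {
      which_rx <- which(prescribes)
      cls <- sample(names(cfg$drug_class_mix), length(which_rx), replace = TRUE,
                    prob = cfg$drug_class_mix)
      one <- cls != "BOTH"
      rx_enc <- c(eid[which_rx], eid[which_rx][!one])
      rx_t <- c(enc_t[which_rx], enc_t[which_rx][!one])
      rx_cls <- c(ifelse(cls == "BENZO_ONLY", "BENZODIAZEPINE", "OPIOID"),
                  rep("BENZODIAZEPINE", sum(!one)))
      ord <- order(rx_t, rx_enc, rx_cls)
      rx_l[[i]] <- tibble::tibble(
        rx_id = sprintf("%s-rx%03d", pid[i], seq_along(rx_enc)),
        patient_id = pid[i], encounter_id = rx_enc[ord],
        written_at = rx_t[ord], drug_class = rx_cls[ord],
        duration_days = duration_draw(length(rx_enc)),
        prescriber_id = sprintf("prc%03d", sample(200, length(rx_enc), replace = TRUE)),
        drug_name = NA_character_)
    }

    # substance-use patients: one screen per analyte, positive at the
    # configured per-analyte rate, collected at a uniform time in history
    if (archetype[i] == "SUBSTANCE_USE") {
      analytes <- names(cfg$tox_positive_rates)
      pos <- runif(length(analytes)) < cfg$tox_positive_rates
      coll <- gen_start + round(runif(length(analytes), 0, horizon_days * SECONDS_PER_DAY))
      tox_l[[i]] <- tibble::tibble(
        patient_id = pid[i], collected_at = coll,
        analyte = analytes, positive = pos)
    }
  }

  store <- event_store(
    patients = patients,
    encounters = dplyr::bind_rows(enc_l),
    prescriptions = dplyr::bind_rows(rx_l),
    med_admins = dplyr::bind_rows(ma_l),
    tox_screens = dplyr::bind_rows(tox_l))
  attr(store, "archetype") <- setNames(archetype, pid)
  attr(store, "period") <- c(t0, t0 + cfg$period_days * SECONDS_PER_DAY)
  store
}

#' Marginal summary of a cohort
#'
#' Counts and fractions of encounters by facility type, prescriptions by
#' drug class, and patients with any positive toxicology screen or any
#' overdose presentation — the marginals the simulator steers.
#'
#' @param store An [event_store()].
#' @return List with `encounters_by_facility`, `prescriptions_by_class`
#'   (tibbles of counts and fractions) and `patients` (totals plus
#'   any-positive-tox and any-overdose counts).
#' @export
summarize_cohort <- function(store) {
  stopifnot(inherits(store, "event_store"))
  tab_frac <- function(x, levels) {
    cnt <- table(factor(x, levels = levels))
    tibble::tibble(level = names(cnt), n = as.integer(cnt),
                   fraction = if (sum(cnt) > 0) as.numeric(cnt) / sum(cnt) else 0)
  }
  pos <- store$tox_screens[store$tox_screens$positive, , drop = FALSE]
  od <- store$encounters[store$encounters$is_overdose_presentation, , drop = FALSE]
  list(
    encounters_by_facility = tab_frac(store$encounters$facility_type, FACILITY_TYPES),
    prescriptions_by_class = tab_frac(store$prescriptions$drug_class, RX_CLASSES),
    patients = list(
      n_patients = nrow(store$patients),
      n_any_positive_tox = length(unique(pos$patient_id)),
      n_any_overdose = length(unique(od$patient_id))
    )
  )
}
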