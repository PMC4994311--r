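KINDS <- c(patient = "patients", encounter = "encounters",
           prescription = "prescriptions", med_admin = "med_admins",
           tox_screen = "tox_screens")

CSV_FILES <- c(patients = "patients.csv", encounters = "encounters.csv",
               prescriptions = "prescriptions.csv",
               med_admins = "med_admins.csv", tox_screens = "tox_screens.csv")

# Serialize one entity table to plain character columns (ISO-8601 UTC
# timestamps, YYYY-MM-DD dates) so both file formats carry identical text.
serialize_table <- function(df) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_utc(df[[nm]])
    if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
  }
  df
}

#' Read an EMR event log into an event store
#'
#' Two plain-text on-disk formats are supported:
#' * `JSONL` — one JSON object per line, each with a `"kind"` field in
#'   `{patient, encounter, prescription, med_admin, tox_screen}` plus that
#'   kind's fields (snake_case, ISO-8601 timestamps).
#' * `CSV_DIR` — a directory of five CSVs (`patients.csv`,
#'   `encounters.csv`, `prescriptions.csv`, `med_admins.csv`,
#'   `tox_screens.csv`), header row required.
#'
#' Malformed records fail with the offending line (or file/row) and field
#' named; dangling references fail store validation with the offending ids
#' listed. Unknown enum values are rejected, never coerced.
#'
#' @param path File (JSONL) or directory (CSV_DIR).
#' @param format `"JSONL"` or `"CSV_DIR"`.
#' @return A validated [event_store()].
#' @export
load_event_log <- function(path, format = c("JSONL", "CSV_DIR")) {
  format <- match.arg(format)
  if (format == "JSONL") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines_keep <- which(nzchar(trimws(lines)))
    recs <- vector("list", length(lines_keep))
    kinds <- character(length(lines_keep))
    for (i in seq_along(lines_keep)) {
      ln <- lines_keep[i]
      rec <- tryCatch(jsonlite::fromJSON(lines[ln]),
                      error = function(e) {
                        stop(sprintf("line %d: invalid JSON (%s)", ln,
                                     conditionMessage(e)), call. = FALSE)
                      })
      if (is.null(rec$kind) || !(rec$kind %in% names(KINDS))) {
        stop(sprintf("line %d: field 'kind' missing or invalid", ln),
             call. = FALSE)
      }
      kinds[i] <- rec$kind
      rec$kind <- NULL
      recs[[i]] <- lapply(rec, function(v) if (is.null(v)) NA else v)
    }
    tabs <- lapply(names(KINDS), function(k) {
      rows <- recs[kinds == k]
      if (length(rows) == 0) return(NULL)
      dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    })
    names(tabs) <- KINDS
    event_store(patients = tabs$patients, encounters = tabs$encounters,
                prescriptions = tabs$prescriptions,
                med_admins = tabs$med_admins, tox_screens = tabs$tox_screens)
  } else {
    if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
    tabs <- lapply(CSV_FILES, function(f) {
      fp <- file.path(path, f)
      if (!file.exists(fp)) return(NULL)
      readr::read_csv(fp, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
    })
    event_store(patients = tabs$patients, encounters = tabs$encounters,
                prescriptions = tabs$prescriptions,
                med_admins = tabs$med_admins, tox_screens = tabs$tox_screens)
  }
}

#' Write an event store to disk
#'
#' The on-disk record content is identical between formats, so
#' `load_event_log(write_event_log(store, ...))` round-trips the store
#' event-for-event in either format, and equal stores always serialize to
#' identical bytes.
#'
#' @param store An [event_store()].
#' @param path Output file (JSONL) or directory (CSV_DIR; created if
#'   needed).
#' @param format `"JSONL"` or `"CSV_DIR"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(store, path, format = c("JSONL", "CSV_DIR")) {
  format <- match.arg(format)
  stopifnot(inherits(store, "event_store"))
  if (format == "JSONL") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (kind in names(KINDS)) {
      tab <- serialize_table(store[[KINDS[[kind]]]])
      if (nrow(tab) == 0) next
      tab <- tibble::add_column(tab, kind = kind, .before = 1)
      for (i in seq_len(nrow(tab))) {
        rec <- as.list(tab[i, ])
        rec <- rec[!vapply(rec, is.na, logical(1))]
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
      }
    }
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (entity in names(CSV_FILES)) {
      readr::write_csv(serialize_table(store[[entity]]),
                       file.path(path, CSV_FILES[[entity]]), progress = FALSE)
    }
  }
  invisible(path)
}
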