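#' Parse ISO-8601 timestamps to UTC
#'
#' All timestamps in the package are `POSIXct` normalised to UTC. Input
#' strings may carry `Z` or a numeric offset; offsets are converted, not
#' dropped. A "day" is always 86,400 seconds, so window arithmetic is
#' immune to daylight-saving discontinuities.
#'
#' @param x Character vector of ISO-8601 timestamps (e.g.
#'   `"2015-04-07T13:30:00Z"`). `NA` passes through.
#' @return `POSIXct` vector in UTC.
#' @export
#' @examples
#' parse_utc("2015-04-01T10:00:00+02:00") # 08:00:00 UTC
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(lubridate::with_tz(x, "UTC"))
  }
  out <- lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unparseable ISO-8601 timestamp(s): ",
         paste(utils::head(x[bad], 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Format UTC timestamps as ISO-8601 strings
#'
#' Inverse of [parse_utc()] at whole-second resolution (the resolution at
#' which the package stores and simulates events).
#'
#' @param x `POSIXct` vector.
#' @return Character vector like `"2015-04-07T13:30:00Z"`.
#' @export
format_utc <- function(x) {
  out <- format(lubridate::with_tz(x, "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  out[is.na(x)] <- NA_character_
  out
}

# Shift a timestamp by a (possibly fractional) number of days.
days_before <- function(t, days) t - days * SECONDS_PER_DAY

# Elapsed time in days between two POSIXct instants.
elapsed_days <- function(from, to) as.numeric(to) / SECONDS_PER_DAY - as.numeric(from) / SECONDS_PER_DAY
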