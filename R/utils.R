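# Internal helpers shared across modules.

TS_FORMAT <- "%Y-%m-%dT%H:%M"

#' Parse ISO-8601 minute-resolution timestamps
#'
#' Timestamps in the cohort files are timezone-naive local clock times at
#' minute resolution (\code{YYYY-MM-DDTHH:MM}). They are represented
#' internally as POSIXct in UTC so that duration arithmetic is exact clock
#' arithmetic, never shifted by daylight-saving transitions.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector (UTC).
#' @keywords internal
parse_ts <- function(x) {
  out <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop("unparseable timestamp(s) at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         " (expected YYYY-MM-DDTHH:MM, got e.g. '", x[which(bad)[1L]], "')",
         call. = FALSE)
  }
  out[is.na(x) | x == ""] <- NA
  out
}

format_ts <- function(x) {
  ifelse(is.na(x), "", format(x, TS_FORMAT, tz = "UTC"))
}

hours_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

minutes_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "mins"))
}

ts_date <- function(x) as.Date(x, tz = "UTC")

#' Round half away from zero
#'
#' Reporting rounds half-up to the printed precision (3 decimals for
#' metrics, 2 for rates); base \code{round()} rounds half to even, which
#' turns 0.8125 into 0.812 rather than the conventional 0.813.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

# Normalise an organism code: trim whitespace, case-fold. Codes are opaque
# species-level strings; matching is exact after normalisation.
norm_code <- function(x) {
  tolower(trimws(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
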