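#' In-patient hospital-days of a set of admissions
#'
#' Whole days per admission — discharge date minus admission date — with a
#' minimum of one day per admission, summed over the cohort. This is the
#' denominator convention behind incidence per 1000 in-patient
#' hospital-days.
#'
#' @param admissions admissions data.frame with \code{admit_ts} and
#'   \code{discharge_ts}.
#' @return total hospital-days (numeric).
#' @export
hospital_days <- function(admissions) {
  d <- as.numeric(ts_date(admissions$discharge_ts) -
                    ts_date(admissions$admit_ts))
  sum(pmax(d, 1))
}

#' CVC-BSI rates against the standard denominators
#'
#' Expresses a case count against potential episodes, positive blood
#' cultures and admissions (as percentages) and against in-patient
#' hospital-days (per 1000). Rates with a zero denominator are NA, never
#' silently zero. Reporting precision follows the convention of 2 decimals
#' (half-up) for the rendered strings; the returned numeric rates are
#' unrounded.
#'
#' @param case_count number of CVC-BSI episodes.
#' @param denominators named list/vector with any of
#'   \code{potential_episodes}, \code{positive_bcx}, \code{admissions},
#'   \code{hospital_days}.
#' @return object of class \code{rate_table}: data.frame with columns
#'   \code{denominator}, \code{n}, \code{rate} (percent, or per 1000 for
#'   hospital-days), \code{unit}.
#' @examples
#' rates_table(51, list(potential_episodes = 4326, positive_bcx = 1766,
#'                      admissions = 1000, hospital_days = 17782))
#' @export
rates_table <- function(case_count, denominators) {
  denominators <- as.list(denominators)
  known <- c("potential_episodes", "positive_bcx", "admissions",
             "hospital_days")
  unknown <- setdiff(names(denominators), known)
  if (length(unknown)) {
    stop("unknown denominator(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(names(denominators), function(nm) {
    n <- denominators[[nm]]
    per <- if (nm == "hospital_days") 1000 else 100
    unit <- if (nm == "hospital_days") "per_1000" else "percent"
    if (n <= 0) {
      warning("rate undefined for zero denominator: ", nm, call. = FALSE)
      rate <- NA_real_
    } else {
      rate <- case_count / n * per
    }
    data.frame(denominator = nm, n = n, rate = rate, unit = unit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "case_count") <- case_count
  class(out) <- c("rate_table", "data.frame")
  out
}

#' @export
print.rate_table <- function(x, ...) {
  cat("CVC-BSI rate table (", attr(x, "case_count"), "cases )\n")
  for (i in seq_len(nrow(x))) {
    suffix <- if (x$unit[i] == "percent") "%" else " per 1000"
    cat(sprintf("  %-20s (n = %s): %s%s\n", x$denominator[i],
                format(x$n[i], big.mark = ","),
                format(round_half_up(x$rate[i], 2), nsmall = 2), suffix))
  }
  invisible(x)
}

#' Incidence time series per 1000 in-patient hospital-days
#'
#' Bins CVC-BSI episodes (all, and healthcare-associated separately) by
#' the calendar month of their anchoring blood culture, divides by the
#' hospital-days contributed to the month by overlapping stays, and scales
#' per 1000. A stay spanning several months contributes each of its days
#' to the day's month, so the per-bin denominators sum to the cohort's
#' total hospital-days and the series conserves the total case count.
#'
#' @param labels final labels from \code{\link{run_surveillance}}.
#' @param admissions admissions data.frame.
#' @param bin bin width; only \code{"month"} is supported.
#' @return data.frame with \code{bin_start} (Date), \code{cases},
#'   \code{ha_cases}, \code{hospital_days}, \code{rate}, \code{ha_rate};
#'   attribute \code{overall} carries the full-period rates.
#' @export
incidence_series <- function(labels, admissions, bin = "month") {
  if (bin != "month") stop("only monthly bins are supported", call. = FALSE)
  if (!nrow(admissions)) stop("no admissions provided", call. = FALSE)
  month_floor <- function(d) as.Date(format(d, "%Y-%m-01"))

  # distribute each stay's whole days over months; zero-night stays count
  # one day in the admission month
  day_months <- lapply(seq_len(nrow(admissions)), function(i) {
    a0 <- ts_date(admissions$admit_ts[i])
    d0 <- ts_date(admissions$discharge_ts[i])
    if (d0 <= a0) a0 else seq(a0, d0 - 1, by = "day")
  })
  all_days <- as.Date(unlist(day_months), origin = "1970-01-01")
  days_by_month <- table(format(all_days, "%Y-%m-01"))

  pos <- labels[labels$cvc_bsi, , drop = FALSE]
  cases_by_month <- table(format(ts_date(pos$anchor_ts), "%Y-%m-01"))
  ha_by_month <- table(format(ts_date(pos$anchor_ts[pos$ha]), "%Y-%m-01"))

  months <- sort(unique(c(names(days_by_month), names(cases_by_month))))
  get0n <- function(tab, m) if (m %in% names(tab)) as.numeric(tab[[m]]) else 0
  out <- data.frame(
    bin_start = as.Date(months),
    cases = vapply(months, get0n, numeric(1), tab = cases_by_month),
    ha_cases = vapply(months, get0n, numeric(1), tab = ha_by_month),
    hospital_days = vapply(months, get0n, numeric(1), tab = days_by_month),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$rate <- ifelse(out$hospital_days > 0,
                     out$cases / out$hospital_days * 1000, NA_real_)
  out$ha_rate <- ifelse(out$hospital_days > 0,
                        out$ha_cases / out$hospital_days * 1000, NA_real_)
  total_days <- hospital_days(admissions)
  attr(out, "overall") <- c(rate = sum(out$cases) / total_days * 1000,
                            ha_rate = sum(out$ha_cases) / total_days * 1000,
                            hospital_days = total_days)
  out
}
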