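#' Surveillance configuration
#'
#' Collects every numeric threshold of the two rule-based CVC-BSI detection
#' algorithms in one validated record. Defaults encode the published rule
#' set: fever strictly above 38 degrees C, systolic blood pressure strictly
#' below 90 mmHg or diastolic at or below 60 mmHg, a symptom window of three
#' days before and after the anchoring blood culture, a 48-hour pairing
#' window for contaminant cultures, catheter-tip cultures matching within
#' 48 hours after the blood culture at >= 1000 CFU/ml, paired central and
#' peripheral draws at most 15 minutes apart with a differential time to
#' positivity of at least 2 hours (central flagging first), the 14-day
#' repeat infection timeframe, and healthcare-associated classification from
#' admission day 3 onward (admission day = day 1) or on day 1-2 after a
#' readmission within 48 hours.
#'
#' @param fever_threshold fever threshold, degrees C; a temperature is a
#'   symptom when strictly greater than this value.
#' @param sbp_threshold systolic pressure threshold, mmHg; symptom when
#'   strictly less.
#' @param dbp_threshold diastolic pressure threshold, mmHg; symptom when
#'   less than or equal.
#' @param symptom_window_days days before and after the anchor inside which
#'   a symptom qualifies (closed interval, clock arithmetic).
#' @param contaminant_pair_window_hours maximum hours between two draws
#'   growing the same common commensal.
#' @param tip_window_hours hours after the blood culture inside which a
#'   catheter-tip culture can match.
#' @param tip_cfu_threshold minimum tip-culture load, CFU/ml (inclusive).
#' @param paired_draw_max_minutes maximum minutes between the central and
#'   peripheral draws of a differential-time-to-positivity pair.
#' @param dtp_min_hours minimum peripheral-minus-central time-to-positivity
#'   difference, hours (inclusive).
#' @param rit_days length of the repeat infection timeframe in calendar
#'   days, counting the index day as day 1.
#' @param ha_min_day first admission day (admission day = day 1) on which an
#'   episode is healthcare-associated without a qualifying readmission.
#' @param ha_readmission_window_hours look-back from admission to the
#'   previous discharge for the readmission rule.
#' @param bootstrap_reps bootstrap replicates for extrapolated confidence
#'   intervals.
#' @param ci_level confidence level for all intervals.
#' @param require_symptoms_for_pathogens if TRUE, the symptom-using
#'   algorithm variant also demands symptoms for pathogen-anchored episodes;
#'   the default FALSE restricts the symptom conjunct to the contaminant
#'   pathway, mirroring the ECDC bloodstream-infection case definition.
#' @return an object of class \code{surveillance_config}.
#' @examples
#' cfg <- surveillance_config()
#' cfg$fever_threshold
#' @export
surveillance_config <- function(fever_threshold = 38.0,
                                sbp_threshold = 90,
                                dbp_threshold = 60,
                                symptom_window_days = 3L,
                                contaminant_pair_window_hours = 48,
                                tip_window_hours = 48,
                                tip_cfu_threshold = 1000,
                                paired_draw_max_minutes = 15,
                                dtp_min_hours = 2,
                                rit_days = 14L,
                                ha_min_day = 3L,
                                ha_readmission_window_hours = 48,
                                bootstrap_reps = 10000L,
                                ci_level = 0.95,
                                require_symptoms_for_pathogens = FALSE) {
  cfg <- list(
    fever_threshold = as.numeric(fever_threshold),
    sbp_threshold = as.numeric(sbp_threshold),
    dbp_threshold = as.numeric(dbp_threshold),
    symptom_window_days = as.integer(symptom_window_days),
    contaminant_pair_window_hours = as.numeric(contaminant_pair_window_hours),
    tip_window_hours = as.numeric(tip_window_hours),
    tip_cfu_threshold = as.numeric(tip_cfu_threshold),
    paired_draw_max_minutes = as.numeric(paired_draw_max_minutes),
    dtp_min_hours = as.numeric(dtp_min_hours),
    rit_days = as.integer(rit_days),
    ha_min_day = as.integer(ha_min_day),
    ha_readmission_window_hours = as.numeric(ha_readmission_window_hours),
    bootstrap_reps = as.integer(bootstrap_reps),
    ci_level = as.numeric(ci_level),
    require_symptoms_for_pathogens = isTRUE(require_symptoms_for_pathogens)
  )
  class(cfg) <- "surveillance_config"
  validate_surveillance_config(cfg)
}

validate_surveillance_config <- function(cfg) {
  stopifnot(inherits(cfg, "surveillance_config"))
  pos <- c("fever_threshold", "sbp_threshold", "dbp_threshold",
           "contaminant_pair_window_hours", "tip_window_hours",
           "tip_cfu_threshold", "paired_draw_max_minutes", "dtp_min_hours",
           "rit_days", "ha_min_day", "ha_readmission_window_hours",
           "bootstrap_reps")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.finite(v) || v <= 0) {
      stop("surveillance_config: '", f, "' must be strictly positive",
           call. = FALSE)
    }
  }
  if (cfg$symptom_window_days < 0) {
    stop("surveillance_config: 'symptom_window_days' must be >= 0",
         call. = FALSE)
  }
  if (!is.finite(cfg$ci_level) || cfg$ci_level <= 0 || cfg$ci_level >= 1) {
    stop("surveillance_config: 'ci_level' must lie in (0, 1)", call. = FALSE)
  }
  cfg
}

#' @export
print.surveillance_config <- function(x, ...) {
  cat("CVC-BSI surveillance configuration\n")
  flds <- setdiff(names(x), "require_symptoms_for_pathogens")
  for (f in flds) cat(sprintf("  %-32s %s\n", f, format(x[[f]])))
  cat(sprintf("  %-32s %s\n", "require_symptoms_for_pathogens",
              x$require_symptoms_for_pathogens))
  invisible(x)
}

#' Read a surveillance configuration from a YAML file
#'
#' Keys mirror the \code{\link{surveillance_config}} arguments; keys absent
#' from the file take the documented defaults. Unknown keys are an error so
#' that typos do not silently fall back to defaults.
#'
#' @param path path to a YAML key:value file.
#' @return a \code{surveillance_config}.
#' @export
read_surveillance_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(surveillance_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(surveillance_config, vals)
}
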