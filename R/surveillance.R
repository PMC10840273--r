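#' Apply the 14-day repeat infection timeframe
#'
#' Within an admission, positives are scanned in anchor-time order (ties
#' broken by draw id). The first positive opens an episode whose repeat
#' infection timeframe (RIT) covers \code{rit_days} calendar days counting
#' the index day as day 1 — with the default 14 days, the index anchor
#' date plus the following 13 days. Any later positive anchored inside the
#' RIT is marked \code{suppressed_by_rit} (its \code{cvc_bsi} flag is
#' cleared so it never enters counts) and linked to the index episode. The
#' first positive after RIT expiry opens a new episode with a new RIT —
#' the window is anchored on index episodes, never rolling. Negative
#' episodes inside a RIT stay negative; they are not suppressed.
#'
#' @param labels pre-deduplication labels from \code{\link{detect_cvc_bsi}}.
#' @param config a \code{\link{surveillance_config}}.
#' @return the label data.frame with columns \code{suppressed_by_rit} and
#'   \code{index_episode_id} added and \code{cvc_bsi} cleared on
#'   suppressed episodes.
#' @export
apply_rit <- function(labels, config = surveillance_config()) {
  if (!"suppressed_by_rit" %in% names(labels)) {
    labels$suppressed_by_rit <- FALSE
  }
  if (!"index_episode_id" %in% names(labels)) {
    labels$index_episode_id <- NA_character_
  }
  pos_idx <- which(labels$cvc_bsi)
  if (!length(pos_idx)) return(labels)
  for (adm in unique(labels$admission_id[pos_idx])) {
    idx <- pos_idx[labels$admission_id[pos_idx] == adm]
    ord <- order(labels$anchor_ts[idx], labels$anchor_draw_id[idx],
                 method = "radix")
    idx <- idx[ord]
    rit_end <- NULL
    index_ep <- NULL
    for (i in idx) {
      d <- ts_date(labels$anchor_ts[i])
      if (is.null(rit_end) || d > rit_end) {
        rit_end <- d + (config$rit_days - 1L)
        index_ep <- labels$episode_id[i]
      } else {
        labels$suppressed_by_rit[i] <- TRUE
        labels$index_episode_id[i] <- index_ep
        labels$cvc_bsi[i] <- FALSE
      }
    }
  }
  labels
}

#' Healthcare-associated classification of a CVC-BSI episode
#'
#' An episode is healthcare-associated (HA) when its anchoring blood
#' culture was taken on admission day \code{ha_min_day} or later (day of
#' admission = day 1, calendar-date arithmetic), or on day 1 or 2 when the
#' same patient had a previous admission discharged within
#' \code{ha_readmission_window_hours} (default 48 h) before the current
#' admission (clock-time comparison).
#'
#' @param anchor_ts POSIXct anchor of the episode.
#' @param admission one-row data.frame for the episode's admission.
#' @param prior_admissions admissions of the same patient (the current one
#'   and unrelated ones are ignored automatically).
#' @param config a \code{\link{surveillance_config}}.
#' @return list with \code{ha} (logical) and \code{evidence} (tag
#'   \code{"ha_day3"} or \code{"ha_readmission"}, or empty).
#' @export
classify_ha <- function(anchor_ts, admission, prior_admissions,
                        config = surveillance_config()) {
  day <- as.integer(ts_date(anchor_ts) - ts_date(admission$admit_ts)) + 1L
  if (day >= config$ha_min_day) {
    return(list(ha = TRUE, evidence = "ha_day3"))
  }
  if (nrow(prior_admissions)) {
    gap_h <- hours_between(admission$admit_ts, prior_admissions$discharge_ts)
    qualifies <- prior_admissions$admission_id != admission$admission_id &
      gap_h >= 0 & gap_h <= config$ha_readmission_window_hours
    if (any(qualifies)) {
      return(list(ha = TRUE, evidence = "ha_readmission"))
    }
  }
  list(ha = FALSE, evidence = character())
}

#' Run the full CVC-BSI surveillance pipeline on a cohort
#'
#' Enumerates potential episodes, applies the chosen detection algorithm
#' variant, deduplicates repeat positives with the repeat infection
#' timeframe, and classifies the surviving CVC-BSI episodes as
#' healthcare-associated or not. The result is deterministic and carries a
#' complete evidence trail per episode.
#'
#' @param bundle a validated \code{\link{cohort_bundle}}.
#' @param variant \code{"with_symptoms"} (algorithm 1: microbiology plus
#'   bedside symptoms) or \code{"microbiology_only"} (algorithm 2).
#' @param config a \code{\link{surveillance_config}}.
#' @return data.frame with one row per potential episode:
#'   \code{episode_id}, \code{admission_id}, \code{anchor_ts},
#'   \code{variant}, \code{cvc_bsi}, \code{ha}, \code{suppressed_by_rit},
#'   \code{index_episode_id}, \code{evidence}.
#' @examples
#' sim <- generate_cohort(cohort_sim_config(n_admissions = 60, seed = 7))
#' labels <- run_surveillance(sim$bundle, "microbiology_only")
#' table(labels$cvc_bsi)
#' @export
run_surveillance <- function(bundle,
                             variant = c("with_symptoms",
                                         "microbiology_only"),
                             config = surveillance_config()) {
  variant <- match.arg(variant)
  labels <- detect_cvc_bsi(bundle, variant, config)
  labels <- apply_rit(labels, config)
  labels$ha <- FALSE
  pos <- which(labels$cvc_bsi)
  if (length(pos)) {
    adm <- bundle$admissions
    for (i in pos) {
      a <- adm[adm$admission_id == labels$admission_id[i], , drop = FALSE]
      prior <- adm[adm$patient_id == a$patient_id, , drop = FALSE]
      res <- classify_ha(labels$anchor_ts[i], a, prior, config)
      labels$ha[i] <- res$ha
      if (length(res$evidence)) {
        labels$evidence[i] <- paste(c(labels$evidence[i], res$evidence),
                                    collapse = ";")
      }
    }
  }
  data.frame(episode_id = labels$episode_id,
             admission_id = labels$admission_id,
             anchor_ts = labels$anchor_ts,
             variant = variant,
             cvc_bsi = labels$cvc_bsi,
             ha = labels$ha,
             suppressed_by_rit = labels$suppressed_by_rit,
             index_episode_id = labels$index_episode_id,
             evidence = labels$evidence,
             stringsAsFactors = FALSE)
}
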