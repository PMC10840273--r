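#' Enumerate potential CVC-BSI episodes
#'
#' The unit of surveillance: every blood-culture draw during an admission
#' is one potential episode, and every admission during which no blood
#' culture was taken counts as exactly one potential episode (so that
#' denominators cover the whole admitted population, not only tested
#' patients).
#'
#' @param bundle a validated \code{\link{cohort_bundle}}.
#' @return data.frame with columns \code{episode_id}, \code{admission_id},
#'   \code{anchor} (\code{"bcx_draw"} or \code{"admission_without_bcx"}),
#'   \code{anchor_draw_id}, \code{anchor_ts}; ordered by admission, anchor
#'   time, then draw id.
#' @export
enumerate_potential_episodes <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dt <- draw_table(bundle$blood_cultures)
  adm <- bundle$admissions
  no_bcx <- adm[!(adm$admission_id %in% dt$admission_id), , drop = FALSE]
  ep_draw <- data.frame(
    episode_id = sprintf("bcx:%s", dt$draw_id),
    admission_id = dt$admission_id,
    anchor = rep("bcx_draw", nrow(dt)),
    anchor_draw_id = dt$draw_id,
    anchor_ts = dt$draw_ts,
    stringsAsFactors = FALSE)
  ep_adm <- data.frame(
    episode_id = sprintf("adm:%s", no_bcx$admission_id),
    admission_id = no_bcx$admission_id,
    anchor = rep("admission_without_bcx", nrow(no_bcx)),
    anchor_draw_id = rep(NA_character_, nrow(no_bcx)),
    anchor_ts = no_bcx$admit_ts,
    stringsAsFactors = FALSE)
  ep <- rbind(ep_draw, ep_adm)
  ep <- ep[order(ep$admission_id, ep$anchor_ts, ep$anchor_draw_id,
                 method = "radix", na.last = FALSE), , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

#' Test for BSI symptoms around an anchor time
#'
#' A symptom is fever (temperature strictly above the fever threshold) or
#' hypotension (systolic strictly below the systolic threshold, or
#' diastolic at or below the diastolic threshold). The observation must
#' fall inside the closed window of \code{symptom_window_days} days before
#' or after the anchor, computed as clock arithmetic (plus/minus
#' \code{symptom_window_days} times 24 hours), matching the infection
#' window period around the blood culture.
#'
#' @param vitals vital observations for the admission (columns
#'   \code{obs_ts}, \code{kind}, \code{value}).
#' @param anchor_ts POSIXct anchor (normally the blood-culture draw time).
#' @param config a \code{\link{surveillance_config}}.
#' @return TRUE if at least one qualifying observation exists in-window.
#' @export
has_bsi_symptoms <- function(vitals, anchor_ts, config = surveillance_config()) {
  if (!nrow(vitals)) return(FALSE)
  half <- config$symptom_window_days * 24 * 3600
  inwin <- vitals$obs_ts >= anchor_ts - half & vitals$obs_ts <= anchor_ts + half
  if (!any(inwin)) return(FALSE)
  v <- vitals[inwin, , drop = FALSE]
  any((v$kind == "temperature" & v$value > config$fever_threshold) |
      (v$kind == "sbp" & v$value < config$sbp_threshold) |
      (v$kind == "dbp" & v$value <= config$dbp_threshold))
}

#' Confirm a bloodstream infection for one positive draw
#'
#' A recognised pathogen needs a single positive culture. A common
#' commensal only confirms a BSI when a second, distinct draw grows the
#' same commensal species within the pairing window (default 48 h) — and,
#' under the symptom-using algorithm variant, BSI symptoms are present
#' around the draw. Under the microbiology-only variant the symptom
#' conjunct is dropped.
#'
#' @param draw_id id of a positive draw.
#' @param blood_cultures long blood-culture table for the draw's admission
#'   (one row per draw x isolate).
#' @param vitals vital observations for the admission.
#' @param variant \code{"with_symptoms"} (algorithm 1) or
#'   \code{"microbiology_only"} (algorithm 2).
#' @param config a \code{\link{surveillance_config}}.
#' @param commensal_list character vector of common-commensal codes.
#' @return list with \code{confirmed} (logical), \code{evidence}
#'   (character vector of satisfied criterion tags) and
#'   \code{qualifying_organisms} (codes that carried the confirmation —
#'   the organisms a catheter-attribution match must involve).
#' @export
confirm_bsi <- function(draw_id, blood_cultures, vitals,
                        variant = c("with_symptoms", "microbiology_only"),
                        config = surveillance_config(),
                        commensal_list = default_commensal_list()) {
  variant <- match.arg(variant)
  bc <- blood_cultures
  iso <- bc[bc$draw_id == draw_id & !is.na(bc$organism_code), , drop = FALSE]
  if (!nrow(iso)) {
    stop("confirm_bsi called on a negative draw: ", draw_id, call. = FALSE)
  }
  draw_ts <- iso$draw_ts[1L]
  cls <- classify_isolate(iso$organism_code, commensal_list)
  evidence <- character()
  qualifying <- character()

  symptoms_checked <- FALSE
  symptoms_present <- NA
  need_symptoms <- function() {
    if (!symptoms_checked) {
      symptoms_present <<- has_bsi_symptoms(vitals, draw_ts, config)
      symptoms_checked <<- TRUE
    }
    symptoms_present
  }

  path_orgs <- iso$organism_code[cls == "pathogen"]
  if (length(path_orgs)) {
    ok <- TRUE
    if (variant == "with_symptoms" && config$require_symptoms_for_pathogens) {
      ok <- need_symptoms()
      if (ok) evidence <- c(evidence, "symptoms")
    }
    if (ok) {
      evidence <- c(evidence, "pathogen_bsi")
      qualifying <- c(qualifying, path_orgs)
    }
  }

  comm_orgs <- iso$organism_code[cls == "commensal"]
  if (length(comm_orgs)) {
    other <- bc[bc$draw_id != draw_id & !is.na(bc$organism_code), ,
                drop = FALSE]
    win_h <- config$contaminant_pair_window_hours
    for (org in unique(comm_orgs)) {
      mates <- other[other$organism_code == org &
                       abs(hours_between(other$draw_ts, draw_ts)) <= win_h, ,
                     drop = FALSE]
      if (nrow(mates)) {
        ok <- variant != "with_symptoms" || need_symptoms()
        if (ok) {
          if (variant == "with_symptoms" && !("symptoms" %in% evidence)) {
            evidence <- c(evidence, "symptoms")
          }
          evidence <- unique(c(evidence, "commensal_pair"))
          qualifying <- c(qualifying, org)
        }
      }
    }
  }

  list(confirmed = length(qualifying) > 0,
       evidence = unique(evidence),
       qualifying_organisms = unique(qualifying))
}

#' Catheter attribution via CVC-tip culture
#'
#' A BSI is catheter-related when a quantitative CVC-tip culture at or
#' above the CFU threshold (default 1000 CFU/ml) grows the same species as
#' a BSI-qualifying blood-culture isolate and was collected within the tip
#' window after the blood culture (default 48 h; tips collected before the
#' draw never match).
#'
#' @param draw_id id of a BSI-confirmed draw.
#' @param blood_cultures long blood-culture table for the admission.
#' @param tip_cultures tip-culture table for the admission.
#' @param qualifying_organisms organism codes from \code{\link{confirm_bsi}}.
#' @param config a \code{\link{surveillance_config}}.
#' @return TRUE when a matching tip culture exists.
#' @export
cvc_attribution_tip <- function(draw_id, blood_cultures, tip_cultures,
                                qualifying_organisms,
                                config = surveillance_config()) {
  if (!nrow(tip_cultures) || !length(qualifying_organisms)) return(FALSE)
  draw_ts <- blood_cultures$draw_ts[match(draw_id, blood_cultures$draw_id)]
  dt_h <- hours_between(tip_cultures$collect_ts, draw_ts)
  any(tip_cultures$cfu_per_ml >= config$tip_cfu_threshold &
        tip_cultures$organism_code %in% qualifying_organisms &
        dt_h >= 0 & dt_h <= config$tip_window_hours)
}

#' Catheter attribution via differential time to positivity
#'
#' A BSI is catheter-related when the draw belongs to a central/peripheral
#' pair taken at most \code{paired_draw_max_minutes} apart (default 15
#' min), both growing the same qualifying species with recorded times to
#' positivity, and the peripheral culture flags at least
#' \code{dtp_min_hours} (default 2 h) later than the central one. Missing
#' time to positivity on either member fails the criterion — no
#' imputation. Draws with unspecified site can anchor a BSI but never form
#' a differential-time pair.
#'
#' @inheritParams cvc_attribution_tip
#' @return TRUE when a qualifying pair exists.
#' @export
cvc_attribution_dtp <- function(draw_id, blood_cultures,
                                qualifying_organisms,
                                config = surveillance_config()) {
  if (!length(qualifying_organisms)) return(FALSE)
  bc <- blood_cultures
  me <- bc[bc$draw_id == draw_id & !is.na(bc$organism_code), , drop = FALSE]
  site_me <- me$site[1L]
  if (!site_me %in% c("central", "peripheral")) return(FALSE)
  site_other <- if (site_me == "central") "peripheral" else "central"
  others <- bc[bc$draw_id != draw_id & bc$site == site_other &
                 !is.na(bc$organism_code), , drop = FALSE]
  if (!nrow(others)) return(FALSE)
  for (org in intersect(unique(me$organism_code), qualifying_organisms)) {
    my_ttp <- me$ttp_hours[me$organism_code == org]
    if (!length(my_ttp) || is.na(my_ttp[1L])) next
    cand <- others[others$organism_code == org &
                     !is.na(others$ttp_hours) &
                     abs(minutes_between(others$draw_ts, me$draw_ts[1L])) <=
                       config$paired_draw_max_minutes, , drop = FALSE]
    if (!nrow(cand)) next
    if (site_me == "central") {
      if (any(cand$ttp_hours - my_ttp[1L] >= config$dtp_min_hours)) return(TRUE)
    } else {
      if (any(my_ttp[1L] - cand$ttp_hours >= config$dtp_min_hours)) return(TRUE)
    }
  }
  FALSE
}

#' Detect CVC-BSI episodes (before repeat-infection deduplication)
#'
#' For every potential episode anchored on a positive draw, the episode is
#' CVC-BSI when the BSI is confirmed (\code{\link{confirm_bsi}}) and the
#' infection is attributed to the catheter by a matching tip culture
#' (\code{\link{cvc_attribution_tip}}) or a differential-time-to-positivity
#' pair (\code{\link{cvc_attribution_dtp}}). Episodes anchored on negative
#' draws or on admissions without cultures are always negative. When a
#' draw satisfies both attribution criteria both tags are recorded; the
#' episode counts once.
#'
#' @param bundle a validated \code{\link{cohort_bundle}}.
#' @param variant \code{"with_symptoms"} or \code{"microbiology_only"}.
#' @param config a \code{\link{surveillance_config}}.
#' @return data.frame of pre-deduplication labels: \code{episode_id},
#'   \code{admission_id}, \code{anchor_draw_id}, \code{anchor_ts},
#'   \code{cvc_bsi}, \code{evidence} (semicolon-joined tags).
#' @export
detect_cvc_bsi <- function(bundle,
                           variant = c("with_symptoms", "microbiology_only"),
                           config = surveillance_config()) {
  variant <- match.arg(variant)
  episodes <- enumerate_potential_episodes(bundle)
  labels <- data.frame(
    episode_id = episodes$episode_id,
    admission_id = episodes$admission_id,
    anchor_draw_id = episodes$anchor_draw_id,
    anchor_ts = episodes$anchor_ts,
    cvc_bsi = logical(nrow(episodes)),
    evidence = character(nrow(episodes)),
    stringsAsFactors = FALSE)
  if (!nrow(episodes)) return(labels)

  bc <- bundle$blood_cultures
  pos_ids <- unique(bc$draw_id[!is.na(bc$organism_code)])
  todo <- which(!is.na(labels$anchor_draw_id) &
                  labels$anchor_draw_id %in% pos_ids)
  if (!length(todo)) return(labels)

  bc_by_adm <- split(bc, bc$admission_id)
  tips_by_adm <- split(bundle$tip_cultures, bundle$tip_cultures$admission_id)
  vit_by_adm <- split(bundle$vitals, bundle$vitals$admission_id)
  empty_tips <- empty_tip_cultures()
  empty_vit <- empty_vitals()

  for (i in todo) {
    adm_id <- labels$admission_id[i]
    d_id <- labels$anchor_draw_id[i]
    bc_adm <- bc_by_adm[[adm_id]]
    vit_adm <- vit_by_adm[[adm_id]] %||% empty_vit
    conf <- confirm_bsi(d_id, bc_adm, vit_adm, variant, config,
                        bundle$commensal_list)
    ev <- conf$evidence
    pos <- FALSE
    if (conf$confirmed) {
      tips_adm <- tips_by_adm[[adm_id]] %||% empty_tips
      tip_ok <- cvc_attribution_tip(d_id, bc_adm, tips_adm,
                                    conf$qualifying_organisms, config)
      dtp_ok <- cvc_attribution_dtp(d_id, bc_adm,
                                    conf$qualifying_organisms, config)
      if (tip_ok) ev <- c(ev, "tip_match")
      if (dtp_ok) ev <- c(ev, "dtp_match")
      pos <- tip_ok || dtp_ok
    }
    labels$cvc_bsi[i] <- pos
    labels$evidence[i] <- paste(ev, collapse = ";")
  }
  labels
}
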