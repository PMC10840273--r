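# Builders for tiny hand-specified cohorts, plus an independent
# brute-force oracle for the detection rules.

TEST_COMMENSALS <- c("staphylococcus epidermidis", "staphylococcus hominis",
                     "micrococcus luteus")

ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
}

mk_admissions <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(admission_id = r[[1]], patient_id = r[[2]],
               admit_ts = ts(r[[3]]), discharge_ts = ts(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

mk_draw <- function(draw_id, admission_id, draw_ts, site = "unspecified",
                    organism_code = NA_character_, ttp_hours = NA_real_) {
  data.frame(draw_id = draw_id, admission_id = admission_id,
             draw_ts = ts(draw_ts), site = site,
             organism_code = organism_code,
             ttp_hours = ttp_hours, stringsAsFactors = FALSE)
}

mk_vital <- function(admission_id, obs_ts, kind, value) {
  data.frame(admission_id = admission_id, obs_ts = ts(obs_ts), kind = kind,
             value = value, stringsAsFactors = FALSE)
}

mk_tip <- function(admission_id, collect_ts, organism_code, cfu_per_ml) {
  data.frame(admission_id = admission_id, collect_ts = ts(collect_ts),
             organism_code = organism_code, cfu_per_ml = cfu_per_ml,
             stringsAsFactors = FALSE)
}

# one 30-day admission starting 2018-03-01 08:00, id "A1"/patient "P1"
one_adm_bundle <- function(blood_cultures = NULL, tip_cultures = NULL,
                           vitals = NULL, extra_admissions = NULL) {
  adm <- mk_admissions(list("A1", "P1", "2018-03-01T08:00",
                            "2018-03-31T08:00"))
  if (!is.null(extra_admissions)) adm <- rbind(adm, extra_admissions)
  cohort_bundle(
    admissions = adm,
    blood_cultures = blood_cultures %||%
      cvcbsi:::empty_blood_cultures(),
    tip_cultures = tip_cultures %||% cvcbsi:::empty_tip_cultures(),
    vitals = vitals %||% cvcbsi:::empty_vitals(),
    commensal_list = TEST_COMMENSALS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent re-implementation of the per-episode decision, written as
# plain nested loops straight from the rule statement; used to
# cross-check detect_cvc_bsi on arbitrary cohorts.
oracle_positive <- function(bundle, draw_id, variant,
                            cfg = surveillance_config()) {
  bc <- bundle$blood_cultures
  mine <- bc[bc$draw_id == draw_id & !is.na(bc$organism_code), ,
             drop = FALSE]
  if (!nrow(mine)) return(FALSE)
  adm_id <- mine$admission_id[1]
  t0 <- mine$draw_ts[1]

  vit <- bundle$vitals[bundle$vitals$admission_id == adm_id, , drop = FALSE]
  symptoms <- FALSE
  for (r in seq_len(nrow(vit))) {
    gap <- abs(as.numeric(difftime(vit$obs_ts[r], t0, units = "secs")))
    if (gap <= cfg$symptom_window_days * 86400) {
      k <- vit$kind[r]; v <- vit$value[r]
      if ((k == "temperature" && v > cfg$fever_threshold) ||
          (k == "sbp" && v < cfg$sbp_threshold) ||
          (k == "dbp" && v <= cfg$dbp_threshold)) symptoms <- TRUE
    }
  }

  adm_bc <- bc[bc$admission_id == adm_id & !is.na(bc$organism_code), ,
               drop = FALSE]
  qualifying <- character()
  for (r in seq_len(nrow(mine))) {
    org <- mine$organism_code[r]
    if (!(org %in% bundle$commensal_list)) {
      qualifying <- c(qualifying, org)
    } else {
      for (s in seq_len(nrow(adm_bc))) {
        if (adm_bc$draw_id[s] == draw_id) next
        if (adm_bc$organism_code[s] != org) next
        gap_h <- abs(as.numeric(difftime(adm_bc$draw_ts[s], t0,
                                         units = "hours")))
        if (gap_h <= cfg$contaminant_pair_window_hours &&
            (variant == "microbiology_only" || symptoms)) {
          qualifying <- c(qualifying, org)
        }
      }
    }
  }
  if (!length(qualifying)) return(FALSE)

  tips <- bundle$tip_cultures[bundle$tip_cultures$admission_id == adm_id, ,
                              drop = FALSE]
  for (r in seq_len(nrow(tips))) {
    dt_h <- as.numeric(difftime(tips$collect_ts[r], t0, units = "hours"))
    if (tips$organism_code[r] %in% qualifying &&
        tips$cfu_per_ml[r] >= cfg$tip_cfu_threshold &&
        dt_h >= 0 && dt_h <= cfg$tip_window_hours) return(TRUE)
  }

  my_site <- mine$site[1]
  if (my_site %in% c("central", "peripheral")) {
    for (r in seq_len(nrow(mine))) {
      org <- mine$organism_code[r]
      if (!(org %in% qualifying) || is.na(mine$ttp_hours[r])) next
      for (s in seq_len(nrow(adm_bc))) {
        if (adm_bc$draw_id[s] == draw_id) next
        if (adm_bc$organism_code[s] != org) next
        if (is.na(adm_bc$ttp_hours[s])) next
        other_site <- adm_bc$site[s]
        if (!(other_site %in% c("central", "peripheral")) ||
            other_site == my_site) next
        gap_m <- abs(as.numeric(difftime(adm_bc$draw_ts[s], t0,
                                         units = "mins")))
        if (gap_m > cfg$paired_draw_max_minutes) next
        central_ttp <- if (my_site == "central") mine$ttp_hours[r] else
          adm_bc$ttp_hours[s]
        periph_ttp <- if (my_site == "peripheral") mine$ttp_hours[r] else
          adm_bc$ttp_hours[s]
        if (periph_ttp - central_ttp >= cfg$dtp_min_hours) return(TRUE)
      }
    }
  }
  FALSE
}
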