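# Organism pools used by the generator. Implanted cases use dedicated codes
# so that a planted infection can never interact with background cultures
# (no accidental pairing, tip match or differential-time pair); the
# commensal pools are drawn from the shipped common-commensal list.
SIM_ORGS <- list(
  implant_pathogen = c("staphylococcus aureus", "escherichia coli",
                       "klebsiella pneumoniae", "candida albicans"),
  implant_commensal = c("staphylococcus epidermidis",
                        "staphylococcus hominis"),
  background_pathogen = c("enterococcus faecalis", "pseudomonas aeruginosa",
                          "streptococcus pneumoniae", "proteus mirabilis"),
  background_commensal = c("staphylococcus haemolyticus",
                           "micrococcus luteus", "cutibacterium acnes",
                           "corynebacterium striatum"),
  background_tip = c("enterobacter cloacae", "serratia marcescens")
)

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the shape of a hospital-wide surveillance cohort:
#' five of six admissions have at least one blood culture, roughly a third
#' of draws grow an organism, CVC-BSI affects about 1.2\% of the
#' culture-anchored episodes in culture-positive admissions, about 63\% of
#' cases are healthcare-associated, and length of stay is log-normal with
#' a median around 8 days.
#'
#' @param n_admissions number of admissions to generate.
#' @param frac_with_bcx fraction of admissions with at least one blood
#'   culture drawn.
#' @param frac_positive_bcx fraction of draws growing at least one
#'   organism.
#' @param mean_draws mean number of draws per cultured admission.
#' @param cvc_bsi_prevalence target fraction of draw-anchored episodes (in
#'   cultured admissions) that are true CVC-BSI.
#' @param ha_fraction fraction of implanted CVC-BSI that are
#'   healthcare-associated.
#' @param commensal_fraction fraction of positive isolates (and of
#'   implanted cases) involving a common commensal rather than a
#'   recognised pathogen.
#' @param tip_vs_dtp_mix fraction of implanted cases attributed via a
#'   catheter-tip culture (the rest via differential time to positivity).
#' @param symptom_recording_rate fraction of admissions with background
#'   vital-sign series recorded.
#' @param los_meanlog,los_sdlog log-normal length-of-stay parameters
#'   (days).
#' @param start_date first possible admission date.
#' @param period_days admission dates are spread over this many days.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return object of class \code{cohort_sim_config}.
#' @export
cohort_sim_config <- function(n_admissions = 1500L,
                              frac_with_bcx = 5 / 6,
                              frac_positive_bcx = 0.36,
                              mean_draws = 3.9,
                              cvc_bsi_prevalence = 0.012,
                              ha_fraction = 0.63,
                              commensal_fraction = 0.30,
                              tip_vs_dtp_mix = 0.5,
                              symptom_recording_rate = 0.9,
                              los_meanlog = log(8),
                              los_sdlog = 0.8,
                              start_date = "2018-01-01",
                              period_days = 700L,
                              seed = 20240205L) {
  cfg <- list(n_admissions = as.integer(n_admissions),
              frac_with_bcx = frac_with_bcx,
              frac_positive_bcx = frac_positive_bcx,
              mean_draws = mean_draws,
              cvc_bsi_prevalence = cvc_bsi_prevalence,
              ha_fraction = ha_fraction,
              commensal_fraction = commensal_fraction,
              tip_vs_dtp_mix = tip_vs_dtp_mix,
              symptom_recording_rate = symptom_recording_rate,
              los_meanlog = los_meanlog,
              los_sdlog = los_sdlog,
              start_date = as.Date(start_date),
              period_days = as.integer(period_days),
              seed = as.integer(seed))
  class(cfg) <- "cohort_sim_config"
  fr <- c("frac_with_bcx", "frac_positive_bcx", "cvc_bsi_prevalence",
          "ha_fraction", "commensal_fraction", "tip_vs_dtp_mix",
          "symptom_recording_rate")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("cohort_sim_config: '", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_admissions <= 0) {
    stop("cohort_sim_config: n_admissions must be positive", call. = FALSE)
  }
  # implant probability per cultured admission implied by the episode-level
  # prevalence target; infeasible targets are rejected up front
  p_implant <- cfg$cvc_bsi_prevalence * cfg$mean_draws
  if (p_implant > 1) {
    stop("infeasible config: cvc_bsi_prevalence * mean_draws = ",
         round(p_implant, 3), " > 1; lower the prevalence or raise ",
         "mean_draws", call. = FALSE)
  }
  cfg
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  force(code)
}

rand_ttp <- function(n) pmin(6 + stats::rlnorm(n, log(12), 0.6), 72)

#' Generate a labelled synthetic EHR cohort
#'
#' Builds a full cohort bundle — admissions, blood-culture draws with
#' sites and times to positivity, catheter-tip cultures, vital-sign series
#' and reference labels — in which every true CVC-BSI is implanted by an
#' explicit recipe (pathogen or commensal pathway; tip-culture or
#' differential-time attribution; day-3 or readmission HA route) that
#' satisfies the detection rules by construction, and every background
#' episode violates at least one conjunct by construction (background
#' organisms never match implant organisms, background tip cultures grow
#' organisms absent from blood cultures, and background draws are spaced
#' more than the pairing window for differential time to positivity).
#' Truth recovery is therefore exact on unambiguous cohorts; boundary
#' behaviour is exercised separately by
#' \code{\link{implant_edge_cases}}.
#'
#' @param config a \code{\link{cohort_sim_config}}.
#' @return list with \code{bundle} (a \code{\link{cohort_bundle}} whose
#'   \code{reference_labels} carry the ground truth) and \code{truth}
#'   (list with \code{reference_labels} and the per-case \code{recipes}).
#' @examples
#' sim <- generate_cohort(cohort_sim_config(n_admissions = 50, seed = 1))
#' sim$bundle
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_admissions
  adm_id <- sprintf("A%06d", seq_len(n))
  pat_id <- sprintf("P%06d", seq_len(n))
  admit_day <- cfg$start_date + sample.int(cfg$period_days, n, replace = TRUE) - 1L
  admit_ts <- as.POSIXct(paste0(format(admit_day), "T",
                                sprintf("%02d:%02d",
                                        sample(0:23, n, TRUE),
                                        sample(0:59, n, TRUE))),
                         format = "%Y-%m-%dT%H:%M", tz = "UTC")
  los_days <- pmax(1, round(stats::rlnorm(n, cfg$los_meanlog, cfg$los_sdlog)))
  discharge_ts <- admit_ts + los_days * 86400 +
    sample(0:600, n, TRUE) * 60
  admissions <- data.frame(admission_id = adm_id, patient_id = pat_id,
                           admit_ts = admit_ts, discharge_ts = discharge_ts,
                           stringsAsFactors = FALSE)

  has_bcx <- stats::runif(n) < cfg$frac_with_bcx
  p_implant <- cfg$cvc_bsi_prevalence * cfg$mean_draws
  implant <- has_bcx & stats::runif(n) < p_implant

  bc_rows <- list()
  tip_rows <- list()
  vit_rows <- list()
  recipes <- list()
  draw_counter <- 0L
  new_draw_id <- function() {
    draw_counter <<- draw_counter + 1L
    sprintf("D%07d", draw_counter)
  }

  extra_adm <- list()  # prior admissions planted for the readmission HA route

  for (i in seq_len(n)) {
    if (!has_bcx[i]) next
    a_start <- admit_ts[i]
    a_end <- discharge_ts[i]
    stay_h <- hours_between(a_end, a_start)

    # hourly slot grid keeps background draws > 15 min apart
    n_slots <- max(1L, floor(stay_h - 2))
    n_draws <- min(max(1L, stats::rpois(1, cfg$mean_draws - 1) + 1L), n_slots)
    slots <- sort(sample.int(n_slots, n_draws))
    draw_ts <- a_start + slots * 3600 + sample(0:29, n_draws, TRUE) * 60

    sites <- sample(c("peripheral", "central", "unspecified"), n_draws,
                    TRUE, prob = c(0.6, 0.3, 0.1))
    positive <- stats::runif(n_draws) < cfg$frac_positive_bcx
    for (j in seq_len(n_draws)) {
      d_id <- new_draw_id()
      if (positive[j]) {
        pool <- if (stats::runif(1) < cfg$commensal_fraction) {
          SIM_ORGS$background_commensal
        } else {
          SIM_ORGS$background_pathogen
        }
        bc_rows[[length(bc_rows) + 1L]] <- data.frame(
          draw_id = d_id, admission_id = adm_id[i], draw_ts = draw_ts[j],
          site = sites[j], organism_code = sample(pool, 1L),
          ttp_hours = round(rand_ttp(1), 1), stringsAsFactors = FALSE)
      } else {
        bc_rows[[length(bc_rows) + 1L]] <- data.frame(
          draw_id = d_id, admission_id = adm_id[i], draw_ts = draw_ts[j],
          site = sites[j], organism_code = NA_character_,
          ttp_hours = NA_real_, stringsAsFactors = FALSE)
      }
    }

    # sporadic background tip cultures; organisms never grown in blood
    if (stats::runif(1) < 0.1) {
      tip_rows[[length(tip_rows) + 1L]] <- data.frame(
        admission_id = adm_id[i],
        collect_ts = a_start + stats::runif(1, 1, max(2, stay_h - 1)) * 3600,
        organism_code = sample(SIM_ORGS$background_tip, 1L),
        cfu_per_ml = round(stats::runif(1, 0, 5e4)),
        stringsAsFactors = FALSE)
    }

    # background vitals: 6-hourly, never symptom-qualifying
    if (stats::runif(1) < cfg$symptom_recording_rate) {
      obs_ts <- seq(a_start + 3600, a_end, by = 6 * 3600)
      if (length(obs_ts)) {
        k <- length(obs_ts)
        vit_rows[[length(vit_rows) + 1L]] <- data.frame(
          admission_id = rep(adm_id[i], 3L * k),
          obs_ts = rep(obs_ts, 3L),
          kind = rep(c("temperature", "sbp", "dbp"), each = k),
          value = c(round(stats::runif(k, 36.3, 38.0), 1),
                    round(stats::runif(k, 100, 150)),
                    round(stats::runif(k, 65, 95))),
          stringsAsFactors = FALSE)
      }
    }

    if (implant[i]) {
      rec <- implant_case(i, admissions, cfg, new_draw_id)
      bc_rows <- c(bc_rows, rec$bc)
      tip_rows <- c(tip_rows, rec$tips)
      vit_rows <- c(vit_rows, rec$vitals)
      if (!is.null(rec$prior_admission)) {
        extra_adm[[length(extra_adm) + 1L]] <- rec$prior_admission
      }
      recipes[[length(recipes) + 1L]] <- rec$recipe
    }
  }

  if (length(extra_adm)) {
    admissions <- rbind(admissions, do.call(rbind, extra_adm))
  }
  bc <- if (length(bc_rows)) do.call(rbind, bc_rows) else
    empty_blood_cultures()
  tips <- if (length(tip_rows)) do.call(rbind, tip_rows) else
    empty_tip_cultures()
  vits <- if (length(vit_rows)) do.call(rbind, vit_rows) else
    empty_vitals()
  recipes <- if (length(recipes)) do.call(rbind, recipes) else
    data.frame(admission_id = character(), pathway = character(),
               route = character(), ha = logical(),
               index_draw_id = character(), stringsAsFactors = FALSE)

  bundle <- cohort_bundle(admissions, bc, tips, vits,
                          commensal_list = default_commensal_list())
  episodes <- enumerate_potential_episodes(bundle)
  ref <- data.frame(episode_id = episodes$episode_id,
                    cvc_bsi = FALSE, ha = FALSE, stringsAsFactors = FALSE)
  if (nrow(recipes)) {
    idx <- match(paste0("bcx:", recipes$index_draw_id), ref$episode_id)
    ref$cvc_bsi[idx] <- TRUE
    ref$ha[idx] <- recipes$ha
  }
  bundle$reference_labels <- coerce_reference_labels(ref)
  list(bundle = bundle,
       truth = list(reference_labels = bundle$reference_labels,
                    recipes = recipes))
}

# One implanted CVC-BSI case for admission i. Implant organisms are
# disjoint from every background pool, so implanted draws interact only
# with each other; the anchor is placed mid-day with a guaranteed margin
# of at least two hours before discharge.
implant_case <- function(i, admissions, cfg, new_draw_id) {
  adm <- admissions[i, ]
  admit_date <- ts_date(adm$admit_ts)
  stay_days <- as.integer(ts_date(adm$discharge_ts) - admit_date)
  pathway <- if (stats::runif(1) < cfg$commensal_fraction) "commensal"
             else "pathogen"
  route <- if (stats::runif(1) < cfg$tip_vs_dtp_mix) "tip" else "dtp"
  want_ha <- stats::runif(1) < cfg$ha_fraction

  anchor_for_day <- function(d) {
    as.POSIXct(paste0(format(admit_date + (d - 1L)), "T12:40"),
               format = "%Y-%m-%dT%H:%M", tz = "UTC")
  }

  prior_admission <- NULL
  if (want_ha && stay_days >= 3) {
    ha_route <- "day3"
    day_pool <- 3:min(stay_days, 10)
    anchor_ts <- anchor_for_day(day_pool[sample.int(length(day_pool), 1L)])
    # day 3 noon always lies inside the stay; later days may not
    if (anchor_ts >= adm$discharge_ts - 2 * 3600) {
      anchor_ts <- anchor_for_day(3L)
    }
  } else if (want_ha) {
    ha_route <- "readmission"
    anchor_ts <- anchor_for_day(1L)
    prior_admission <- data.frame(
      admission_id = paste0(adm$admission_id, "p"),
      patient_id = adm$patient_id,
      admit_ts = adm$admit_ts - 7 * 86400,
      discharge_ts = adm$admit_ts -
        round(stats::runif(1, 1, 47)) * 3600,
      stringsAsFactors = FALSE)
  } else {
    ha_route <- "none"
    anchor_ts <- anchor_for_day(1L)
  }
  if (anchor_ts <= adm$admit_ts) anchor_ts <- adm$admit_ts + 40 * 60

  org <- if (pathway == "pathogen") sample(SIM_ORGS$implant_pathogen, 1L)
         else sample(SIM_ORGS$implant_commensal, 1L)
  bc <- list()
  tips <- list()
  vitals <- list()

  mk_draw <- function(ts, site, ttp) {
    data.frame(draw_id = new_draw_id(), admission_id = adm$admission_id,
               draw_ts = ts, site = site, organism_code = org,
               ttp_hours = ttp, stringsAsFactors = FALSE)
  }

  if (route == "dtp") {
    central_ttp <- round(stats::runif(1, 8, 16), 1)
    d1 <- mk_draw(anchor_ts, "central", central_ttp)
    d2 <- mk_draw(anchor_ts + 10 * 60, "peripheral",
                  central_ttp + round(stats::runif(1, 2.5, 6), 1))
    bc <- list(d1, d2)
    index_draw_id <- d1$draw_id
  } else {
    d1 <- mk_draw(anchor_ts, "unspecified", round(rand_ttp(1), 1))
    bc <- list(d1)
    index_draw_id <- d1$draw_id
    tips[[1L]] <- data.frame(
      admission_id = adm$admission_id, collect_ts = anchor_ts + 24 * 3600,
      organism_code = org, cfu_per_ml = 10000, stringsAsFactors = FALSE)
    if (pathway == "commensal") {
      # the second distinct draw of the contaminant pair, capped inside
      # both the pairing window and the stay
      remaining_h <- hours_between(adm$discharge_ts, anchor_ts)
      gap_h <- max(1, min(20, floor(remaining_h) - 1))
      bc[[2L]] <- mk_draw(anchor_ts + gap_h * 3600, "unspecified",
                          round(rand_ttp(1), 1))
    }
  }
  if (pathway == "commensal") {
    # symptoms so both algorithm variants confirm the commensal pathway
    vitals[[1L]] <- data.frame(
      admission_id = adm$admission_id, obs_ts = anchor_ts + 2 * 3600,
      kind = "temperature", value = 38.9, stringsAsFactors = FALSE)
  }

  list(bc = bc, tips = tips, vitals = vitals,
       prior_admission = prior_admission,
       recipe = data.frame(admission_id = adm$admission_id,
                           pathway = pathway, route = route, ha = want_ha,
                           ha_route = ha_route,
                           index_draw_id = index_draw_id,
                           stringsAsFactors = FALSE))
}
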