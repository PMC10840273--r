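#' Append boundary fixtures to a generated cohort
#'
#' Adds a set of hand-constructed admissions that each sit exactly on one
#' decision boundary of the rule set: a contaminant pair exactly 48 h
#' apart (and one at 49 h), a differential time to positivity of exactly
#' 2 h (and a wrong-direction and a 16-minute-gap pair), a tip culture at
#' exactly +48 h, exactly 1000 CFU/ml, before the draw, and below
#' threshold, a temperature of exactly 38.0 (not fever), a diastolic
#' pressure of exactly 60 (hypotension), a symptom one minute outside the
#' window, repeat positives 13 and 14 days apart, and readmissions
#' exactly 48 h and 72 h before admission. Every fixture carries its
#' intended final label per algorithm variant and for the reference
#' standard in \code{truth$edge_cases}.
#'
#' @param bundle a \code{\link{cohort_bundle}} (typically from
#'   \code{\link{generate_cohort}}).
#' @param truth the matching truth list (may be NULL for a bare bundle).
#' @return list with the augmented \code{bundle} and \code{truth}; the
#'   truth gains an \code{edge_cases} data.frame with columns
#'   \code{fixture}, \code{episode_id}, \code{expected_ref},
#'   \code{expected_v1}, \code{expected_v2}, \code{expected_ha}.
#' @export
implant_edge_cases <- function(bundle, truth = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  ts0 <- function(day, hm = "12:00") {
    as.POSIXct(sprintf("2018-06-%02dT%s", day, hm),
               format = "%Y-%m-%dT%H:%M", tz = "UTC")
  }
  path_org <- "staphylococcus aureus"
  comm_org <- "staphylococcus epidermidis"

  adm_rows <- list(); bc_rows <- list(); tip_rows <- list()
  vit_rows <- list(); exp_rows <- list()
  ctr <- 0L

  add_case <- function(fixture, draws, tips = NULL, vitals = NULL,
                       expected_ref, expected_v1, expected_v2,
                       expected_ha = NA, index = 1L, also = list(),
                       admit = ts0(1, "08:00"), discharge = ts0(28, "10:00"),
                       prior_discharge_h = NA) {
    ctr <<- ctr + 1L
    aid <- sprintf("EC%02d", ctr)
    pid <- paste0("P", aid)
    adm_rows[[length(adm_rows) + 1L]] <<- data.frame(
      admission_id = aid, patient_id = pid,
      admit_ts = admit, discharge_ts = discharge, stringsAsFactors = FALSE)
    if (!is.na(prior_discharge_h)) {
      adm_rows[[length(adm_rows) + 1L]] <<- data.frame(
        admission_id = paste0(aid, "p"), patient_id = pid,
        admit_ts = admit - 10 * 86400,
        discharge_ts = admit - prior_discharge_h * 3600,
        stringsAsFactors = FALSE)
    }
    for (k in seq_along(draws)) {
      d <- draws[[k]]
      bc_rows[[length(bc_rows) + 1L]] <<- data.frame(
        draw_id = sprintf("%s-d%d", aid, k), admission_id = aid,
        draw_ts = d$ts, site = d$site %||% "unspecified",
        organism_code = d$org, ttp_hours = d$ttp %||% NA_real_,
        stringsAsFactors = FALSE)
    }
    for (tp in tips %||% list()) {
      tip_rows[[length(tip_rows) + 1L]] <<- data.frame(
        admission_id = aid, collect_ts = tp$ts, organism_code = tp$org,
        cfu_per_ml = tp$cfu, stringsAsFactors = FALSE)
    }
    for (v in vitals %||% list()) {
      vit_rows[[length(vit_rows) + 1L]] <<- data.frame(
        admission_id = aid, obs_ts = v$ts, kind = v$kind, value = v$value,
        stringsAsFactors = FALSE)
    }
    exp_rows[[length(exp_rows) + 1L]] <<- data.frame(
      fixture = fixture,
      episode_id = sprintf("bcx:%s-d%d", aid, index),
      expected_ref = expected_ref, expected_v1 = expected_v1,
      expected_v2 = expected_v2, expected_ha = expected_ha,
      stringsAsFactors = FALSE)
    for (ex in also) {
      exp_rows[[length(exp_rows) + 1L]] <<- data.frame(
        fixture = paste0(fixture, "_draw", ex$index),
        episode_id = sprintf("bcx:%s-d%d", aid, ex$index),
        expected_ref = ex$ref, expected_v1 = ex$v1, expected_v2 = ex$v2,
        expected_ha = ex$ha %||% NA, stringsAsFactors = FALSE)
    }
  }

  t_anchor <- ts0(4)  # day 4 of the stay: healthcare-associated by day rule
  fever <- list(ts = t_anchor + 3600, kind = "temperature", value = 38.9)

  # contaminant pair at exactly the 48 h window edge (inclusive)
  add_case("pair_window_48h",
           draws = list(list(ts = t_anchor, org = comm_org, ttp = 20),
                        list(ts = t_anchor + 48 * 3600, org = comm_org,
                             ttp = 22)),
           tips = list(list(ts = t_anchor + 24 * 3600, org = comm_org,
                            cfu = 1e4)),
           vitals = list(fever),
           expected_ref = TRUE, expected_v1 = TRUE, expected_v2 = TRUE,
           expected_ha = TRUE)
  # one hour past the window: no confirmation
  add_case("pair_window_49h",
           draws = list(list(ts = t_anchor, org = comm_org, ttp = 20),
                        list(ts = t_anchor + 49 * 3600, org = comm_org,
                             ttp = 22)),
           tips = list(list(ts = t_anchor + 24 * 3600, org = comm_org,
                            cfu = 1e4)),
           vitals = list(fever),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = FALSE)
  # differential time to positivity exactly 2 h, central first (inclusive)
  add_case("dtp_exact_2h",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 10,
                             site = "central"),
                        list(ts = t_anchor + 10 * 60, org = path_org,
                             ttp = 12, site = "peripheral")),
           expected_ref = TRUE, expected_v1 = TRUE, expected_v2 = TRUE,
           expected_ha = TRUE)
  # peripheral flags first: wrong direction
  add_case("dtp_wrong_direction",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 12,
                             site = "central"),
                        list(ts = t_anchor + 10 * 60, org = path_org,
                             ttp = 10, site = "peripheral")),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = FALSE)
  # draws 16 minutes apart: not a pair, whatever the positivity gap
  add_case("dtp_gap_16min",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 10,
                             site = "central"),
                        list(ts = t_anchor + 16 * 60, org = path_org,
                             ttp = 15, site = "peripheral")),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = FALSE)
  # missing peripheral time to positivity: criterion fails, no imputation
  add_case("dtp_missing_ttp",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 10,
                             site = "central"),
                        list(ts = t_anchor + 10 * 60, org = path_org,
                             ttp = NA_real_, site = "peripheral")),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = FALSE)
  # tip culture at exactly +48 h and exactly 1000 CFU/ml (both inclusive)
  add_case("tip_exact_48h_1000cfu",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 14)),
           tips = list(list(ts = t_anchor + 48 * 3600, org = path_org,
                            cfu = 1000)),
           expected_ref = TRUE, expected_v1 = TRUE, expected_v2 = TRUE,
           expected_ha = TRUE)
  # tip collected before the draw never matches
  add_case("tip_before_draw",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 14)),
           tips = list(list(ts = t_anchor - 2 * 3600, org = path_org,
                            cfu = 1e4)),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = FALSE)
  # tip below the quantitative threshold
  add_case("tip_low_cfu",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 14)),
           tips = list(list(ts = t_anchor + 24 * 3600, org = path_org,
                            cfu = 500)),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = FALSE)
  # temperature exactly 38.0 is not fever: the symptom-using variant and
  # the reference reject the contaminant pair; microbiology-only accepts
  add_case("temp_38_exact",
           draws = list(list(ts = t_anchor, org = comm_org, ttp = 20),
                        list(ts = t_anchor + 24 * 3600, org = comm_org,
                             ttp = 22)),
           tips = list(list(ts = t_anchor + 12 * 3600, org = comm_org,
                            cfu = 1e4)),
           vitals = list(list(ts = t_anchor, kind = "temperature",
                              value = 38.0)),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = TRUE)
  # diastolic exactly 60 is hypotension (inclusive threshold)
  add_case("dbp_60_exact",
           draws = list(list(ts = t_anchor, org = comm_org, ttp = 20),
                        list(ts = t_anchor + 24 * 3600, org = comm_org,
                             ttp = 22)),
           tips = list(list(ts = t_anchor + 12 * 3600, org = comm_org,
                            cfu = 1e4)),
           vitals = list(list(ts = t_anchor - 2 * 86400, kind = "dbp",
                              value = 60)),
           expected_ref = TRUE, expected_v1 = TRUE, expected_v2 = TRUE,
           expected_ha = TRUE)
  # qualifying value one minute outside the +/- 3 day window
  add_case("symptom_outside_window",
           draws = list(list(ts = t_anchor, org = comm_org, ttp = 20),
                        list(ts = t_anchor + 24 * 3600, org = comm_org,
                             ttp = 22)),
           tips = list(list(ts = t_anchor + 12 * 3600, org = comm_org,
                            cfu = 1e4)),
           vitals = list(list(ts = t_anchor + 3 * 86400 + 60, kind = "sbp",
                              value = 85)),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = TRUE)
  # second positive 14 days after the first: repeat infection timeframe
  # expired, a new episode opens
  add_case("rit_day14_new_episode",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 14),
                        list(ts = t_anchor + 14 * 86400, org = path_org,
                             ttp = 14)),
           tips = list(list(ts = t_anchor + 24 * 3600, org = path_org,
                            cfu = 1e4),
                       list(ts = t_anchor + 14 * 86400 + 24 * 3600,
                            org = path_org, cfu = 1e4)),
           expected_ref = TRUE, expected_v1 = TRUE, expected_v2 = TRUE,
           expected_ha = TRUE, index = 2L,
           also = list(list(index = 1L, ref = TRUE, v1 = TRUE, v2 = TRUE,
                            ha = TRUE)))
  # second positive on day 13 of the timeframe: suppressed
  add_case("rit_day13_suppressed",
           draws = list(list(ts = t_anchor, org = path_org, ttp = 14),
                        list(ts = t_anchor + 13 * 86400, org = path_org,
                             ttp = 14)),
           tips = list(list(ts = t_anchor + 24 * 3600, org = path_org,
                            cfu = 1e4),
                       list(ts = t_anchor + 13 * 86400 + 24 * 3600,
                            org = path_org, cfu = 1e4)),
           expected_ref = FALSE, expected_v1 = FALSE, expected_v2 = FALSE,
           index = 2L,
           also = list(list(index = 1L, ref = TRUE, v1 = TRUE, v2 = TRUE,
                            ha = TRUE)))
  # anchor on admission day 2 with the previous discharge exactly 48 h
  # before admission: healthcare-associated by the readmission rule
  add_case("readmission_exact_48h",
           draws = list(list(ts = ts0(2, "12:40"), org = path_org,
                             ttp = 14)),
           tips = list(list(ts = ts0(3, "12:40"), org = path_org,
                            cfu = 1e4)),
           expected_ref = TRUE, expected_v1 = TRUE, expected_v2 = TRUE,
           expected_ha = TRUE, prior_discharge_h = 48)
  # previous discharge 72 h before admission: outside the look-back
  add_case("readmission_72h",
           draws = list(list(ts = ts0(2, "12:40"), org = path_org,
                             ttp = 14)),
           tips = list(list(ts = ts0(3, "12:40"), org = path_org,
                            cfu = 1e4)),
           expected_ref = TRUE, expected_v1 = TRUE, expected_v2 = TRUE,
           expected_ha = FALSE, prior_discharge_h = 72)

  edge_expected <- do.call(rbind, exp_rows)
  new_bundle <- cohort_bundle(
    admissions = rbind(bundle$admissions, do.call(rbind, adm_rows)),
    blood_cultures = rbind(bundle$blood_cultures, do.call(rbind, bc_rows)),
    tip_cultures = rbind(bundle$tip_cultures, do.call(rbind, tip_rows)),
    vitals = rbind(bundle$vitals, do.call(rbind, vit_rows)),
    commensal_list = bundle$commensal_list)

  episodes <- enumerate_potential_episodes(new_bundle)
  ref <- data.frame(episode_id = episodes$episode_id, cvc_bsi = FALSE,
                    ha = FALSE, stringsAsFactors = FALSE)
  if (!is.null(bundle$reference_labels)) {
    old <- bundle$reference_labels
    m <- match(old$episode_id, ref$episode_id)
    ref$cvc_bsi[m] <- old$cvc_bsi
    ref$ha[m] <- old$ha
  }
  pos <- edge_expected[edge_expected$expected_ref, , drop = FALSE]
  m <- match(pos$episode_id, ref$episode_id)
  ref$cvc_bsi[m] <- TRUE
  ref$ha[m] <- ifelse(is.na(pos$expected_ha), FALSE, pos$expected_ha)
  new_bundle$reference_labels <- coerce_reference_labels(ref)

  truth <- truth %||% list()
  truth$reference_labels <- new_bundle$reference_labels
  truth$edge_cases <- edge_expected
  list(bundle = new_bundle, truth = truth)
}
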