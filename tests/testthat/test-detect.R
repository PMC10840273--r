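cfg <- surveillance_config()

test_that("symptom window applies the strict/inclusive thresholds", {
  anchor <- ts("2018-03-05T12:00")
  v <- function(...) mk_vital("A1", ...)
  expect_true(has_bsi_symptoms(v("2018-03-06T12:00", "temperature", 38.5),
                               anchor, cfg))
  # fever is strictly greater than 38.0
  expect_false(has_bsi_symptoms(v("2018-03-05T12:00", "temperature", 38.0),
                                anchor, cfg))
  # diastolic 60 is inclusive, two days before the anchor
  expect_true(has_bsi_symptoms(v("2018-03-03T12:00", "dbp", 60),
                               anchor, cfg))
  # one minute past the three-day window
  expect_false(has_bsi_symptoms(v("2018-03-08T12:01", "sbp", 85),
                                anchor, cfg))
  expect_true(has_bsi_symptoms(v("2018-03-08T12:00", "sbp", 85),
                               anchor, cfg))
})

comm <- "staphylococcus epidermidis"
path <- "staphylococcus aureus"

test_that("one culture confirms a pathogen; commensals need a pair", {
  bc1 <- mk_draw("d1", "A1", "2018-03-02T10:00", organism_code = path,
                 ttp_hours = 12)
  for (v in c("with_symptoms", "microbiology_only")) {
    res <- confirm_bsi("d1", bc1, cvcbsi:::empty_vitals(), v, cfg,
                       TEST_COMMENSALS)
    expect_true(res$confirmed)
    expect_true("pathogen_bsi" %in% res$evidence)
  }

  pair47 <- rbind(
    mk_draw("d1", "A1", "2018-03-02T10:00", organism_code = comm,
            ttp_hours = 20),
    mk_draw("d2", "A1", "2018-03-04T09:00", organism_code = comm,
            ttp_hours = 24))  # 47 h apart
  fever <- mk_vital("A1", "2018-03-02T12:00", "temperature", 39.0)

  res <- confirm_bsi("d1", pair47, fever, "with_symptoms", cfg,
                     TEST_COMMENSALS)
  expect_true(res$confirmed)
  expect_setequal(res$evidence, c("symptoms", "commensal_pair"))

  # same pair, no symptoms: variant 1 rejects, variant 2 accepts
  res1 <- confirm_bsi("d1", pair47, cvcbsi:::empty_vitals(),
                      "with_symptoms", cfg, TEST_COMMENSALS)
  res2 <- confirm_bsi("d1", pair47, cvcbsi:::empty_vitals(),
                      "microbiology_only", cfg, TEST_COMMENSALS)
  expect_false(res1$confirmed)
  expect_true(res2$confirmed)

  # 49 h apart fails both variants even with symptoms
  pair49 <- rbind(pair47[1, ],
                  mk_draw("d2", "A1", "2018-03-04T11:00",
                          organism_code = comm, ttp_hours = 24))
  expect_false(confirm_bsi("d1", pair49, fever, "with_symptoms", cfg,
                           TEST_COMMENSALS)$confirmed)
  expect_false(confirm_bsi("d1", pair49, fever, "microbiology_only", cfg,
                           TEST_COMMENSALS)$confirmed)

  neg <- mk_draw("d9", "A1", "2018-03-02T10:00")
  expect_error(confirm_bsi("d9", neg, cvcbsi:::empty_vitals(),
                           "with_symptoms", cfg, TEST_COMMENSALS),
               "negative draw")
})

test_that("tip attribution honours the CFU threshold and the after-window", {
  bc <- mk_draw("d1", "A1", "2018-03-02T10:00", organism_code = path,
                ttp_hours = 12)
  tip <- function(dt_h, cfu, org = path) {
    mk_tip("A1", ts("2018-03-02T10:00") + dt_h * 3600, org, cfu)
  }
  expect_true(cvc_attribution_tip("d1", bc, tip(24, 1000), path, cfg))
  expect_false(cvc_attribution_tip("d1", bc, tip(24, 500), path, cfg))
  expect_true(cvc_attribution_tip("d1", bc, tip(48, 1e4), path, cfg))
  expect_false(cvc_attribution_tip("d1", bc, tip(49, 1e4), path, cfg))
  expect_false(cvc_attribution_tip("d1", bc, tip(-2, 1e4), path, cfg))
  expect_false(cvc_attribution_tip("d1", bc, tip(24, 1e4, "other"), path,
                                   cfg))
})

test_that("differential time to positivity needs direction, pairing and data", {
  mk_pair <- function(gap_min, c_ttp, p_ttp, p_site = "peripheral") {
    rbind(mk_draw("c", "A1", "2018-03-02T10:00", site = "central",
                  organism_code = path, ttp_hours = c_ttp),
          mk_draw("p", "A1", ts("2018-03-02T10:00") + gap_min * 60,
                  site = p_site, organism_code = path, ttp_hours = p_ttp))
  }
  expect_true(cvc_attribution_dtp("c", mk_pair(10, 10, 12), path, cfg))
  expect_true(cvc_attribution_dtp("p", mk_pair(10, 10, 12), path, cfg))
  # exactly 2 h is inclusive; wrong direction fails
  expect_false(cvc_attribution_dtp("c", mk_pair(10, 12, 10), path, cfg))
  expect_false(cvc_attribution_dtp("c", mk_pair(16, 10, 15), path, cfg))
  expect_false(cvc_attribution_dtp("c", mk_pair(10, 10, NA), path, cfg))
  # unspecified site can never join a pair
  expect_false(cvc_attribution_dtp("c", mk_pair(10, 10, 14,
                                                p_site = "unspecified"),
                                   path, cfg))
})

test_that("detection composes confirmation with attribution", {
  bc <- mk_draw("d1", "A1", "2018-03-02T10:00", organism_code = path,
                ttp_hours = 12)
  tip <- mk_tip("A1", "2018-03-03T10:00", path, 1e4)
  b <- one_adm_bundle(blood_cultures = bc, tip_cultures = tip)
  lab <- detect_cvc_bsi(b, "microbiology_only", cfg)
  expect_true(lab$cvc_bsi)
  expect_setequal(strsplit(lab$evidence, ";")[[1]],
                  c("pathogen_bsi", "tip_match"))

  # confirmed but unattributed stays negative
  b2 <- one_adm_bundle(blood_cultures = bc)
  expect_false(detect_cvc_bsi(b2, "microbiology_only", cfg)$cvc_bsi)

  # negative draws and culture-free admissions are always negative
  b3 <- one_adm_bundle(blood_cultures = mk_draw("d1", "A1",
                                                "2018-03-02T10:00"))
  expect_false(any(detect_cvc_bsi(b3, "microbiology_only", cfg)$cvc_bsi))
})

test_that("episode enumeration counts draws plus culture-free admissions", {
  adm <- mk_admissions(list("A1", "P1", "2018-03-01T08:00",
                            "2018-03-20T08:00"),
                       list("A2", "P2", "2018-03-01T08:00",
                            "2018-03-20T08:00"))
  bc <- rbind(mk_draw("d1", "A1", "2018-03-02T10:00"),
              mk_draw("d2", "A1", "2018-03-03T10:00"),
              mk_draw("d3", "A1", "2018-03-04T10:00"))
  b <- cohort_bundle(adm, bc, commensal_list = TEST_COMMENSALS)
  ep <- enumerate_potential_episodes(b)
  expect_equal(nrow(ep), 4L)
  expect_equal(sum(ep$anchor == "bcx_draw"), 3L)
  expect_equal(sum(ep$anchor == "admission_without_bcx"), 1L)
})

test_that("detection agrees with the brute-force rule oracle", {
  for (seed in c(2, 13)) {
    sim <- generate_cohort(cohort_sim_config(n_admissions = 60,
                                             seed = seed))
    withec <- implant_edge_cases(sim$bundle, sim$truth)
    b <- withec$bundle
    pos_draws <- unique(
      b$blood_cultures$draw_id[!is.na(b$blood_cultures$organism_code)])
    for (v in c("with_symptoms", "microbiology_only")) {
      lab <- detect_cvc_bsi(b, v, cfg)
      got <- lab$cvc_bsi[match(paste0("bcx:", pos_draws), lab$episode_id)]
      want <- vapply(pos_draws, function(d) oracle_positive(b, d, v, cfg),
                     logical(1))
      expect_equal(got, unname(want), info = paste(seed, v))
    }
  }
})

test_that("symptom-using positives are a subset of microbiology-only", {
  for (seed in c(4, 21, 33)) {
    sim <- generate_cohort(cohort_sim_config(n_admissions = 80,
                                             seed = seed))
    ec <- implant_edge_cases(sim$bundle, sim$truth)
    l1 <- detect_cvc_bsi(ec$bundle, "with_symptoms", cfg)
    l2 <- detect_cvc_bsi(ec$bundle, "microbiology_only", cfg)
    expect_true(all(l2$cvc_bsi[l1$cvc_bsi]), info = seed)
  }
})

test_that("tightening any threshold never increases the positive count", {
  sim <- generate_cohort(cohort_sim_config(n_admissions = 120, seed = 8))
  ec <- implant_edge_cases(sim$bundle, sim$truth)
  base <- sum(detect_cvc_bsi(ec$bundle, "microbiology_only", cfg)$cvc_bsi)
  tighter <- list(
    surveillance_config(contaminant_pair_window_hours = 24),
    surveillance_config(tip_window_hours = 24),
    surveillance_config(symptom_window_days = 1),
    surveillance_config(paired_draw_max_minutes = 5),
    surveillance_config(tip_cfu_threshold = 1e5),
    surveillance_config(dtp_min_hours = 6))
  for (tcfg in tighter) {
    n <- sum(detect_cvc_bsi(ec$bundle, "microbiology_only", tcfg)$cvc_bsi)
    expect_lte(n, base)
  }
  # and for the symptom-using variant, where the symptom window binds
  base1 <- sum(detect_cvc_bsi(ec$bundle, "with_symptoms", cfg)$cvc_bsi)
  n1 <- sum(detect_cvc_bsi(ec$bundle, "with_symptoms",
                           surveillance_config(symptom_window_days = 0))$cvc_bsi)
  expect_lte(n1, base1)
})
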