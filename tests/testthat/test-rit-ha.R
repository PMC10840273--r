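cfg <- surveillance_config()

mk_labels <- function(days, positive = TRUE, admission_id = "A1") {
  n <- length(days)
  data.frame(
    episode_id = sprintf("bcx:d%d", seq_len(n)),
    admission_id = admission_id,
    anchor_draw_id = sprintf("d%d", seq_len(n)),
    anchor_ts = ts("2018-03-01T10:00") + days * 86400,
    cvc_bsi = rep_len(positive, n),
    evidence = "",
    stringsAsFactors = FALSE)
}

test_that("repeat infection timeframe covers 14 days anchored on the index", {
  # day 13 is inside the window (index day counts as day 1)
  out <- apply_rit(mk_labels(c(0, 13)), cfg)
  expect_equal(out$cvc_bsi, c(TRUE, FALSE))
  expect_equal(out$suppressed_by_rit, c(FALSE, TRUE))
  expect_equal(out$index_episode_id[2], "bcx:d1")

  # day 14 opens a new episode
  out <- apply_rit(mk_labels(c(0, 14)), cfg)
  expect_equal(out$cvc_bsi, c(TRUE, TRUE))
  expect_false(any(out$suppressed_by_rit))

  # the window is anchored on the first positive, not rolling
  out <- apply_rit(mk_labels(c(0, 10, 20)), cfg)
  expect_equal(out$cvc_bsi, c(TRUE, FALSE, TRUE))
  expect_equal(out$suppressed_by_rit, c(FALSE, TRUE, FALSE))
})

test_that("suppression is per admission and skips negatives", {
  two_adm <- rbind(mk_labels(c(0, 5), admission_id = "A1"),
                   mk_labels(c(0, 5), admission_id = "A2"))
  two_adm$episode_id <- sprintf("bcx:x%d", 1:4)
  out <- apply_rit(two_adm, cfg)
  expect_equal(out$cvc_bsi, c(TRUE, FALSE, TRUE, FALSE))

  # a negative episode inside the window stays negative, not suppressed
  lab <- mk_labels(c(0, 5, 6))
  lab$cvc_bsi[2] <- FALSE
  out <- apply_rit(lab, cfg)
  expect_equal(out$suppressed_by_rit, c(FALSE, FALSE, TRUE))
  expect_false(out$cvc_bsi[2])
})

test_that("applying the timeframe twice changes nothing", {
  lab <- mk_labels(c(0, 3, 13, 20, 40))
  once <- apply_rit(lab, cfg)
  twice <- apply_rit(once, cfg)
  expect_identical(once, twice)
  # single-positive admissions are untouched
  single <- apply_rit(mk_labels(5), cfg)
  expect_true(single$cvc_bsi)
  expect_false(single$suppressed_by_rit)
})

test_that("ties at one timestamp are broken by draw id", {
  lab <- mk_labels(c(0, 0))
  out <- apply_rit(lab, cfg)
  expect_equal(out$suppressed_by_rit, c(FALSE, TRUE))
  expect_equal(out$index_episode_id[2], "bcx:d1")
})

test_that("healthcare-associated classification follows day and readmission rules", {
  adm <- data.frame(admission_id = "A1", patient_id = "P1",
                    admit_ts = ts("2018-03-01T08:00"),
                    discharge_ts = ts("2018-03-20T08:00"),
                    stringsAsFactors = FALSE)
  prior <- function(gap_h) {
    data.frame(admission_id = "A0", patient_id = "P1",
               admit_ts = ts("2018-02-01T08:00"),
               discharge_ts = ts("2018-03-01T08:00") - gap_h * 3600,
               stringsAsFactors = FALSE)
  }
  none <- adm[0, ]

  # calendar day 3 of the stay (crossing two midnights)
  expect_true(classify_ha(ts("2018-03-03T01:00"), adm, none, cfg)$ha)
  expect_equal(classify_ha(ts("2018-03-03T01:00"), adm, none,
                           cfg)$evidence, "ha_day3")
  # day 1 or 2 without a qualifying readmission
  expect_false(classify_ha(ts("2018-03-01T09:00"), adm, none, cfg)$ha)
  expect_false(classify_ha(ts("2018-03-02T23:00"), adm, none, cfg)$ha)
  # day 2 with the previous discharge 24 h before admission
  res <- classify_ha(ts("2018-03-02T09:00"), adm, rbind(adm, prior(24)),
                     cfg)
  expect_true(res$ha)
  expect_equal(res$evidence, "ha_readmission")
  # exactly 48 h qualifies; 72 h does not
  expect_true(classify_ha(ts("2018-03-02T09:00"), adm,
                          rbind(adm, prior(48)), cfg)$ha)
  expect_false(classify_ha(ts("2018-03-02T09:00"), adm,
                           rbind(adm, prior(72)), cfg)$ha)
})

test_that("every healthcare-associated label implies a detected episode", {
  sim <- generate_cohort(cohort_sim_config(n_admissions = 150, seed = 17))
  ec <- implant_edge_cases(sim$bundle, sim$truth)
  for (v in c("with_symptoms", "microbiology_only")) {
    lab <- run_surveillance(ec$bundle, v)
    expect_true(all(lab$cvc_bsi[lab$ha]))
    expect_false(any(lab$cvc_bsi[lab$suppressed_by_rit]))
    expect_true(all(!is.na(lab$index_episode_id[lab$suppressed_by_rit])))
  }
})
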