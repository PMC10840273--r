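test_that("generation is a deterministic function of the configuration", {
  cfg <- cohort_sim_config(n_admissions = 60, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (tab in c("admissions", "blood_cultures", "tip_cultures", "vitals",
                "reference_labels")) {
    expect_identical(a$bundle[[tab]], b$bundle[[tab]], info = tab)
  }
  expect_identical(a$truth$recipes, b$truth$recipes)
  c2 <- generate_cohort(cohort_sim_config(n_admissions = 60, seed = 78))
  expect_false(identical(a$bundle$blood_cultures,
                         c2$bundle$blood_cultures))
})

test_that("zero prevalence yields a case-free cohort", {
  sim <- generate_cohort(cohort_sim_config(n_admissions = 80,
                                           cvc_bsi_prevalence = 0,
                                           seed = 3))
  expect_equal(sum(sim$truth$reference_labels$cvc_bsi), 0L)
  expect_equal(nrow(sim$truth$recipes), 0L)
  lab <- run_surveillance(sim$bundle, "microbiology_only")
  expect_false(any(lab$cvc_bsi))
})

test_that("infeasible prevalence targets are rejected up front", {
  expect_error(cohort_sim_config(cvc_bsi_prevalence = 0.5, mean_draws = 4),
               "infeasible")
})

test_that("marginal frequencies converge to the configured targets", {
  cfg <- cohort_sim_config(n_admissions = 2500, seed = 19)
  sim <- generate_cohort(cfg)
  bc <- sim$bundle$blood_cultures
  draws <- bc[!duplicated(bc$draw_id), ]
  n_draws <- nrow(draws)
  frac_pos <- mean(!is.na(draws$organism_code[match(unique(bc$draw_id),
                                                    bc$draw_id)]))
  # positive-draw fraction: background rate plus the small implant surplus
  tol <- 4 * sqrt(0.36 * 0.64 / n_draws) + 0.01
  expect_lt(abs(frac_pos - cfg$frac_positive_bcx), tol)

  ref <- sim$truth$reference_labels
  n_cases <- sum(ref$cvc_bsi)
  # episode prevalence among draw-anchored episodes
  n_bcx_ep <- sum(startsWith(ref$episode_id, "bcx:"))
  prev <- n_cases / n_bcx_ep
  expect_lt(abs(prev - cfg$cvc_bsi_prevalence),
            4 * sqrt(cfg$cvc_bsi_prevalence / n_bcx_ep) + 0.002)

  ha_frac <- sum(ref$ha) / n_cases
  expect_lt(abs(ha_frac - cfg$ha_fraction),
            4 * sqrt(cfg$ha_fraction * (1 - cfg$ha_fraction) / n_cases))

  # admissions with at least one draw
  dt <- unique(draws$admission_id)
  frac_bcx <- length(dt) / cfg$n_admissions
  expect_lt(abs(frac_bcx - cfg$frac_with_bcx),
            4 * sqrt(cfg$frac_with_bcx * (1 - cfg$frac_with_bcx) /
                       cfg$n_admissions) + 0.01)
})

test_that("generated bundles satisfy every structural invariant", {
  for (seed in c(1, 2)) {
    sim <- generate_cohort(cohort_sim_config(n_admissions = 100,
                                             seed = seed))
    expect_s3_class(validate_bundle(sim$bundle), "cohort_bundle")
    ep <- enumerate_potential_episodes(sim$bundle)
    dt <- sim$bundle$blood_cultures
    n_draws <- length(unique(dt$draw_id))
    n_nobcx <- sum(!(sim$bundle$admissions$admission_id %in%
                       dt$admission_id))
    expect_equal(nrow(ep), n_draws + n_nobcx)
    expect_equal(nrow(sim$truth$reference_labels), nrow(ep))
  }
})

test_that("surveillance recovers the implanted truth exactly", {
  for (seed in c(7, 23)) {
    sim <- generate_cohort(cohort_sim_config(n_admissions = 400,
                                             seed = seed))
    ref <- sim$truth$reference_labels
    for (v in c("with_symptoms", "microbiology_only")) {
      lab <- run_surveillance(sim$bundle, v)
      m <- match(ref$episode_id, lab$episode_id)
      expect_equal(lab$cvc_bsi[m], ref$cvc_bsi,
                   info = paste(seed, v, "cvc_bsi"))
      expect_equal(lab$ha[m], ref$ha, info = paste(seed, v, "ha"))
    }
  }
})

test_that("boundary fixtures carry their intended labels", {
  sim <- generate_cohort(cohort_sim_config(n_admissions = 30, seed = 2))
  ec <- implant_edge_cases(sim$bundle, sim$truth)
  e <- ec$truth$edge_cases
  l1 <- run_surveillance(ec$bundle, "with_symptoms")
  l2 <- run_surveillance(ec$bundle, "microbiology_only")
  m1 <- match(e$episode_id, l1$episode_id)
  m2 <- match(e$episode_id, l2$episode_id)
  expect_equal(l1$cvc_bsi[m1], e$expected_v1, info = "variant 1 labels")
  expect_equal(l2$cvc_bsi[m2], e$expected_v2, info = "variant 2 labels")
  has_ha <- !is.na(e$expected_ha)
  expect_equal(l2$ha[m2][has_ha], e$expected_ha[has_ha],
               info = "healthcare-associated flags")
  # the day-13 repeat is suppressed and linked to its index episode
  sup <- l2[match(e$episode_id[e$fixture == "rit_day13_suppressed"],
                  l2$episode_id), ]
  expect_true(sup$suppressed_by_rit)
  expect_equal(sup$index_episode_id,
               e$episode_id[e$fixture == "rit_day13_suppressed_draw1"])
})
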