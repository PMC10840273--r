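test_that("confusion matrices are built from aligned episode labels", {
  ids <- sprintf("e%02d", 1:10)
  pred <- data.frame(episode_id = ids, cvc_bsi = c(rep(TRUE, 2),
                                                   rep(FALSE, 8)))
  expect_equal(unclass(build_confusion(pred, pred))[c("tp", "fp", "fn",
                                                      "tn")],
               list(tp = 2L, fp = 0L, fn = 0L, tn = 8L))

  # order invariance: shuffled reference aligns on episode_id
  set.seed(1)
  ref <- pred[sample.int(10), ]
  cm <- build_confusion(pred, ref)
  expect_equal(cm$tp, 2L)
  expect_equal(cm$tn, 8L)

  mismatched <- data.frame(episode_id = c(ids[-1], "zz"),
                           cvc_bsi = rep(FALSE, 10))
  expect_error(build_confusion(pred, mismatched), "same episodes")

  # all-negative predictions against 51 positives among 4326 episodes
  ids2 <- sprintf("e%04d", 1:4326)
  ref2 <- data.frame(episode_id = ids2,
                     cvc_bsi = c(rep(TRUE, 51), rep(FALSE, 4275)))
  pred2 <- data.frame(episode_id = ids2, cvc_bsi = FALSE)
  cm2 <- build_confusion(pred2, ref2)
  expect_equal(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn), c(0L, 0L, 51L, 4275L))
})

test_that("metric points reproduce the published validation panel", {
  # counts, expected (sens, spec, ppv, npv, auroc, kappa) at 3 decimals
  cases <- list(
    list(cm = confusion_matrix(44, 3, 7, 4272),
         want = c(0.863, 0.999, 0.936, 0.998, 0.931, 0.897)),
    list(cm = confusion_matrix(45, 4, 6, 4271),
         want = c(0.882, 0.999, 0.918, 0.999, 0.941, 0.899)),
    list(cm = confusion_matrix(25, 1, 7, 4293),
         want = c(0.781, 1.000, 0.962, 0.998, 0.891, 0.861)),
    list(cm = confusion_matrix(26, 1, 6, 4293),
         want = c(0.813, 1.000, 0.963, 0.999, 0.906, 0.881)))
  for (cs in cases) {
    bm <- binary_metrics(cs$cm, ci = FALSE)
    got <- round_half_up(c(bm$sensitivity$point, bm$specificity$point,
                           bm$ppv$point, bm$npv$point,
                           auroc_binary(cs$cm), cohens_kappa(cs$cm)), 3)
    expect_equal(got, cs$want)
  }
  # perfect classifier
  bm <- binary_metrics(confusion_matrix(5, 0, 0, 95), ci = FALSE)
  expect_equal(vapply(bm, function(e) e$point, numeric(1)),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  expect_equal(cohens_kappa(confusion_matrix(5, 0, 0, 95)), 1)
  expect_equal(auroc_binary(confusion_matrix(50, 50, 50, 50)), 0.5)
})

test_that("zero marginals flag the metric as undefined, never as zero", {
  cm <- confusion_matrix(0, 0, 5, 95)  # nothing predicted positive
  expect_warning(bm <- binary_metrics(cm, ci = FALSE), "ppv")
  expect_true(is.na(bm$ppv$point))
  expect_false(is.na(bm$sensitivity$point))
})

test_that("Wilson intervals match the frozen published values", {
  expect_equal(round_half_up(wilson_ci(44, 51), 3), c(0.743, 0.932))
  expect_equal(round_half_up(wilson_ci(45, 51), 3), c(0.766, 0.945))
  expect_equal(round_half_up(wilson_ci(25, 32), 3), c(0.612, 0.890))
  expect_equal(round_half_up(wilson_ci(26, 32), 3), c(0.647, 0.911))
  expect_equal(wilson_ci(0, 10)[1], 0)
  expect_error(wilson_ci(3, 0), "positive")
  expect_error(wilson_ci(5, 3), "successes")
})

test_that("Wilson intervals agree with the score-test oracle", {
  for (n in c(10, 51, 500)) {
    for (k in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      got <- wilson_ci(k, n)
      want <- as.numeric(
        stats::prop.test(k, n, correct = FALSE)$conf.int)
      expect_equal(got, want, tolerance = 1e-10,
                   info = sprintf("k=%d n=%d", k, n))
      expect_true(got[1] <= k / n && k / n <= got[2])
      expect_true(got[1] >= 0 && got[2] <= 1)
    }
  }
  # fixed proportion, growing n: interval narrows
  widths <- vapply(c(20, 80, 320), function(n) {
    diff(wilson_ci(n * 0.25, n))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("kappa agrees with the independent agreement oracle", {
  skip_if_not_installed("e1071")
  for (cells in list(c(44, 3, 7, 4272), c(26, 1, 6, 4293),
                     c(10, 20, 30, 40))) {
    cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
    tab <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2, 2)
    want <- e1071::classAgreement(tab)$kappa
    expect_equal(cohens_kappa(cm), want, tolerance = 1e-12)
  }
})
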