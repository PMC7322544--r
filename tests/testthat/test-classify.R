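ds <- load_compound_dataset()

pos <- function(ec5) list(positive = TRUE, qtc_ec5 = ec5,
                          cmax_noeffect = NULL)
neg <- function(cmax) list(positive = FALSE, qtc_ec5 = NULL,
                           cmax_noeffect = cmax)

test_that("IC20 follows from the Hill pore-block closed form", {
  expect_equal(ic20_from_ic50(8, 1), 2)
  expect_equal(ic20_from_ic50(0.018, 1.08), 0.018 * 4^(-1 / 1.08))
  expect_lt(abs(ic20_from_ic50(0.018, 1.08) - 0.005), 1e-3)
  # step-block limit: IC20 -> IC50 as the Hill coefficient grows
  expect_equal(ic20_from_ic50(3, 1e6), 3, tolerance = 1e-4)
  expect_error(ic20_from_ic50(-1, 1), "positive")
  # 20% block at the IC20, by construction
  expect_equal(pore_block_scale(ic20_from_ic50(5, 1.3), 5, 1.3), 0.8)
})

test_that("margin rule reproduces the printed example calls", {
  expect_equal(margin_rule(0.004, pos(0.07)), "TP")
  expect_equal(margin_rule(12, pos(1.8)), "FN")      # 12 > 9
  expect_equal(margin_rule(1.04, neg(3)), "FP")
  expect_equal(margin_rule(">30", neg(8.7)), "TN")   # censored IC20
  expect_equal(margin_rule(5, neg(5)), "TN")         # boundary -> TN
  expect_equal(margin_rule(0.35, pos(0.07)), "TP")   # 5-fold inclusive
})

test_that("in-silico rule requires APD90 up and EMw down", {
  expect_equal(insilico_rule("up", "down", pos(0.07)), "TP")
  expect_equal(insilico_rule("up", "up", neg(0.7)), "TN")
  expect_equal(insilico_rule("up", "down", neg(8.7)), "FP")
  expect_equal(insilico_rule("down", "up", pos(1)), "FN")
  # any supra-threshold shortening counts, even inside down-up / up-down
  expect_equal(insilico_rule("up", "down-up", pos(7.2)), "TP")
  expect_equal(insilico_rule("down-up", "up", neg(0.4)), "TN")
  expect_equal(insilico_rule("up", "up-down", neg(2)), "FP")
  expect_error(insilico_rule("NA", "down", pos(1)), "unavailable")
})

test_that("tPKPD reclassification follows the margin and censoring rules", {
  expect_equal(tpkpd_reclassify("FP", 9.2, neg(8.7)), "TN")
  expect_equal(tpkpd_reclassify("FP", 6.1, neg(7.7)), "FP")
  expect_equal(tpkpd_reclassify("TP", 0.21, pos(0.02)), "FN") # 10.5-fold over
  expect_equal(tpkpd_reclassify("TP", 0.5, pos(0.1)), "TP")   # boundary 5x
  expect_equal(tpkpd_reclassify("TP", 0.01, pos(1)), "TP")    # under-prediction
  expect_equal(tpkpd_reclassify("FP", 8.7, neg(8.7)), "TN")   # equality -> TN
  expect_equal(tpkpd_reclassify("TN", 99, neg(1)), "TN")      # pass-through
  expect_equal(tpkpd_reclassify("FN", 99, pos(1)), "FN")
  expect_error(tpkpd_reclassify("TP", NA, pos(1)), "required")
})

test_that("reclassification never crosses the in-vivo outcome", {
  # exhaustive over label x prediction grid: a negative outcome can never
  # become TP, a positive outcome can never become TN
  preds <- c(0.01, 0.1, 1, 5, 10, 100)
  for (p in preds) {
    for (lab in c("TP", "FN")) {
      out <- tpkpd_reclassify(lab, p, pos(1))
      expect_true(out %in% c("TP", "FN"))
    }
    for (lab in c("FP", "TN")) {
      out <- tpkpd_reclassify(lab, p, neg(1))
      expect_true(out %in% c("FP", "TN"))
    }
  }
})

test_that("confusion tabulation counts the packaged label columns", {
  cm <- confusion_matrix(ds$insilico$px_insilico_label)
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 33L, tn = 29L, fp = 11L, fn = 0L))
  cm4 <- confusion_matrix(
    ds$margin$px_label[ds$margin$px_label != "NA"])
  expect_equal(unclass(cm4)[c("tp", "tn", "fp", "fn")],
               list(tp = 28L, tn = 28L, fp = 12L, fn = 5L))
  expect_equal(with(confusion_matrix(character(0)), tp + tn + fp + fn), 0L)
  expect_error(confusion_matrix(c("TP", "XX")), "invalid")
})

test_that("predictive metrics and Wilson intervals behave", {
  m <- structure(list(tp = 33, tn = 29, fp = 11, fn = 0),
                 class = "qts_confusion")
  pm <- predictive_metrics(m)
  get <- function(nm) pm$estimate[pm$metric == nm]
  expect_equal(get("accuracy"), 62 / 73)
  expect_equal(get("specificity"), 29 / 40)
  expect_equal(get("sensitivity"), 1)
  # Wilson CI of 29/29: upper 1, lower < 1
  ci <- wilson_ci(29, 29)
  expect_equal(ci[2], 1)
  expect_lt(ci[1], 1)
  # interval brackets the estimate and tightens with n
  expect_true(ci[1] <= 1 && 1 <= ci[2])
  w10 <- wilson_ci(8, 10); w100 <- wilson_ci(80, 100)
  expect_lt(diff(wilson_ci(80, 100)), diff(wilson_ci(8, 10)))
  expect_true(w10[1] < 0.8 && 0.8 < w10[2])
  # degenerate: (1,1,0,0) -> accuracy 1 with CI narrower than [0,1]
  m2 <- structure(list(tp = 1, tn = 1, fp = 0, fn = 0),
                  class = "qts_confusion")
  pm2 <- predictive_metrics(m2)
  acc2 <- pm2[pm2$metric == "accuracy", ]
  expect_equal(acc2$estimate, 1)
  expect_gt(acc2$lower, 0)
  # zero-denominator ratios flagged as NA with n = 0, not propagated
  m3 <- structure(list(tp = 0, tn = 5, fp = 0, fn = 0),
                  class = "qts_confusion")
  pm3 <- predictive_metrics(m3)
  expect_true(is.na(pm3$estimate[pm3$metric == "ppv"]))
  expect_equal(pm3$n[pm3$metric == "ppv"], 0L)
  # Clopper-Pearson option agrees with binom.test
  pmcp <- predictive_metrics(m, ci = "clopper-pearson")
  bt <- binom.test(62, 73)$conf.int
  expect_equal(pmcp$lower[pmcp$metric == "accuracy"], bt[1])
})
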