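test_that("ROC curve has the required geometry", {
  set.seed(3)
  s <- runif(40); l <- rbinom(40, 1, s)
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  rc <- roc_curve(s, l)
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("trapezoid AUC equals exhaustive pair counting, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(14)
  for (i in 1:12) {
    n <- sample(6:12, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # coarse grid forces ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l)$auc, pair_count_auc(s, l))
  }
  expect_error(auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC and DeLong machinery agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(25)
  l <- rep(c(0, 1), each = 20)
  sa <- rnorm(40, l); sb <- rnorm(40, 0.6 * l)
  a <- auc(sa, l)
  pr <- pROC::roc(l, sa, quiet = TRUE, direction = "<")
  expect_equal(a$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(a$ci_low, a$ci_high), ci[c(1, 3)], tolerance = 1e-8)
  cmp <- compare_auc_delong(sa, sb, l)
  prb <- pROC::roc(l, sb, quiet = TRUE, direction = "<")
  rt <- pROC::roc.test(pr, prb, method = "delong", paired = TRUE)
  expect_equal(cmp$p, rt$p.value, tolerance = 1e-8)
  expect_equal(cmp$z, unname(rt$statistic), tolerance = 1e-8)
})

test_that("paired DeLong test: self-comparison, antisymmetry, variance reduction", {
  set.seed(16)
  l <- rep(c(0, 1), each = 10)
  s <- rnorm(20, l)
  self <- compare_auc_delong(s, s, l)
  expect_equal(c(self$delta, self$z, self$p), c(0, 0, 1))
  s2 <- rnorm(20, 0.5 * l)
  ab <- compare_auc_delong(s, s2, l)
  ba <- compare_auc_delong(s2, s, l)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  # against constant scores the paired variance reduces to the single-model
  # DeLong variance
  const <- rep(0.5, 20)
  expect_equal(compare_auc_delong(s, const, l)$var, auc(s, l)$var)
  expect_error(compare_auc_delong(s, s2[-1], l), "paired")
})

test_that("confusion metrics reproduce their defining ratios with exact CIs", {
  # perfect separation
  cm <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(cm$metrics$estimate[1:3], c(1, 1, 1))
  # all predicted positive: sens 1, spec 0, PPV = prevalence
  ap <- confusion_metrics(rep(0.9, 10), rep(c(1, 0), c(7, 3)), 0.5)
  expect_equal(ap$metrics$estimate[ap$metrics$metric == "sensitivity"], 1)
  expect_equal(ap$metrics$estimate[ap$metrics$metric == "specificity"], 0)
  expect_equal(ap$metrics$estimate[ap$metrics$metric == "ppv"], 0.7)
  # TP 42 / FN 3 / TN 17 / FP 3 (validation-cohort-sized worked example)
  sc <- c(rep(0.8, 42), rep(0.2, 3), rep(0.1, 17), rep(0.9, 3))
  lb <- c(rep(1, 45), rep(0, 20))
  cm2 <- confusion_metrics(sc, lb, 0.5)
  expect_equal(cm2$tp, 42); expect_equal(cm2$fn, 3)
  expect_equal(cm2$tn, 17); expect_equal(cm2$fp, 3)
  m <- cm2$metrics
  expect_equal(m$estimate[m$metric == "sensitivity"], 42 / 45)
  expect_equal(m$estimate[m$metric == "specificity"], 17 / 20)
  expect_equal(m$estimate[m$metric == "accuracy"], 59 / 65)
  # exact binomial intervals stay inside [0, 1] and match binom.test
  expect_true(all(m$ci_low >= 0 & m$ci_high <= 1))
  bt <- binom.test(42, 45)$conf.int
  expect_equal(c(m$ci_low[m$metric == "sensitivity"],
                 m$ci_high[m$metric == "sensitivity"]),
               as.numeric(bt), tolerance = 1e-9)
  # tied score at the cutoff classifies positive
  tie <- confusion_metrics(c(0.5, 0.4), c(1, 0), 0.5)
  expect_equal(tie$tp, 1); expect_equal(tie$tn, 1)
})

test_that("two-category NRI: null, worked example, sign flip", {
  set.seed(20)
  l <- rep(c(1, 0), c(45, 20))
  s <- runif(65)
  null <- nri(s, s, l, 0.5, 0.5)
  expect_equal(c(null$nri_events, null$nri_nonevents, null$nri_total), c(0, 0, 0))
  # net 3/45 events up, net 5/20 non-events down
  old <- rep(0.4, 65)
  new <- old
  new[1:3] <- 0.9     # 3 events reclassified to malignant
  new[46:50] <- 0.1   # 5 non-events stay benign
  old[46:50] <- 0.9   # ... after being called malignant by the old model
  res <- nri(old, new, l, 0.5, 0.5)
  expect_equal(res$nri_events, 3 / 45)
  expect_equal(res$nri_nonevents, 5 / 20)
  expect_equal(res$nri_total, 3 / 45 + 5 / 20)
  expect_equal(res$nri_total, res$nri_events + res$nri_nonevents)
  flip <- nri(new, old, l, 0.5, 0.5)
  expect_equal(flip$nri_events, -res$nri_events)
  expect_equal(flip$nri_nonevents, -res$nri_nonevents)
  expect_error(nri(s, s, rep(1, 65), 0.5, 0.5), "both classes")
})

test_that("Brier score formula and prevalence property", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  expect_equal(brier(c(0.9, 0.2), c(1, 0)), 0.025)
  set.seed(22)
  l <- rbinom(200, 1, 0.3)
  p <- mean(l)
  expect_equal(brier(rep(p, 200), l), p * (1 - p))
})

test_that("calibration curve bins behave and stay within [0, 1]", {
  cc <- calibration_curve(c(0.31, 0.32, 0.33), c(1, 0, 1), n_bins = 10)
  expect_equal(nrow(cc), 1)   # all scores in one bin
  expect_equal(cc$n, 3L)
  set.seed(24)
  s <- runif(500); l <- rbinom(500, 1, s)
  cc2 <- calibration_curve(s, l)
  expect_true(all(cc2$event_fraction >= 0 & cc2$event_fraction <= 1))
  expect_equal(sum(cc2$n), 500)
  expect_equal(attr(cc2, "brier"), brier(s, l))
  expect_error(calibration_curve(s, l, n_bins = 1), "2 bins")
})

test_that("decision curve matches hand evaluation and its bounds", {
  # 10-lesion worked set at pt = 0.3
  s <- c(0.9, 0.8, 0.7, 0.4, 0.2, 0.6, 0.35, 0.1, 0.05, 0.25)
  l <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1)
  dc <- decision_curve(s, l, pt_grid = 0.3)
  tp <- sum(s >= 0.3 & l == 1); fp <- sum(s >= 0.3 & l == 0)
  expect_equal(dc$nb_model, tp / 10 - fp / 10 * 0.3 / 0.7)
  expect_equal(dc$nb_none, 0)
  # treat-all tends to prevalence as pt -> 0+
  tiny <- decision_curve(s, l, pt_grid = 1e-6)
  expect_equal(tiny$nb_all, mean(l), tolerance = 1e-5)
  # model net benefit never exceeds prevalence
  full <- decision_curve(s, l)
  expect_true(all(full$nb_model <= mean(l) + 1e-12))
  expect_error(decision_curve(s, l, pt_grid = c(0.5, 1)), "strictly")
})

test_that("evaluate_scores bundles a coherent report", {
  set.seed(26)
  l <- rep(c(0, 1), each = 15)
  s <- plogis(rnorm(30, 2 * l - 1))
  rep_ <- evaluate_scores(s, l, cutoff = 0.5)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$auc$auc, pair_count_auc(s, l))
  expect_equal(rep_$brier, mean((s - l)^2))
  expect_output(print(rep_), "AUC")
})
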