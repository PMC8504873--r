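# Discrimination, reclassification, calibration and clinical-utility
# statistics for paired risk-score models, implemented from their defining
# formulas.

check_scores_labels <- function(scores, labels) {
  labels <- as_label01(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  labels
}

#' Empirical ROC curve
#'
#' Ordered `(FPR, TPR, threshold)` triples as the classification threshold
#' sweeps from `+Inf` down through the distinct scores (predict positive at
#' `score >= threshold`). Starts at `(0, 0)` and ends at `(1, 1)`; both
#' coordinates are non-decreasing.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels (1 = event/malignant), both classes present.
#' @return data frame of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  out <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "Sensitivity", col = col, ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  } else graphics::lines(x$fpr, x$tpr, col = col, ...)
  invisible(x)
}

# DeLong placement values: for each event, the fraction of non-events it
# beats (ties count 1/2), and vice versa.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1L]  # events
  y <- scores[labels == 0L]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  list(v10 = v10, v01 = v01)
}

#' AUC with DeLong variance and confidence interval
#'
#' The area under the ROC curve by trapezoidal integration, which on the
#' empirical ROC equals the Mann-Whitney statistic (ties counted 1/2). The
#' variance and 95% CI (clipped to `[0, 1]`) use DeLong's nonparametric
#' estimator from the per-observation placement values.
#'
#' @inheritParams roc_curve
#' @param conf confidence level (default 0.95).
#' @return object of class `auc_result`: list with `auc`, `var`, `ci_low`,
#'   `ci_high`, `n_events`, `n_nonevents`.
#' @export
auc <- function(scores, labels, conf = 0.95) {
  labels <- check_scores_labels(scores, labels)
  rc <- roc_curve(scores, labels)
  a <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
  pl <- delong_placements(scores, labels)
  n1 <- length(pl$v10); n0 <- length(pl$v01)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(auc = a, var = v,
                 ci_low = max(0, a - z * sqrt(v)),
                 ci_high = min(1, a + z * sqrt(v)),
                 n_events = n1, n_nonevents = n0, conf = conf),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f; DeLong), %d events / %d non-events\n",
              x$auc, 100 * x$conf, x$ci_low, x$ci_high, x$n_events, x$n_nonevents))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two models scored on the same lesions. The variance of the AUC
#' difference uses the covariance of the two models' placement values; the
#' p-value is two-sided normal. Comparing a model with itself gives
#' `delta = 0`, `z = 0`, `p = 1`; swapping the models negates `delta` and
#' `z`.
#'
#' @param scores_a,scores_b paired score vectors (same lesions, same order).
#' @inheritParams roc_curve
#' @return list with `auc_a`, `auc_b`, `delta`, `var`, `z`, `p`.
#' @export
compare_auc_delong <- function(scores_a, scores_b, labels) {
  labels <- check_scores_labels(scores_a, labels)
  if (length(scores_a) != length(scores_b))
    stop("paired comparison requires scores for the same lesions")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- auc_a - auc_b
  z <- if (v > 0) delta / sqrt(v) else 0
  p <- if (v > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(delta == 0)
  if (v <= 0 && delta == 0) p <- 1
  list(auc_a = auc_a, auc_b = auc_b, delta = delta, var = v, z = z, p = p)
}

# Exact (Clopper-Pearson) binomial interval.
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Confusion-matrix metrics at an operating cutoff
#'
#' Classifies malignant at `score >= cutoff` and reports sensitivity,
#' specificity, accuracy, PPV and NPV with exact Clopper-Pearson 95%
#' intervals (a deliberate divergence from normal-approximation intervals,
#' which can exceed 1).
#'
#' @inheritParams roc_curve
#' @param cutoff risk-score cutoff in `[0, 1]`.
#' @return object of class `confusion_metrics`: list with counts `tp`, `fp`,
#'   `tn`, `fn` and a `metrics` data frame (estimate, ci_low, ci_high).
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  labels <- as_label01(labels)
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  fp <- sum(pred & labels == 0L); tn <- sum(!pred & labels == 0L)
  rows <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    accuracy = c(tp + tn, tp + tn + fp + fn),
    ppv = c(tp, tp + fp),
    npv = c(tn, tn + fn))
  metrics <- do.call(rbind, lapply(names(rows), function(nm) {
    x <- rows[[nm]][1]; n <- rows[[nm]][2]
    ci <- clopper_pearson(x, n)
    data.frame(metric = nm, estimate = if (n > 0) x / n else NA_real_,
               ci_low = ci[1], ci_high = ci[2])
  }))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, cutoff = cutoff,
                 metrics = metrics),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion at cutoff %.3f: TP %d, FP %d, TN %d, FN %d\n",
              x$cutoff, x$tp, x$fp, x$tn, x$fn))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n",
                m$metric[i], m$estimate[i], m$ci_low[i], m$ci_high[i]))
  invisible(x)
}

#' Two-category net reclassification index
#'
#' Compares an old and a new model, each classified at its own operating
#' cutoff (`score >= cutoff` predicts malignant). "Up" is a crossing from
#' predicted-benign to predicted-malignant.
#' `NRI+ = (up_events - down_events) / n_events`,
#' `NRI- = (down_nonevents - up_nonevents) / n_nonevents`, and the total is
#' their exact sum. The z statistic uses the standard asymptotic variance:
#' the sum of the two components' binomial-difference variances.
#'
#' @param scores_old,scores_new paired score vectors.
#' @inheritParams roc_curve
#' @param cutoff_old,cutoff_new the two models' operating cutoffs.
#' @return object of class `nri_result`: list with `nri_events`,
#'   `nri_nonevents`, `nri_total`, `z`, `p` and the movement counts.
#' @export
nri <- function(scores_old, scores_new, labels, cutoff_old, cutoff_new) {
  labels <- check_scores_labels(scores_old, labels)
  if (length(scores_old) != length(scores_new))
    stop("paired comparison requires scores for the same lesions")
  pred_old <- scores_old >= cutoff_old
  pred_new <- scores_new >= cutoff_new
  up <- !pred_old & pred_new
  down <- pred_old & !pred_new
  ev <- labels == 1L
  n_e <- sum(ev); n_ne <- sum(!ev)
  up_e <- sum(up & ev); down_e <- sum(down & ev)
  up_ne <- sum(up & !ev); down_ne <- sum(down & !ev)
  nri_e <- (up_e - down_e) / n_e
  nri_ne <- (down_ne - up_ne) / n_ne
  v_e <- (up_e + down_e) / n_e^2 - (up_e - down_e)^2 / n_e^3
  v_ne <- (up_ne + down_ne) / n_ne^2 - (down_ne - up_ne)^2 / n_ne^3
  total <- nri_e + nri_ne
  v <- v_e + v_ne
  z <- if (v > 0) total / sqrt(v) else 0
  p <- if (v > 0) 2 * stats::pnorm(-abs(z)) else 1
  structure(list(nri_events = nri_e, nri_nonevents = nri_ne, nri_total = total,
                 z = z, p = p,
                 counts = c(up_events = up_e, down_events = down_e,
                            up_nonevents = up_ne, down_nonevents = down_ne),
                 n_events = n_e, n_nonevents = n_ne),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI = %.3f (events %.3f + non-events %.3f), z = %.2f, p = %.3g\n",
              x$nri_total, x$nri_events, x$nri_nonevents, x$z, x$p))
  invisible(x)
}

#' Brier score
#'
#' Mean squared difference between predicted risk and the binary outcome;
#' 0 is perfect, and a constant prediction at the prevalence `p` scores
#' `p (1 - p)`.
#'
#' @inheritParams roc_curve
#' @return a single number.
#' @export
brier <- function(scores, labels) {
  labels <- as_label01(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  mean((scores - labels)^2)
}

#' Calibration curve
#'
#' Bins predicted risks into equal-width bins on `[0, 1]` and reports the
#' per-bin mean predicted risk and observed event fraction (empty bins are
#' omitted), with the Brier score attached as a scalar summary.
#'
#' @inheritParams roc_curve
#' @param n_bins number of equal-width bins (>= 2).
#' @return object of class `calibration_curve`: data frame with columns
#'   `bin`, `mean_score`, `event_fraction`, `n`; attribute `brier`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  labels <- as_label01(labels)
  if (n_bins < 2L) stop("need at least 2 bins")
  bin <- pmin(floor(scores * n_bins) + 1L, n_bins)
  keep <- sort(unique(bin))
  out <- data.frame(
    bin = keep,
    mean_score = vapply(keep, function(b) mean(scores[bin == b]), 0),
    event_fraction = vapply(keep, function(b) mean(labels[bin == b]), 0),
    n = vapply(keep, function(b) sum(bin == b), 0L))
  attr(out, "brier") <- brier(scores, labels)
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$mean_score, x$event_fraction, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Mean predicted risk", ylab = "Observed event fraction",
                 type = "b", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of treating at threshold probability `pt`, classifying
#' positive at `score >= pt`:
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)`, compared against the treat-all
#' and treat-none (identically zero) strategies.
#'
#' @inheritParams roc_curve
#' @param pt_grid threshold probabilities, all strictly inside `(0, 1)`
#'   (default 0.01 to 0.99 in steps of 0.01).
#' @return object of class `decision_curve`: data frame with columns `pt`,
#'   `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(scores, labels, pt_grid = seq(0.01, 0.99, by = 0.01)) {
  labels <- as_label01(labels)
  if (any(pt_grid <= 0 | pt_grid >= 1)) stop("thresholds must lie strictly in (0, 1)")
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(pt_grid, function(pt) {
    pred <- scores >= pt
    tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
  nb_all <- prev - (1 - prev) * pt_grid / (1 - pt_grid)
  out <- data.frame(pt = pt_grid, nb_model = nb, nb_all = nb_all, nb_none = 0)
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' @export
plot.decision_curve <- function(x, ...) {
  graphics::plot(x$pt, x$nb_model, type = "l",
                 ylim = range(c(x$nb_model, 0, max(x$nb_all))),
                 xlab = "Threshold probability", ylab = "Net benefit", ...)
  graphics::lines(x$pt, x$nb_all, lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3, col = "grey60")
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), col = c("black", "grey40", "grey60"),
                   bty = "n")
  invisible(x)
}

#' Full evaluation of one model on one cohort
#'
#' Convenience wrapper bundling AUC/CI, confusion metrics at the model's
#' cutoff, Brier score, calibration curve and decision curve.
#'
#' @inheritParams roc_curve
#' @param cutoff operating cutoff (e.g. chosen on the training cohort).
#' @return object of class `eval_report`.
#' @export
evaluate_scores <- function(scores, labels, cutoff) {
  labels <- check_scores_labels(scores, labels)
  structure(list(
    auc = auc(scores, labels),
    confusion = confusion_metrics(scores, labels, cutoff),
    brier = brier(scores, labels),
    calibration = calibration_curve(scores, labels),
    decision = decision_curve(scores, labels),
    roc = roc_curve(scores, labels),
    cutoff = cutoff, n = length(labels)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$auc)
  print(x$confusion)
  cat(sprintf("  Brier score: %.3f\n", x$brier))
  invisible(x)
}
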