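#' Configuration for an end-to-end conversion-method comparison
#'
#' Bundles the synthetic-cohort settings, feature bank, split, classifiers
#' and master seed of one experiment. Every stage seed (cohort generation,
#' split, SMOTE, LASSO folds, classifiers) is derived deterministically from
#' the master seed, so a config fully determines the result.
#'
#' @param config an [swe_config()] describing the cohort to simulate.
#' @param n_benign,n_malignant cohort class counts (defaults: the 40/90
#'   composition of a 130-lesion cohort).
#' @param bank a [feature_bank()].
#' @param ratio train:validation split ratio.
#' @param classifiers character subset of `rf`, `svm`, `adaboost`, `lr`.
#' @param smote apply SMOTE to the training cohort?
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(config = swe_config(mode = "metameric"),
                       n_benign = 40L, n_malignant = 90L,
                       bank = feature_bank(),
                       ratio = c(1, 1),
                       classifiers = c("rf", "svm", "adaboost", "lr"),
                       smote = TRUE, seed = 1L) {
  classifiers <- match.arg(classifiers,
                           c("rf", "svm", "adaboost", "lr"), several.ok = TRUE)
  structure(list(config = config, n_benign = n_benign,
                 n_malignant = n_malignant, bank = bank, ratio = ratio,
                 classifiers = classifiers, smote = smote, seed = seed),
            class = "run_config")
}

#' Run the two-arm conversion-method comparison
#'
#' The core experiment: one cohort of color elastograms is processed by both
#' preprocessing arms — direct luminance conversion and RGB three-channel
#' decomposition — through the identical split, oversampling, feature
#' selection and classifier stages with identical derived seeds, so the
#' conversion method is the only varying factor. Each arm is evaluated on
#' the validation cohort (AUC with DeLong CI, confusion metrics at the
#' training-chosen Youden cutoff, Brier, calibration, decision curve) and
#' the arms are compared pairwise (DeLong test, two-category NRI with each
#' arm at its own cutoff, Brier difference).
#'
#' @param rc a [run_config()]; alternatively pass a prebuilt cohort via
#'   `cohort` to evaluate external data.
#' @param cohort optional `swe_cohort`; when supplied the synthetic
#'   generation step is skipped.
#' @param quiet suppress stage-by-stage progress messages?
#' @return object of class `swe_comparison`: per-arm, per-classifier
#'   evaluation reports, the pairwise comparison table, per-lesion scores
#'   and a run manifest with all seeds.
#' @export
run_comparison <- function(rc = run_config(), cohort = NULL, quiet = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(cohort)) {
    cohort <- generate_cohort(rc$config, rc$n_benign, rc$n_malignant,
                              seed = derive_seed(rc$seed, "cohort"))
    say("simulate: %d images (%d benign / %d malignant), mode = %s",
        length(cohort), rc$n_benign, rc$n_malignant, rc$config$mode)
  }
  tables <- list(direct = extract_cohort(cohort, rc$bank, "direct"),
                 rgb = extract_cohort(cohort, rc$bank, "rgb3"))
  say("extract: %d features (direct), %d features (rgb3)",
      ncol(feature_matrix(tables$direct)), ncol(feature_matrix(tables$rgb)))
  split_seed <- derive_seed(rc$seed, "split")
  splits <- lapply(tables, stratified_split, ratio = rc$ratio, seed = split_seed)
  stopifnot(identical(splits$direct$train$id, splits$rgb$train$id))
  say("split: %d train / %d validation (seed %d)",
      nrow(splits$direct$train), nrow(splits$direct$valid), split_seed)

  arms <- list()
  for (arm in c("direct", "rgb")) {
    arms[[arm]] <- list()
    for (cl in rc$classifiers) {
      fit <- suppressWarnings(
        ultrasomics_fit(splits[[arm]]$train, classifier = cl,
                        smote = rc$smote, seed = rc$seed))
      valid <- splits[[arm]]$valid
      scores <- predict(fit, valid)
      arms[[arm]][[cl]] <- list(
        fit = fit,
        scores = scores,
        labels = valid$label,
        report = evaluate_scores(scores, valid$label, fit$cutoff))
      say("train/evaluate [%s, %s]: %d selected features, validation AUC %.3f",
          arm, cl, length(fit$features), arms[[arm]][[cl]]$report$auc$auc)
    }
  }

  comparison <- lapply(stats::setNames(rc$classifiers, rc$classifiers), function(cl) {
    d <- arms$direct[[cl]]; r <- arms$rgb[[cl]]
    list(delong = compare_auc_delong(r$scores, d$scores, d$labels),
         nri = nri(d$scores, r$scores, d$labels,
                   d$fit$cutoff, r$fit$cutoff),
         brier_direct = d$report$brier,
         brier_rgb = r$report$brier)
  })

  manifest <- list(
    master_seed = rc$seed,
    stage_seeds = list(cohort = derive_seed(rc$seed, "cohort"),
                       split = split_seed,
                       smote = derive_seed(rc$seed, "smote"),
                       lasso = derive_seed(rc$seed, "lasso"),
                       classifier = derive_seed(rc$seed, "classifier"),
                       calibration = derive_seed(rc$seed, "calibration")),
    n_images = length(cohort),
    n_train = nrow(splits$direct$train),
    n_valid = nrow(splits$direct$valid),
    n_features = c(direct = ncol(feature_matrix(tables$direct)),
                   rgb = ncol(feature_matrix(tables$rgb))),
    classifiers = rc$classifiers,
    smote = rc$smote,
    selected_features = lapply(arms, function(a)
      lapply(a, function(x) x$fit$features)))

  structure(list(arms = arms, comparison = comparison, manifest = manifest,
                 splits = lapply(splits, function(s) list(train_id = s$train$id,
                                                          valid_id = s$valid$id)),
                 tables = tables),
            class = "swe_comparison")
}

#' @export
print.swe_comparison <- function(x, ...) {
  cat("Conversion-method comparison (validation cohort)\n")
  cat(sprintf("  %d images: %d train / %d validation; master seed %d\n",
              x$manifest$n_images, x$manifest$n_train, x$manifest$n_valid,
              x$manifest$master_seed))
  cat(sprintf("  features: %d (direct) vs %d (rgb3)\n\n",
              x$manifest$n_features["direct"], x$manifest$n_features["rgb"]))
  for (cl in names(x$comparison)) {
    cmp <- x$comparison[[cl]]
    cat(sprintf("[%s]\n", toupper(cl)))
    cat(sprintf("  AUC direct %.3f vs rgb %.3f (DeLong p = %.3g)\n",
                cmp$delong$auc_b, cmp$delong$auc_a, cmp$delong$p))
    cat(sprintf("  NRI (rgb vs direct) = %.3f (events %.3f, non-events %.3f; p = %.3g)\n",
                cmp$nri$nri_total, cmp$nri$nri_events, cmp$nri$nri_nonevents,
                cmp$nri$p))
    cat(sprintf("  Brier direct %.3f vs rgb %.3f\n",
                cmp$brier_direct, cmp$brier_rgb))
  }
  invisible(x)
}

#' @export
plot.swe_comparison <- function(x, classifier = names(x$comparison)[1],
                                which = c("roc", "decision", "calibration"),
                                ...) {
  which <- match.arg(which)
  d <- x$arms$direct[[classifier]]$report
  r <- x$arms$rgb[[classifier]]$report
  if (which == "roc") {
    plot(d$roc, col = "grey40",
         main = sprintf("ROC, %s (validation)", toupper(classifier)))
    plot(r$roc, add = TRUE, col = "firebrick")
    graphics::legend("bottomright",
                     c(sprintf("direct (AUC %.3f)", d$auc$auc),
                       sprintf("rgb3 (AUC %.3f)", r$auc$auc)),
                     col = c("grey40", "firebrick"), lty = 1, bty = "n")
  } else if (which == "decision") {
    plot(r$decision, main = sprintf("Decision curves, %s", toupper(classifier)))
    graphics::lines(d$decision$pt, d$decision$nb_model, col = "grey40")
  } else {
    plot(r$calibration, main = sprintf("Calibration, %s (rgb3)", toupper(classifier)))
  }
  invisible(x)
}

#' Export a comparison's reports and manifest to a directory
#'
#' Writes `manifest.json`, per-arm score CSVs and a JSON summary of every
#' comparison statistic.
#'
#' @param x an `swe_comparison`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_comparison <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_json(x$manifest, file.path(dir, "manifest.json"))
  for (arm in names(x$arms)) for (cl in names(x$arms[[arm]])) {
    rec <- x$arms[[arm]][[cl]]
    write_scores_csv(x$splits[[arm]]$valid_id %||% seq_along(rec$scores),
                     rec$labels, rec$scores, paste(arm, cl, sep = "_"),
                     "validation",
                     file.path(dir, sprintf("scores_%s_%s.csv", arm, cl)))
  }
  summary <- lapply(x$comparison, function(cmp) list(
    auc_direct = cmp$delong$auc_b, auc_rgb = cmp$delong$auc_a,
    delta_auc = cmp$delong$delta, delong_p = cmp$delong$p,
    nri_total = cmp$nri$nri_total, nri_events = cmp$nri$nri_events,
    nri_nonevents = cmp$nri$nri_nonevents, nri_p = cmp$nri$p,
    brier_direct = cmp$brier_direct, brier_rgb = cmp$brier_rgb))
  write_report_json(summary, file.path(dir, "comparison.json"))
  invisible(dir)
}
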