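# Risk-score classifiers on LASSO-selected features. All four emit
# probabilities in [0, 1]; margin classifiers (SVM, AdaBoost) are mapped to
# probabilities by Platt-style sigmoid calibration fitted on out-of-fold
# training margins.

# Discrete AdaBoost with decision stumps (rpart, maxdepth = 1).
fit_adaboost <- function(Z, y01, n_stumps = 100L) {
  df <- as.data.frame(Z)
  df$.y <- factor(y01, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0)
  for (m in seq_len(n_stumps)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(w * (pred != y01)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y01, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break  # perfect stump; further rounds are redundant
  }
  structure(list(stumps = stumps, alphas = alphas), class = "adaboost_stumps")
}

predict_adaboost <- function(object, Z) {
  df <- as.data.frame(Z)
  F <- rep(0, nrow(df))
  for (m in seq_along(object$stumps)) {
    pred <- as.integer(as.character(
      stats::predict(object$stumps[[m]], df, type = "class")))
    F <- F + object$alphas[m] * (2 * pred - 1)
  }
  if (length(object$alphas)) F / sum(abs(object$alphas)) else F
}

# Platt sigmoid: logistic regression of the outcome on the margin. Degenerate
# margins (zero variance) fall back to the prevalence.
fit_platt <- function(margins, y01) {
  if (stats::var(margins) == 0)
    return(list(constant = mean(y01)))
  fit <- suppressWarnings(stats::glm(y01 ~ margins, family = stats::binomial()))
  list(coef = stats::coef(fit))
}

apply_platt <- function(cal, margins) {
  if (!is.null(cal$constant)) return(rep(cal$constant, length(margins)))
  stats::plogis(cal$coef[1] + cal$coef[2] * margins)
}

# Fit one classifier kind on a selected, standardized matrix with synthetic
# internal column names (F1..Fk) to keep formula interfaces safe.
fit_one_classifier <- function(kind, Z, y01, seed, rf_trees, ada_stumps) {
  yf <- factor(y01, levels = c(0, 1))
  with_seed(seed, switch(kind,
    rf = list(model = randomForest::randomForest(x = Z, y = yf,
                                                 ntree = rf_trees)),
    svm = list(model = e1071::svm(x = Z, y = yf, kernel = "radial",
                                  gamma = 1 / ncol(Z), cost = 1,
                                  scale = FALSE)),
    adaboost = list(model = fit_adaboost(Z, y01, ada_stumps)),
    lr = {
      df <- as.data.frame(Z); df$.y <- y01
      list(model = suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial())))
    }))
}

classifier_margin <- function(kind, fit, Z) {
  switch(kind,
    rf = stats::predict(fit$model, Z, type = "prob")[, "1"],
    svm = as.numeric(attr(stats::predict(fit$model, Z, decision.values = TRUE),
                          "decision.values")[, 1]),
    adaboost = predict_adaboost(fit$model, Z),
    lr = stats::predict(fit$model, as.data.frame(Z), type = "response"))
}

#' Fit an ultrasomics risk-score model
#'
#' The full training pipeline on one conversion arm's feature table:
#' training-set standardization, duplicate/constant column removal, SMOTE
#' minority oversampling (training data only), LASSO feature selection, and
#' one of four classifiers (random forest, RBF-kernel SVM, AdaBoost with
#' decision stumps, or unpenalized logistic regression on the selected
#' features). SVM and AdaBoost margins are calibrated to probabilities with
#' a Platt sigmoid fitted on out-of-fold training margins, so all four model
#' kinds emit comparable risk scores in `[0, 1]`. The operating cutoff is
#' chosen on the (oversampled) training scores by the Youden index.
#'
#' All randomness (SMOTE, CV folds, classifier) is derived deterministically
#' from `seed`: two fits with the same inputs and seed agree exactly.
#'
#' @param train a [feature_table()] with both classes present.
#' @param classifier `"rf"`, `"svm"`, `"adaboost"` or `"lr"`.
#' @param smote apply SMOTE rebalancing (default TRUE)?
#' @param k SMOTE neighbour count.
#' @param nfolds folds for LASSO CV and margin calibration.
#' @param rf_trees random-forest tree count (default 500).
#' @param ada_stumps AdaBoost stump count (default 100).
#' @param seed master seed for the fit.
#' @return object of class `ultrasomics_fit` with `print`, `summary`,
#'   `coef`, `predict` and `residuals` methods.
#' @export
ultrasomics_fit <- function(train, classifier = c("rf", "svm", "adaboost", "lr"),
                            smote = TRUE, k = 5L, nfolds = 5L,
                            rf_trees = 500L, ada_stumps = 100L, seed = 1L) {
  classifier <- match.arg(classifier)
  lab <- as_label01(train$label)
  if (length(unique(lab)) < 2L) stop("training set must contain both classes")
  std <- standardize_train(feature_matrix(train))
  ztab <- feature_table(train$id, lab, std$Z)
  if (smote) ztab <- smote_oversample(ztab, k = k, seed = derive_seed(seed, "smote"))
  Zb <- feature_matrix(ztab); yb <- ztab$label
  sel <- lasso_select(Zb, yb, nfolds = nfolds, seed = derive_seed(seed, "lasso"))
  Zs <- Zb[, sel$selected, drop = FALSE]
  internal <- sprintf("F%d", seq_along(sel$selected))
  colnames(Zs) <- internal
  fit <- fit_one_classifier(classifier, Zs, yb, derive_seed(seed, "classifier"),
                            rf_trees, ada_stumps)
  calibration <- NULL
  if (classifier %in% c("svm", "adaboost")) {
    oof <- with_seed(derive_seed(seed, "calibration"), {
      foldid <- sample(rep(seq_len(nfolds), length.out = nrow(Zs)))
      m <- numeric(nrow(Zs))
      for (f in seq_len(nfolds)) {
        hold <- foldid == f
        ffit <- fit_one_classifier(classifier, Zs[!hold, , drop = FALSE],
                                   yb[!hold], derive_seed(seed, "classifier"),
                                   rf_trees, ada_stumps)
        m[hold] <- classifier_margin(classifier, ffit, Zs[hold, , drop = FALSE])
      }
      m
    })
    calibration <- fit_platt(oof, yb)
  }
  object <- structure(list(
    classifier = classifier, std = std, selection = sel,
    features = sel$selected, internal_names = internal,
    fit = fit, calibration = calibration,
    smote = smote, seed = seed,
    n_train = nrow(train), n_after_smote = nrow(ztab),
    train_labels = lab
  ), class = "ultrasomics_fit")
  train_scores <- predict(object, train)
  object$train_scores <- train_scores
  object$cutoff <- suppressWarnings(choose_cutoff(train_scores, lab))
  object
}

#' Predict risk scores from a fitted ultrasomics model
#'
#' @param object an [ultrasomics_fit()] model.
#' @param newdata a `feature_table` (or a plain data frame / matrix carrying
#'   the model's feature columns).
#' @param type `"score"` for risk scores in `[0, 1]`, `"class"` for 0/1
#'   predictions at the model's operating cutoff.
#' @param ... unused.
#' @return numeric vector of scores, or integer 0/1 vector.
#' @export
predict.ultrasomics_fit <- function(object, newdata,
                                    type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, setdiff(colnames(newdata), c("id", "label")), drop = FALSE])
  Z <- standardize_apply(X, object$std)[, object$features, drop = FALSE]
  colnames(Z) <- object$internal_names
  m <- classifier_margin(object$classifier, object$fit, Z)
  score <- if (is.null(object$calibration)) m else apply_platt(object$calibration, m)
  score <- clamp(as.numeric(score), 0, 1)
  if (type == "class") as.integer(score >= object$cutoff) else score
}

#' Risk scores for a cohort table (spec-style alias of the predict method)
#' @inheritParams predict.ultrasomics_fit
#' @param table a `feature_table`.
#' @param model an `ultrasomics_fit`.
#' @return numeric risk scores in `[0, 1]`, one per lesion.
#' @export
predict_scores <- function(model, table) predict(model, table, type = "score")

#' @export
print.ultrasomics_fit <- function(x, ...) {
  kinds <- c(rf = "random forest", svm = "SVM (RBF)",
             adaboost = "AdaBoost (stumps)", lr = "logistic regression")
  cat(sprintf("Ultrasomics risk-score model: %s\n", kinds[[x$classifier]]))
  cat(sprintf("  trained on %d lesions%s, %d LASSO-selected feature(s)\n",
              x$n_train,
              if (x$smote) sprintf(" (SMOTE-balanced to %d)", x$n_after_smote) else "",
              length(x$features)))
  cat(sprintf("  operating cutoff (Youden): %.3f; seed %d\n", x$cutoff, x$seed))
  invisible(x)
}

#' @export
summary.ultrasomics_fit <- function(object, ...) {
  print(object)
  cat("Selected features:\n")
  cat(" ", paste(object$features, collapse = "\n  "), "\n")
  cat(sprintf("LASSO: lambda = %s (%s rule)\n",
              if (is.na(object$selection$lambda)) "NA"
              else format(object$selection$lambda, digits = 4),
              object$selection$rule))
  invisible(object)
}

#' @export
coef.ultrasomics_fit <- function(object, ...) {
  if (object$classifier == "lr") {
    cf <- stats::coef(object$fit$model)
    names(cf) <- c("(Intercept)", object$features)
    return(cf)
  }
  s <- object$selection
  if (is.na(s$lambda)) return(stats::setNames(rep(NA_real_, length(object$features)),
                                              object$features))
  cf <- as.matrix(stats::coef(s$cv, s = s$lambda))
  stats::setNames(cf[c("(Intercept)", object$features), 1],
                  c("(Intercept)", object$features))
}

#' @export
residuals.ultrasomics_fit <- function(object, ...) {
  object$train_scores - object$train_labels
}
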