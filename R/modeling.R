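#' Stratified random split of a cohort feature table
#'
#' Splits lesions into training and validation sets at the given ratio,
#' preserving the class proportions within integer rounding. A 1:1 split of
#' a 90-malignant / 40-benign cohort yields a 65-lesion training set with 45
#' malignant and 20 benign lesions.
#'
#' @param table a [feature_table()].
#' @param ratio length-2 positive numeric, train:validation parts
#'   (default `c(1, 1)`).
#' @param seed integer seed; the partition is reproducible from it.
#' @return list with elements `train` and `valid` (feature tables whose
#'   union is the input and intersection is empty) plus the `seed`.
#' @export
stratified_split <- function(table, ratio = c(1, 1), seed = NULL) {
  stopifnot(inherits(table, "data.frame"), length(ratio) == 2, all(ratio > 0))
  p_train <- ratio[1] / sum(ratio)
  lab <- table$label
  if (any(tabulate(lab + 1L, 2L) < 2L))
    stop("each class needs at least 2 lesions to stratify")
  with_seed(seed, {
    idx_train <- integer(0)
    for (cls in c(0L, 1L)) {
      rows <- which(lab == cls)
      k <- round(length(rows) * p_train)
      k <- min(max(k, 1L), length(rows) - 1L)
      idx_train <- c(idx_train, sample(rows, k))
    }
    idx_train <- sort(idx_train)
    list(train = table[idx_train, , drop = FALSE],
         valid = table[-idx_train, , drop = FALSE],
         seed = seed)
  })
}

#' SMOTE minority oversampling
#'
#' Raises the minority class of a training table to the majority count by
#' interpolating synthetic samples: each new sample is `x + u * (x' - x)`
#' with `u ~ Uniform(0, 1)`, `x` a real minority sample and `x'` one of its
#' `k` nearest minority neighbours (Euclidean distance on standardized
#' features). Majority rows are never altered, and oversampling must only
#' ever be applied to training data.
#'
#' @param table a [feature_table()] (training cohort).
#' @param k number of nearest minority neighbours (default 5); truncated
#'   with a warning if it exceeds `minority size - 1`.
#' @param seed integer seed.
#' @return a `feature_table` with equal class counts; synthetic rows get ids
#'   `synth_<n>`.
#' @export
smote_oversample <- function(table, k = 5L, seed = NULL) {
  lab <- table$label
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  if (n_pos == n_neg) return(table)
  minority <- if (n_pos < n_neg) 1L else 0L
  n_min <- min(n_pos, n_neg)
  if (n_min < 2L) stop("SMOTE needs at least 2 minority samples to interpolate")
  if (k > n_min - 1L) {
    warning("k exceeds minority size - 1; truncated to ", n_min - 1L)
    k <- n_min - 1L
  }
  X <- feature_matrix(table)
  Xm <- X[lab == minority, , drop = FALSE]
  # neighbour search on standardized features (constant columns contribute 0)
  sds <- apply(Xm, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- sweep(sweep(Xm, 2, colMeans(Xm)), 2, sds, "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  nb <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  n_new <- abs(n_pos - n_neg)
  with_seed(seed, {
    synth <- matrix(0, n_new, ncol(X), dimnames = list(NULL, colnames(X)))
    for (s in seq_len(n_new)) {
      i <- ((s - 1L) %% n_min) + 1L
      j <- nb[i, sample.int(k, 1L)]
      u <- stats::runif(1)
      synth[s, ] <- Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
    }
    out <- feature_table(c(table$id, sprintf("synth_%03d", seq_len(n_new))),
                         c(lab, rep(minority, n_new)),
                         rbind(X, synth))
    out
  })
}

# Training-set standardization. Returns centered/scaled matrix plus the
# parameters needed to transform new data identically. Constant columns are
# dropped with a warning; exact duplicate columns are dropped (keeping the
# lowest-index one), which both removes degenerate collinearity and fixes
# the documented lowest-index tie-break for duplicated features.
standardize_train <- function(X) {
  keep <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature column(s) dropped before fitting")
    keep <- keep[sds > 0]
  }
  X <- X[, keep, drop = FALSE]
  dup <- duplicated(t(X))
  if (any(dup)) keep <- keep[!dup]
  X <- X[, keep, drop = FALSE]
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  list(Z = sweep(sweep(X, 2, center), 2, scale, "/"),
       features = keep, center = center, scale = scale)
}

standardize_apply <- function(X, std) {
  missing <- setdiff(std$features, colnames(X))
  if (length(missing))
    stop("table lacks model features: ", paste(utils::head(missing, 3), collapse = ", "))
  X <- X[, std$features, drop = FALSE]
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

#' LASSO feature selection by cross-validated logistic regression
#'
#' Fits an L1-penalized logistic regression path over a lambda grid on
#' standardized features and selects the features with nonzero coefficients
#' at the lambda chosen by k-fold cross-validated deviance with the 1-SE
#' rule. If the 1-SE model is intercept-only the selection falls back to
#' `lambda.min`, and failing that to the first feature entering the path, so
#' downstream classifiers always receive at least one predictor.
#'
#' @param Z standardized feature matrix (zero mean, unit variance on the
#'   training cohort).
#' @param label 0/1 outcome vector.
#' @param nfolds cross-validation folds (default 5).
#' @param lambda optional lambda grid (default: glmnet's).
#' @param seed integer seed controlling the fold assignment.
#' @return object of class `lasso_selection`: list with `selected` (feature
#'   names), `lambda` (chosen value), `rule`, `lambda_grid`, `nfolds`,
#'   `seed` and the fitted `cv` object.
#' @export
lasso_select <- function(Z, label, nfolds = 5L, lambda = NULL, seed = NULL) {
  stopifnot(is.matrix(Z), nrow(Z) == length(label))
  label <- as_label01(label)
  with_seed(seed, {
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(Z)))
    cv <- glmnet::cv.glmnet(Z, label, family = "binomial", foldid = foldid,
                            lambda = lambda, standardize = FALSE)
    pick <- function(lam) {
      cf <- as.matrix(stats::coef(cv, s = lam))
      rownames(cf)[-1][cf[-1, 1] != 0]
    }
    sel <- pick(cv$lambda.1se); rule <- "1se"; lam <- cv$lambda.1se
    if (length(sel) == 0L) {
      sel <- pick(cv$lambda.min); rule <- "min"; lam <- cv$lambda.min
    }
    if (length(sel) == 0L) {
      # first feature to enter the regularization path
      beta <- cv$glmnet.fit$beta
      enter <- apply(as.matrix(beta) != 0, 1, function(r) {
        w <- which(r); if (length(w)) w[1] else Inf
      })
      sel <- rownames(beta)[which.min(enter)]
      rule <- "first_entry"; lam <- NA_real_
    }
    structure(list(selected = sel, lambda = lam, rule = rule,
                   lambda_grid = cv$lambda, nfolds = nfolds, seed = seed,
                   cv = cv),
              class = "lasso_selection")
  })
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("LASSO selection: %d feature(s) at lambda = %s (%s rule, %d-fold CV)\n",
              length(x$selected),
              if (is.na(x$lambda)) "NA" else format(x$lambda, digits = 4),
              x$rule, x$nfolds))
  if (length(x$selected) <= 12) cat(" ", paste(x$selected, collapse = "\n  "), "\n")
  invisible(x)
}

#' Operating cutoff by the Youden index
#'
#' Chooses the risk-score cutoff maximizing `sensitivity + specificity - 1`
#' on a (training) cohort, classifying malignant at `score >= cutoff`.
#' Candidate cutoffs are the midpoints between consecutive distinct scores
#' together with the minimum score (classify-all-positive); ties are broken
#' toward the lower cutoff. Degenerate single-valued scores return 0.5 with
#' a warning.
#'
#' @param scores numeric risk scores in `[0, 1]`.
#' @param labels 0/1 labels.
#' @return a single cutoff value.
#' @export
choose_cutoff <- function(scores, labels) {
  labels <- as_label01(labels)
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("degenerate single-valued scores; cutoff defaults to 0.5")
    return(0.5)
  }
  cand <- c(u[1], (u[-length(u)] + u[-1]) / 2)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  # integer-exact numerator of sens + spec - 1 = (tp * n0 - fp * n1)/(n1 n0),
  # so tie detection is immune to floating-point rounding
  youden_num <- vapply(cand, function(ct) {
    pred <- scores >= ct
    sum(pred & labels == 1L) * n0 - sum(pred & labels == 0L) * n1
  }, 0)
  cand[which.max(youden_num)]  # which.max takes the first (lowest) maximizer
}
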