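# Small labelled table with informative and noise features.
toy_table <- function(n1 = 45, n0 = 20, p_noise = 10, sep = 3, seed = 1) {
  set.seed(seed)
  n <- n1 + n0
  lab <- c(rep(1L, n1), rep(0L, n0))
  X <- matrix(rnorm(n * p_noise), n, p_noise,
              dimnames = list(NULL, sprintf("noise_%02d", seq_len(p_noise))))
  X <- cbind(signal = rnorm(n, sep * lab), X)
  feature_table(sprintf("l%03d", seq_len(n)), lab, X)
}

test_that("a 1:1 stratified split of a 90/40 cohort yields the 65-lesion training set", {
  tab <- toy_table(n1 = 90, n0 = 40)
  sp <- stratified_split(tab, c(1, 1), seed = 2)
  expect_equal(nrow(sp$train), 65)
  expect_equal(sum(sp$train$label == 1), 45)
  expect_equal(sum(sp$train$label == 0), 20)
  expect_setequal(c(sp$train$id, sp$valid$id), tab$id)
  expect_length(intersect(sp$train$id, sp$valid$id), 0)
  sp2 <- stratified_split(tab, c(1, 1), seed = 2)
  expect_identical(sp$train$id, sp2$train$id)
  tiny <- toy_table(n1 = 2, n0 = 2)
  sp3 <- stratified_split(tiny, c(1, 1), seed = 1)
  expect_equal(as.integer(table(sp3$train$label)), c(1L, 1L))
  expect_error(stratified_split(toy_table(n1 = 1, n0 = 5), c(1, 1), 1),
               "at least 2")
})

test_that("SMOTE balances 45/20 to 45/45 and only adds interpolated minority rows", {
  tab <- toy_table(n1 = 45, n0 = 20)
  out <- smote_oversample(tab, k = 5, seed = 3)
  expect_equal(nrow(out), 90)
  expect_equal(sum(out$label == 1), 45)
  expect_equal(sum(out$label == 0), 45)
  # majority rows untouched, original minority rows preserved verbatim
  expect_identical(feature_matrix(out)[seq_len(65), ], feature_matrix(tab))
  # every synthetic row is coordinate-wise between two real minority rows
  Xmin <- feature_matrix(tab)[tab$label == 0, ]
  synth <- feature_matrix(out)[66:90, ]
  lo <- apply(Xmin, 2, min); hi <- apply(Xmin, 2, max)
  for (s in seq_len(nrow(synth))) {
    expect_true(all(synth[s, ] >= lo - 1e-12 & synth[s, ] <= hi + 1e-12))
    # and exactly on a segment: s = x + u (x' - x) for some minority pair
    on_segment <- FALSE
    for (i in seq_len(nrow(Xmin))) for (j in seq_len(nrow(Xmin))) {
      if (i == j) next
      d <- Xmin[j, ] - Xmin[i, ]
      nz <- which(abs(d) > 1e-12)
      u <- (synth[s, nz[1]] - Xmin[i, nz[1]]) / d[nz[1]]
      if (u >= 0 && u <= 1 &&
          max(abs(synth[s, ] - (Xmin[i, ] + u * d))) < 1e-8) {
        on_segment <- TRUE; break
      }
    }
    expect_true(on_segment)
  }
})

test_that("SMOTE edge cases: balanced input unchanged, tiny minority, k truncation", {
  bal <- toy_table(n1 = 10, n0 = 10)
  expect_identical(smote_oversample(bal, seed = 1), bal)
  expect_error(smote_oversample(toy_table(n1 = 10, n0 = 1), seed = 1),
               "at least 2 minority")
  expect_warning(out <- smote_oversample(toy_table(n1 = 10, n0 = 3), k = 5, seed = 1),
                 "truncated")
  expect_equal(sum(out$label == 0), 10)
})

test_that("LASSO finds a separating feature among pure noise", {
  set.seed(10)
  n <- 100
  lab <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 200), n, 200,
              dimnames = list(NULL, sprintf("noise_%03d", 1:200)))
  X <- cbind(X, signal = lab + rnorm(n, 0, 0.1))
  Z <- scale(X)
  sel <- lasso_select(Z, lab, seed = 5)
  expect_true("signal" %in% sel$selected)
  expect_lt(length(sel$selected), 30)
  # the chosen lambda lies on the grid
  expect_true(is.na(sel$lambda) || any(abs(sel$lambda - sel$lambda_grid) < 1e-12))
})

test_that("duplicated columns keep only the lowest-index copy", {
  tab <- toy_table(n1 = 30, n0 = 30)
  X <- feature_matrix(tab)
  X2 <- cbind(X, signal_copy = X[, "signal"])
  std <- rgbomics:::standardize_train(X2)
  expect_true("signal" %in% std$features)
  expect_false("signal_copy" %in% std$features)
  const <- cbind(X, flat = rep(1, nrow(X)))
  expect_warning(std2 <- rgbomics:::standardize_train(const), "constant")
  expect_false("flat" %in% std2$features)
})

test_that("Youden cutoff matches exhaustive search and handles degeneracy", {
  # perfectly separated: lowest midpoint in the gap
  s <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  l <- c(0, 0, 0, 1, 1, 1)
  expect_equal(choose_cutoff(s, l), 0.5)
  # brute-force oracle over candidate midpoints on random overlapping scores
  set.seed(8)
  for (i in 1:10) {
    sc <- round(runif(30), 2)
    lb <- rbinom(30, 1, plogis(4 * (sc - 0.5)))
    if (length(unique(lb)) < 2 || length(unique(sc)) < 2) next
    u <- sort(unique(sc))
    cand <- c(u[1], (head(u, -1) + tail(u, -1)) / 2)
    youden <- sapply(cand, function(ct) {
      mean(sc[lb == 1] >= ct) - mean(sc[lb == 0] >= ct)
    })
    best <- min(cand[youden >= max(youden) - 1e-12])  # lowest among tied maxima
    expect_equal(choose_cutoff(sc, lb), best)
  }
  expect_warning(ct <- choose_cutoff(rep(0.4, 10), rep(c(0, 1), 5)), "degenerate")
  expect_equal(ct, 0.5)
})

test_that("fitted models are deterministic, bounded and permutation-equivariant", {
  tab <- toy_table(n1 = 40, n0 = 25, seed = 6)
  valid <- toy_table(n1 = 20, n0 = 12, seed = 7)
  for (cl in c("rf", "svm", "adaboost", "lr")) {
    fit1 <- suppressWarnings(ultrasomics_fit(tab, cl, seed = 11))
    fit2 <- suppressWarnings(ultrasomics_fit(tab, cl, seed = 11))
    s1 <- predict(fit1, valid); s2 <- predict(fit2, valid)
    expect_identical(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1))
    perm <- sample(nrow(valid))
    expect_equal(predict(fit1, valid[perm, ]), s1[perm])
  }
})

test_that("separable data yield perfect training discrimination; LR equals its own logistic form", {
  tab <- toy_table(n1 = 30, n0 = 30, sep = 8, seed = 12)
  rf <- ultrasomics_fit(tab, "rf", smote = FALSE, seed = 2)
  expect_equal(auc(rf$train_scores, tab$label)$auc, 1)
  lr <- suppressWarnings(ultrasomics_fit(tab, "lr", smote = FALSE, seed = 2))
  Z <- rgbomics:::standardize_apply(feature_matrix(tab), lr$std)[, lr$features, drop = FALSE]
  eta <- coef(lr)[1] + as.numeric(Z %*% coef(lr)[-1])
  expect_equal(predict(lr, tab), unname(plogis(eta)), tolerance = 1e-8)
})

test_that("degenerate inputs raise informative modeling errors", {
  tab <- toy_table(n1 = 20, n0 = 10)
  one_class <- tab[tab$label == 1, ]
  expect_error(ultrasomics_fit(one_class, "rf", seed = 1), "both classes")
  fit <- ultrasomics_fit(tab, "rf", seed = 1)
  crippled <- tab[, setdiff(colnames(tab), fit$features[1])]
  expect_error(predict(fit, crippled), "lacks model features")
})
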