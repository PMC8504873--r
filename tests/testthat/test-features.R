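test_that("equal-width discretization covers edge cases and the exact ramp counts", {
  expect_equal(discretize(rep(7, 10), 8), rep(1L, 10))
  expect_setequal(discretize(c(0, 255), 2), c(1L, 2L))
  ramp <- 0:255
  counts <- tabulate(discretize(ramp, 32), 32)
  expect_true(all(abs(counts - 8) <= 1))
  expect_equal(sum(counts), 256)
  expect_error(discretize(numeric(0), 8), "empty")
  expect_error(discretize(1:5, 1), "2 bins")
})

test_that("first-order features match their defining formulas", {
  const <- first_order(rep(42, 50))
  expect_equal(unname(const[c("mean", "variance", "entropy", "sd", "range")]),
               c(42, 0, 0, 0, 0))
  two <- first_order(rep(c(0, 255), 20))
  expect_equal(unname(two["mean"]), 127.5)
  expect_equal(unname(two["entropy"]), 1)   # one bit
  # hand computation of the moment formulas on a fixed 10-value sample
  x <- c(3, 7, 7, 2, 9, 14, 5, 5, 1, 12)
  mu <- mean(x); m2 <- mean((x - mu)^2)
  v <- first_order(x)
  expect_equal(unname(v["skewness"]), mean((x - mu)^3) / m2^1.5)
  expect_equal(unname(v["kurtosis"]), mean((x - mu)^4) / m2^2)
  expect_equal(unname(v["energy"]), sum(x^2))
  expect_equal(unname(v["rms"]), sqrt(mean(x^2)))
  expect_equal(unname(v["p10"]), unname(quantile(x, 0.1)))
  expect_length(v, 19)
})

test_that("GLCM handles the constant and checkerboard anchor cases", {
  m <- matrix(1L, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  v <- glcm_features(m, mask, bins = 8)
  expect_equal(unname(v[c("contrast", "max_probability", "entropy")]), c(0, 1, 0))
  # 2x2 checkerboard, horizontal offset only: zero diagonal, contrast 1
  cb <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  P <- rgbomics:::glcm_matrix(cb, matrix(TRUE, 2, 2), 2L, c(0L, 1L))
  expect_equal(sum(P), 1)
  expect_equal(unname(diag(P)), c(0, 0))
  expect_equal(sum(P * (row(P) - col(P))^2), 1)
  expect_error(glcm_features(m, matrix(c(TRUE, rep(FALSE, 15)), 4, 4)), "< 2")
})

test_that("GLCM features equal brute-force pair enumeration on random images", {
  set.seed(7)
  for (i in 1:6) {
    h <- sample(5:16, 1); w <- sample(5:16, 1)
    labels <- matrix(sample.int(6, h * w, replace = TRUE), h, w)
    mask <- matrix(runif(h * w) < 0.8, h, w)
    if (sum(mask) < 4) next
    expect_equal(glcm_features(labels, mask, bins = 6),
                 brute_glcm_features(labels, mask, 6))
    expect_equal(glcm_features(labels, mask, bins = 6, distance = 2),
                 brute_glcm_features(labels, mask, 6, distance = 2))
  }
})

test_that("GLRLM anchors: single runs, alternating runs, pixel conservation", {
  mask_row <- matrix(c(rep(TRUE, 7), rep(FALSE, 7)), 2, 7, byrow = TRUE)
  const <- matrix(1L, 2, 7)
  v <- glrlm_features(const, mask_row, bins = 4)
  # along (0,1): one run of length 7 -> LRE 49; the brute oracle agrees
  expect_equal(v, brute_glrlm_features(const, mask_row, 4))
  runs_h <- brute_runs(const, mask_row, c(0, 1))
  expect_equal(nrow(runs_h), 1)
  expect_equal(sum(runs_h[, "len"]^2) / nrow(runs_h), 49)
  alt <- matrix(rep(c(1L, 2L), 7), 2, 7, byrow = TRUE)  # alternating rows
  alt_mask <- matrix(TRUE, 2, 7)
  runs_alt <- brute_runs(alt, alt_mask, c(0, 1))
  expect_true(all(runs_alt[, "len"] == 1))
  expect_equal(nrow(runs_alt) / sum(alt_mask), 1)    # run percentage 1
  # conservation in every direction
  for (dir in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    runs <- brute_runs(alt, alt_mask, dir)
    expect_equal(sum(runs[, "len"]), sum(alt_mask))
  }
})

test_that("GLRLM features equal brute-force run walking on random images", {
  set.seed(19)
  for (i in 1:6) {
    h <- sample(5:16, 1); w <- sample(5:16, 1)
    labels <- matrix(sample.int(4, h * w, replace = TRUE), h, w)
    mask <- matrix(runif(h * w) < 0.75, h, w)
    if (sum(mask) < 4) next
    expect_equal(glrlm_features(labels, mask, bins = 4),
                 brute_glrlm_features(labels, mask, 4))
  }
})

test_that("shape features of a square match hand values", {
  mask <- matrix(FALSE, 14, 14); mask[3:12, 3:12] <- TRUE
  s <- shape_features(mask)
  expect_equal(unname(s["area"]), 100)
  expect_equal(unname(s["perimeter"]), 40)
  expect_equal(unname(s["circularity"]), 4 * pi * 100 / 1600)
  expect_equal(unname(s["axis_ratio"]), 1)
})

test_that("filter bank behaves on constants: LoG and wavelet details vanish", {
  m <- matrix(5, 16, 16)
  expect_true(all(abs(rgbomics:::log_filter(m, 2)) < 1e-12))
  sw <- rgbomics:::swt_haar(m, 2)
  expect_equal(sw$wavL1LL, m)
  expect_true(all(abs(sw$wavL1HH) < 1e-12))
  expect_true(all(abs(sw$wavL2LH) < 1e-12))
})

test_that("bank size is a pure function of the configuration", {
  expect_equal(bank_size(tiny_bank()), 34)
  expect_equal(bank_size(tiny_bank(families = "first_order")), 19)
  b2 <- feature_bank(filters = list(original = TRUE, log_sigmas = 2,
                                    wavelet_levels = 1L),
                     bins = c(16L, 32L))
  expect_equal(bank_size(b2), 6 * 2 * 34)
  expect_error(feature_bank(bins = 4L), ">= 8")
})

test_that("direct and three-channel extraction obey the multiplicity law", {
  set.seed(23)
  img <- random_color_image(24, 24)
  mask <- matrix(FALSE, 24, 24); mask[6:18, 6:18] <- TRUE
  bank <- tiny_bank()
  vd <- extract_direct(img, mask, bank)
  vr <- extract_rgb3(img, mask, bank)
  expect_length(vd, bank_size(bank))
  expect_length(vr, 3 * bank_size(bank))
  expect_true(all(startsWith(names(vd), "gray_")))
  expect_setequal(unique(sub("_.*", "", names(vr))), c("R", "G", "B"))
  # determinism to the last bit
  expect_identical(vd, extract_direct(img, mask, bank))
  expect_identical(vr, extract_rgb3(img, mask, bank))
  # shape features are emitted once and excluded from the law
  bs <- tiny_bank(shape = TRUE)
  expect_length(extract_direct(img, mask, bs), 34 + 4)
  expect_length(extract_rgb3(img, mask, bs), 3 * 34 + 4)
})

test_that("achromatic images give equal features in all channels; metamers differ in R only", {
  set.seed(31)
  img <- random_color_image(16, 16)
  img[, , 2] <- img[, , 1]; img[, , 3] <- img[, , 1]
  mask <- matrix(TRUE, 16, 16)
  bank <- tiny_bank()
  vd <- extract_direct(img, mask, bank)
  vr <- extract_rgb3(img, mask, bank)
  strip <- function(v) {x <- unname(v); x}
  expect_equal(strip(vr[startsWith(names(vr), "R_")]), strip(vd))
  expect_equal(strip(vr[startsWith(names(vr), "G_")]),
               strip(vr[startsWith(names(vr), "B_")]))
  # constant-color metamer pair: identical gray mean, different R mean
  p <- array(rep(c(50L, 0L, 0L), each = 64), dim = c(8, 8, 3))
  q <- array(rep(c(0L, 0L, 147L), each = 64), dim = c(8, 8, 3))
  fo <- tiny_bank(families = "first_order")
  small_mask <- matrix(TRUE, 8, 8)
  gp <- extract_direct(p, small_mask, fo); gq <- extract_direct(q, small_mask, fo)
  expect_lt(abs(gp[["gray_original_first_order_mean_b16"]] -
                gq[["gray_original_first_order_mean_b16"]]), 0.02)
  rp <- extract_rgb3(p, small_mask, fo); rq <- extract_rgb3(q, small_mask, fo)
  expect_equal(rp[["R_original_first_order_mean_b16"]] -
               rq[["R_original_first_order_mean_b16"]], 50)
})

test_that("cohort extraction assembles a consistent feature table and CSV round-trips", {
  co <- generate_cohort(swe_config(height = 48, width = 48,
                                   axis_range = c(6, 12)), 2, 3, seed = 4)
  ft <- extract_cohort(co, tiny_bank(), "direct")
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 5)
  expect_equal(sum(ft$label), 3)
  expect_false(anyNA(feature_matrix(ft)))
  f <- tempfile(fileext = ".csv")
  write_feature_table(ft, f)
  back <- read_feature_table(f)
  expect_equal(feature_matrix(back), feature_matrix(ft), tolerance = 1e-12)
  expect_equal(back$label, ft$label)
})
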