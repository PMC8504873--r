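# Independent brute-force oracles and small fixture builders. These
# deliberately use the slowest, most literal formulation of each definition
# so they share no code path with the package implementation.

random_color_image <- function(h = 16, w = 16) {
  a <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  storage.mode(a) <- "integer"
  a
}

# AUC as the fraction of concordant (event, non-event) pairs, ties 1/2.
pair_count_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  tot / (length(x) * length(y))
}

# Brute-force symmetric GLCM by explicit pixel-pair enumeration.
brute_glcm_matrix <- function(labels, mask, bins, offset) {
  P <- matrix(0, bins, bins)
  n <- nrow(labels); p <- ncol(labels)
  for (r in seq_len(n)) for (cl in seq_len(p)) {
    r2 <- r + offset[1]; c2 <- cl + offset[2]
    if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= p && mask[r, cl] && mask[r2, c2]) {
      i <- labels[r, cl]; j <- labels[r2, c2]
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

brute_glcm_features <- function(labels, mask, bins, distance = 1) {
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  offsets <- lapply(offsets, function(o) o * distance)
  stats <- list()
  for (off in offsets) {
    P <- brute_glcm_matrix(labels, mask, bins, off)
    if (is.null(P)) next
    i_of <- row(P); j_of <- col(P)
    mu_i <- sum(i_of * P); mu_j <- sum(j_of * P)
    s_i <- sqrt(sum((i_of - mu_i)^2 * P)); s_j <- sqrt(sum((j_of - mu_j)^2 * P))
    pos <- P[P > 0]
    stats[[length(stats) + 1]] <- c(
      contrast = sum(P * (i_of - j_of)^2),
      dissimilarity = sum(P * abs(i_of - j_of)),
      homogeneity = sum(P / (1 + (i_of - j_of)^2)),
      asm = sum(P^2),
      energy = sqrt(sum(P^2)),
      entropy = -sum(pos * log2(pos)),
      correlation = if (s_i > 0 && s_j > 0)
        sum((i_of - mu_i) * (j_of - mu_j) * P) / (s_i * s_j) else 1,
      cluster_shade = sum(P * (i_of + j_of - mu_i - mu_j)^3),
      cluster_prominence = sum(P * (i_of + j_of - mu_i - mu_j)^4),
      max_probability = max(P))
  }
  Reduce(`+`, stats) / length(stats)
}

# Brute-force run collection: walk every maximal run along a direction.
brute_runs <- function(labels, mask, dir) {
  n <- nrow(labels); p <- ncol(labels)
  inside <- function(r, cl) r >= 1 && r <= n && cl >= 1 && cl <= p && mask[r, cl]
  runs <- list()
  for (r in seq_len(n)) for (cl in seq_len(p)) {
    if (!inside(r, cl)) next
    pr <- r - dir[1]; pc <- cl - dir[2]
    # only start a run at a pixel whose predecessor does not continue it
    if (inside(pr, pc) && labels[pr, pc] == labels[r, cl]) next
    len <- 1; rr <- r + dir[1]; cc <- cl + dir[2]
    while (inside(rr, cc) && labels[rr, cc] == labels[r, cl]) {
      len <- len + 1; rr <- rr + dir[1]; cc <- cc + dir[2]
    }
    runs[[length(runs) + 1]] <- c(gray = labels[r, cl], len = len)
  }
  do.call(rbind, runs)
}

brute_glrlm_features <- function(labels, mask, bins) {
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  acc <- NULL
  npix <- sum(mask)
  for (dir in dirs) {
    runs <- brute_runs(labels, mask, dir)
    g <- runs[, "gray"]; l <- runs[, "len"]
    N <- nrow(runs)
    st <- c(sre = sum(1 / l^2) / N,
            lre = sum(l^2) / N,
            gln = sum(table(g)^2) / N,
            rln = sum(table(l)^2) / N,
            run_percentage = N / npix)
    acc <- if (is.null(acc)) st else acc + st
  }
  acc / length(dirs)
}

# Scalar even-odd point-in-polygon test (literal ray-casting definition).
brute_point_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

brute_polygon_mask <- function(vertices, height, width) {
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height)) for (cl in seq_len(width))
    m[r, cl] <- brute_point_in_polygon(r - 0.5, cl - 0.5,
                                       vertices[, 1], vertices[, 2])
  m
}

# Make every pixel achromatic (R = G = B) by copying the R channel.
achromatize <- function(cohort) {
  for (i in seq_along(cohort)) {
    img <- cohort[[i]]$image
    img[, , 2] <- img[, , 1]
    img[, , 3] <- img[, , 1]
    cohort[[i]]$image <- img
  }
  cohort
}

# Small all-families bank on the unfiltered image only (fast in tests).
tiny_bank <- function(families = c("first_order", "glcm", "glrlm"), bins = 16L,
                      shape = FALSE) {
  feature_bank(filters = list(original = TRUE, log_sigmas = numeric(0),
                              wavelet_levels = 0L),
               families = families, bins = bins, shape = shape)
}
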