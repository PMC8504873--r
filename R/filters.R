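# Image filter bank: separable Gaussian smoothing, Laplacian-of-Gaussian,
# and an undecimated (a-trous) Haar wavelet transform. Subbands keep the
# original image size, so one ROI mask applies to every derivative image.

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D convolution with edge replication. kr filters along rows
# (vertical), kc along columns (horizontal); kernels must have odd length.
sep_convolve <- function(m, kr, kc) {
  conv_rows <- function(m, k) {
    half <- (length(k) - 1L) / 2L
    if (half == 0L) return(m * k)
    n <- nrow(m)
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      out <- out + k[j] * m[idx(seq_len(n) + off), , drop = FALSE]
    }
    out
  }
  m <- conv_rows(m, kr)
  t(conv_rows(t(m), kc))
}

gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel_1d(sigma)
  sep_convolve(m, k, k)
}

# Laplacian of Gaussian: blur then 5-point discrete Laplacian.
log_filter <- function(m, sigma) {
  s <- gaussian_blur(m, sigma)
  n <- nrow(s); p <- ncol(s)
  up <- s[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
  dn <- s[pmin(seq_len(n) + 1L, n), , drop = FALSE]
  lf <- s[, pmax(seq_len(p) - 1L, 1L), drop = FALSE]
  rt <- s[, pmin(seq_len(p) + 1L, p), drop = FALSE]
  up + dn + lf + rt - 4 * s
}

# One level of the a-trous (stationary) Haar transform at dilation `step`.
# Returns LL, LH, HL, HH subbands, all at full image size. Edge replication.
swt_haar_level <- function(m, step) {
  n <- nrow(m); p <- ncol(m)
  ri <- pmin(seq_len(n) + step, n)
  ci <- pmin(seq_len(p) + step, p)
  lo_r <- (m + m[ri, , drop = FALSE]) / 2
  hi_r <- (m - m[ri, , drop = FALSE]) / 2
  list(LL = (lo_r + lo_r[, ci, drop = FALSE]) / 2,
       LH = (lo_r - lo_r[, ci, drop = FALSE]) / 2,
       HL = (hi_r + hi_r[, ci, drop = FALSE]) / 2,
       HH = (hi_r - hi_r[, ci, drop = FALSE]) / 2)
}

# Full stationary Haar decomposition: named list wavL{j}{LL,LH,HL,HH}.
swt_haar <- function(m, levels) {
  out <- list()
  approx <- m
  for (j in seq_len(levels)) {
    sb <- swt_haar_level(approx, step = 2L^(j - 1L))
    for (nm in names(sb)) out[[sprintf("wavL%d%s", j, nm)]] <- sb[[nm]]
    approx <- sb$LL
  }
  out
}

# Compute the named derivative images requested by a feature bank for one
# grayscale channel. `filters` is a bank$filters list.
derive_images <- function(m, filters) {
  out <- list()
  if (isTRUE(filters$original)) out$original <- m
  for (s in filters$log_sigmas)
    out[[sprintf("logsig%g", s)]] <- log_filter(m, s)
  if (length(filters$wavelet_levels) == 1L && filters$wavelet_levels > 0)
    out <- c(out, swt_haar(m, filters$wavelet_levels))
  out
}
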