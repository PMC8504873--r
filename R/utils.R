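# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no isolation).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seeds for pipeline stages, all < 2^31.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  stages <- c(cohort = 11L, split = 23L, smote = 37L, lasso = 53L,
              classifier = 71L, calibration = 89L, noise = 101L)
  off <- stages[[stage]]
  as.integer((as.double(master) * 7919 + off) %% 2147483647)
}

# Round half away from zero (half-up for non-negative input), as used when
# quantizing real intensities to 8-bit.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary01 <- function(x) all(x %in% c(0, 1))

# Labels are carried as integer 0 (benign) / 1 (malignant).
as_label01 <- function(label) {
  if (is.factor(label) || is.character(label)) {
    lv <- as.character(label)
    bad <- setdiff(unique(lv), c("benign", "malignant", "0", "1"))
    if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
    return(ifelse(lv %in% c("malignant", "1"), 1L, 0L))
  }
  if (!is_binary01(label)) stop("labels must be 0/1 or benign/malignant")
  as.integer(label)
}
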