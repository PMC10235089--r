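# Internal helpers shared across modules.

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards so
# seeded generators do not disturb the global RNG stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# mean/sd/min/max of a numeric vector with the empty-group fill convention:
# no observations -> all four statistics are 0; one observation -> sd 0.
stat4 <- function(x) {
  if (length(x) == 0L) return(c(mean = 0, sd = 0, min = 0, max = 0))
  s <- stats::sd(x)
  c(mean = mean(x), sd = if (is.na(s)) 0 else s, min = min(x), max = max(x))
}

# mean/sd/max variant used for the neighbor color family.
stat3 <- function(x) {
  if (length(x) == 0L) return(c(mean = 0, sd = 0, max = 0))
  s <- stats::sd(x)
  c(mean = mean(x), sd = if (is.na(s)) 0 else s, max = max(x))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Adjusted (sample) skewness G1; needs n >= 3 and positive variance.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(NA_real_)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Adjusted (sample) excess kurtosis G2; needs n >= 4 and positive variance.
sample_kurtosis <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(NA_real_)
  g2 <- mean((x - mean(x))^4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

# Deterministic derived seed kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %%
               2147483587)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
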