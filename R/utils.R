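# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed derived from a study seed and a stream label,
# so per-network / per-stage RNG streams are independent of processing order.
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, collapse = "/"))
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# z-score a vector; zero-variance vectors map to all zeros (flagged upstream).
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# Shannon entropy (nats) of a nonnegative count/weight vector or matrix.
shannon_entropy <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

clamp01 <- function(x) pmin(1, pmax(0, x))
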