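# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit hash of (seed, key). Used to derive per-image RNG
# streams so cohorts are reproducible regardless of rendering order.
# Arithmetic stays below 2^53 so doubles are exact; result < 2^31.
ca_hash32 <- function(seed, key) {
  mod <- 2147483647
  vapply(as.character(key), function(k) {
    h <- (abs(as.numeric(seed)) + 11) %% mod
    for (b in utf8ToInt(k)) h <- (h * 69069 + b) %% mod
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
ca_with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

ca_stop <- function(...) stop(sprintf(...), call. = FALSE)

ca_check_cols <- function(data, cols, where = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    ca_stop("%s is missing required column(s): %s", where,
            paste(missing, collapse = ", "))
  invisible(TRUE)
}

# softmax draw over columns of a score matrix (rows = observations)
ca_sample_softmax <- function(scores, levels) {
  p <- exp(scores - apply(scores, 1, max))
  p <- p / rowSums(p)
  u <- runif(nrow(p))
  cum <- t(apply(p, 1, cumsum))
  idx <- apply(cum >= u, 1, which.max)
  factor(levels[idx], levels = levels)
}

ca_is_binary <- function(x) {
  ux <- unique(x[!is.na(x)])
  length(ux) <= 2
}
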