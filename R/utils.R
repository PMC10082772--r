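# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded sub-computations never perturb an outer stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit sub-seed derivation (splitmix-style integer hash).
derive_seed <- function(seed, ...) {
  x <- as.double(seed)
  for (k in c(...)) {
    x <- (x * 69069 + as.double(k) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(x %% 2147483629L + 1L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-away-from-zero to 8-bit after clipping to [0, 1]
to_uint8 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  floor(x * 255 + 0.5)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
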