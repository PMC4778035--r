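## Internal helpers: seeded evaluation and a small stable hash for plan stamps.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a root seed and a stream label; keeps independent
# stages on independent, reproducible streams. Result stays below 2^31.
deriveSeed <- function(seed, ...) {
  h <- fnv1a(paste(c(seed, ...), collapse = "|"))
  as.integer(h %% 2147483544) + 1L
}

# Polynomial rolling hash of a string, returned as a double < 2^31.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

# Short hexadecimal stamp for a plan-like R object.
planHash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, vec.len = 1e6, digits.d = 15)),
             collapse = "\n")
  sprintf("%08x", fnv1a(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
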