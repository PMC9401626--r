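# Internal helpers.

# Evaluate expr with a private RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 64-bit hash of a character scalar, returned as 16 hex digits.
# Used to stamp pipeline outputs with a config fingerprint (no external
# digest dependency). Arithmetic is done on two 32-bit halves in doubles.
fnv1a64 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  # 64-bit constants split into hi/lo 16-bit limbs for exact arithmetic
  h <- c(0xcbf2, 0x9ce4, 0x8422, 0x2325)  # offset basis, 4 x 16-bit limbs
  p <- c(0x0000, 0x0100, 0x0000, 0x01b3)  # FNV prime 0x100000001b3
  mul64 <- function(a, b) {
    r <- numeric(4)
    for (i in 4:1) {
      for (j in 4:1) {
        k <- i + j - 4L
        if (k >= 1L) r[k] <- r[k] + a[i] * b[j]
      }
    }
    for (k in 4:2) {   # carry propagate, drop overflow beyond 64 bits
      carry <- floor(r[k] / 65536)
      r[k] <- r[k] %% 65536
      r[k - 1L] <- r[k - 1L] + carry
    }
    r[1] <- r[1] %% 65536
    r
  }
  for (b in bytes) {
    h[4] <- bitwXor(as.integer(h[4]), b)
    h <- mul64(h, p)
  }
  paste0(sprintf("%04x", h), collapse = "")
}

# Stable canonical JSON of an R config list (sorted names) for hashing.
canonicalJson <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  as.character(jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = NA))
}
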