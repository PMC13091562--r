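# Internal helpers: deterministic seed derivation and scoped RNG use.

# 32-bit unsigned arithmetic on doubles (R integers are signed 32-bit).
.mod32 <- 2^32

.mul32 <- function(a, b) {
  ah <- a %/% 65536
  al <- a %% 65536
  (((ah * b) %% 65536) * 65536 + al * b) %% .mod32
}

.xor32 <- function(a, b) {
  ah <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  al <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  ah * 65536 + al
}

.shr32 <- function(a, n) a %/% 2^n

# Murmur3-style integer finalizer: avalanche mixing of a 32-bit word.
.mix32 <- function(x) {
  x <- x %% .mod32
  x <- .xor32(x, .shr32(x, 16))
  x <- .mul32(x, 0x85EBCA6B)
  x <- .xor32(x, .shr32(x, 13))
  x <- .mul32(x, 0xC2B2AE35)
  .xor32(x, .shr32(x, 16))
}

#' Derive a child seed from a master seed and an index
#'
#' Splitmix-style integer hashing of (seed, index). The derivation is
#' order-independent: animal k gets the same child seed regardless of how
#' many other animals are simulated, which keeps cohorts reproducible under
#' subsetting.
#'
#' @param seed Master seed (non-negative integer).
#' @param index Child index (non-negative integer).
#' @return An integer seed in [1, 2^31 - 1].
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), seed >= 0, index >= 0)
  h <- .mix32((.mix32(seed) + .mul32(index %% .mod32, 0x9E3779B9)) %% .mod32)
  out <- h %% (2^31 - 2) + 1
  as.integer(out)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards. `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Index of the trace sample nearest to `target`; ties go to the earlier sample.
nearest_index <- function(times, target) {
  d <- abs(times - target)
  idx <- which(d == min(d))
  idx[1L]
}
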