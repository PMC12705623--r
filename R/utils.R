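#' @keywords internal
"_PACKAGE"

# Run expr with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is restored afterwards so library code never perturbs user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, in double arithmetic
# (exact below 2^53). Deterministic across platforms; used for fingerprint
# and k-mer bucket hashing.
fnv1a <- function(s, salt = 0L) {
  h <- (2166136261 + as.double(salt)) %% 4294967296
  for (b in utf8ToInt(s)) {
    low <- h %% 256                      # xor with a byte only touches low 8 bits
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # h * 16777619 mod 2^32 in split arithmetic (the direct product exceeds 2^53)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  h
}

# Vectorized bucket hash: strings -> integer buckets in 1..nbuckets.
hash_bucket <- function(strings, nbuckets, salt = 0L) {
  vapply(strings, function(s) as.integer(fnv1a(s, salt) %% nbuckets) + 1L,
         integer(1), USE.NAMES = FALSE)
}

# Population standard deviation (1/n denominator).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Sum rows of `x` by integer group in 1..n, returning an n x ncol(x) matrix
# with zero rows for empty groups.
segment_sum <- function(x, group, n) {
  x <- as.matrix(x)
  out <- matrix(0, n, ncol(x))
  s <- rowsum(x, group)
  out[as.integer(rownames(s)), ] <- s
  out
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
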