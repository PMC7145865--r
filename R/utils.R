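# Internal helpers shared across modules.

# Deterministic child-seed derivation: every stochastic stage draws its own
# seed from (master seed, stream id) so stages can be rerun in isolation.
# Values stay inside [1, 2^31 - 2] (R seeds are 32-bit integers).
childSeed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 69621 + as.double(stream) * 10007 + 12345
  as.integer(s %% 2147483646 + 1)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (v - mean(v)) / s
}

# checksum for manifests: FNV-1a over a character scalar, reported as an
# integer so manifests stay plain JSON
.checksum <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  as.integer(h)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
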