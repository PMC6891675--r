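# Internal helpers: seeded substreams and small numeric utilities.

# Evaluate `fn()` under a fixed RNG seed without disturbing the caller's
# RNG state.
.withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit({
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  fn()
}

# Derive a named substream seed from a root seed. Substreams keep property
# draws, noise draws and shift draws independent of one another, so adding
# a band or property does not perturb unrelated draws. The result stays
# well below 2^31 (R integer range).
.subSeed <- function(root, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer(((root %% 1000003) * 1009 + h) %% 2147483647)
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
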