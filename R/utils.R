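# Internal helpers shared across modules.

# Canonical key for an AE term: trimmed, squeezed whitespace, lower case.
# Original casing is preserved everywhere a term is displayed.
norm_term <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

# Deterministic per-stream seed derivation. Stream 0 is reserved for the
# latent truth of a simulated drug; stream i >= 1 for the i-th trial's
# counts, so extending a simulation never perturbs earlier draws.
# Result always lies in [1, 2^31 - 2].
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(seed)) %% m) + 1
  vapply(stream, function(i) {
    as.integer((s * 1103515245 + (as.double(i) + 1) * 12345) %% (m - 1) + 1)
  }, integer(1))
}

# Evaluate an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Format a percent threshold compactly: 2 -> "2", 0.5 -> "0.5".
fmt_pct <- function(pct) {
  format(pct, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}
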