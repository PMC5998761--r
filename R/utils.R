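# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    abort("`seed` must be a single non-negative integer.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fixed fan-out from one user-level seed to per-stage seeds, so each stage is
# independently reproducible. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 999983 * as.numeric(stage)) %% 2147483647)
}

# Format doubles for text artifacts: 9 significant digits, locale-free.
format_num <- function(x) {
  formatC(x, digits = 9L, format = "g", mode = "double")
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
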