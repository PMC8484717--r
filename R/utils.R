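# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals. base::round() rounds half to
# even, which disagrees with the reporting convention used for database
# composition percentages (e.g. 9.51 -> 9.5, 83.25 -> 83.3 at 1 decimal).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 31-ary string hash folded with a seed, reduced mod 2^31 - 1.
# Used for reproducible, leakage-free fold assignment by spectrum id.
string_hash <- function(x, seed = 0L) {
  p <- 2147483647
  vapply(x, function(s) {
    h <- (seed %% p)
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% p
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
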