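# Internal helpers shared across modules.

# Deterministic substream seed: maps (root seed, stream name) to an integer
# in [0, 2^31). Named substreams keep the genotype, per-stage OTU and
# phenotype generators reproducible component by component.
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  m <- 2147480009 # prime below 2^31; all arithmetic stays inside 2^53
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 31 + k) %% m
  as.integer(((seed %% m) + h * 2654435) %% m)
}

# Evaluate expr with a local RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Smallest eigenvalue of a symmetric matrix (values only).
min_eigenvalue <- function(K) {
  min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
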