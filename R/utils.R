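# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the global stream. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed and an index, staying
# within the 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# Configuration/validation error with a dedicated condition class so the
# command-line wrapper can map it to exit code 2 (vs 1 for runtime errors).
stop_config <- function(...) {
  stop(structure(class = c("wptmix_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform integer draw from [lo, hi]; guards the base-R sample() pitfall
# where a degenerate range sample(seq(2, 2), 1) would draw from 1:2.
sample_range <- function(lo, hi) {
  if (lo == hi) return(as.integer(lo))
  sample(seq(lo, hi), 1L)
}
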