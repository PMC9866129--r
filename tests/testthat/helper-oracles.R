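# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately avoid the package's own convolution/downsampling code paths:
# everything here is written with explicit loops and base linear algebra.

# One analysis step by direct convolution: half-point symmetric extension,
# literal convolution sums, dyadic downsampling. Matches the filter-bank
# definition, not the package implementation (which uses FFT convolution).
slow_analysis_step <- function(x, g) {
  L <- length(g)
  n <- length(x)
  ext <- c(rev(x[seq_len(L - 1L)]), x, rev(x[seq(n - L + 2L, n)]))
  m <- length(ext) + L - 1L
  full <- numeric(m)
  for (k in seq_len(m)) {
    acc <- 0
    for (j in seq_len(L)) {
      i <- k - j + 1L
      if (i >= 1L && i <= length(ext)) acc <- acc + g[j] * ext[i]
    }
    full[k] <- acc
  }
  full[seq(L + 1L, by = 2L, length.out = (n + L - 1L) %/% 2L)]
}

# Multilevel low-pass decomposition oracle with amplitude rescale.
slow_decompose <- function(x, lo, level) {
  a <- x
  for (k in seq_len(level)) a <- slow_analysis_step(a, lo)
  a * 2^(-level / 2)
}

# Least-squares oracle by the normal equations.
normal_equations <- function(X, Y) {
  as.numeric(solve(crossprod(X), crossprod(X, Y)))
}

# Count local maxima above a relative threshold, by sign changes only.
brute_maxima_count <- function(y, rel_threshold) {
  thr <- rel_threshold * max(y)
  n <- length(y)
  sum(y[2:(n - 1L)] >= y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n] &
        y[2:(n - 1L)] >= thr)
}

# Reference three-site molecule: doublet, triplet and singlet, well apart.
ref_molecule <- function() {
  synthetic_molecule("ref", list(
    multiplet(2.0, 2L, J = 7, amplitude = 1.0),
    multiplet(5.0, 3L, J = 7, amplitude = 0.6),
    multiplet(8.0, 1L, amplitude = 0.8)))
}

# Small shared library + mixture fixture, built once per test run.
.fixture <- new.env(parent = emptyenv())

small_setup <- function() {
  if (is.null(.fixture$setup)) {
    gen <- generate_library(n_molecules = 12, seed = 42)
    lib <- build_library(gen$spectra)
    .fixture$setup <- list(gen = gen, lib = lib)
  }
  .fixture$setup
}
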