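# Wavelet engine: filter bank identities, transform oracles, level
# selection physics and shift-spectrum extraction.

test_that("the db9 filter bank satisfies the orthogonal wavelet identities", {
  f <- wptmix:::wavelet_filters("db9")
  expect_equal(sum(f$dec_lo), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(f$dec_lo^2), 1, tolerance = 1e-12)
  expect_equal(sum(f$dec_hi), 0, tolerance = 1e-12)
  expect_equal(sum(f$dec_lo * f$dec_hi), 0, tolerance = 1e-12)
  # double-shift orthogonality of the low-pass autocorrelation
  for (k in c(2, 4, 6)) {
    L <- f$length
    expect_equal(sum(f$dec_lo[seq_len(L - k)] * f$dec_lo[seq_len(L - k) + k]),
                 0, tolerance = 1e-12)
  }
  expect_error(wptmix:::wavelet_filters("haar"), "unknown wavelet",
               class = "wptmix_config_error")
})

test_that("one analysis step followed by synthesis reconstructs the signal", {
  set.seed(1)
  for (n in c(100, 255, 4096)) {
    x <- rnorm(n)
    st <- wpt_analyze_step(x)
    xr <- wpt_synthesize_step(st$a, st$d, n)
    expect_lt(max(abs(xr - x)), 1e-8)
  }
})

test_that("the decimated decomposition matches a direct-convolution oracle", {
  set.seed(7)
  x <- rnorm(4096)
  s <- nmr_spectrum(seq(0, 10, length.out = 4096), x)
  dec <- wpt_decompose(s, level = 3)
  oracle <- slow_decompose(x, wptmix:::DB9_DEC_LO, 3)
  expect_lt(max(abs(dec$approximation - oracle)), 1e-10)
})

test_that("a constant spectrum stays constant at any depth after rescaling", {
  s <- nmr_spectrum(seq(0, 10, length.out = 1024), rep(2.5, 1024))
  for (lv in c(1, 3, 5)) {
    dec <- wpt_decompose(s, level = lv)
    expect_equal(dec$approximation, rep(2.5, length(dec$approximation)),
                 tolerance = 1e-10)
  }
})

test_that("depth zero is the identity and excessive depth is rejected", {
  s <- simulate_molecule(ref_molecule(), n_points = 1024)
  dec <- wpt_decompose(s, level = 0)
  expect_equal(dec$approximation, s$intensities)
  expect_equal(dec$ppm_axis, s$shifts)
  expect_error(wpt_decompose(s, level = 20), "too deep",
               class = "wptmix_config_error")
})

test_that("the decimated ppm axis keeps a singlet at its true shift", {
  mol <- synthetic_molecule("s", multiplet(5, 1L))
  s <- simulate_molecule(mol, n_points = 8192)
  for (lv in c(2, 4)) {
    dec <- wpt_decompose(s, level = lv)
    apex <- dec$ppm_axis[which.max(dec$approximation)]
    dstep <- 2^lv * diff(s$shifts[1:2])
    expect_lt(abs(apex - 5), dstep)   # within one decimated grid step
  }
})

test_that("smoothed peak positions stay put across decomposition depths", {
  s <- simulate_molecule(ref_molecule(), n_points = 8192)
  dppm <- diff(s$shifts[1:2])
  for (lv in 1:6) {
    w <- wpt_spectrum(s, level = lv)
    apex <- w$shifts[which.max(w$intensities)]
    expect_lt(abs(apex - 2.0), max(0.01, 2^lv * dppm / 2))
  }
})

test_that("multiplet collapse halves the maxima count of an isolated doublet", {
  mol <- synthetic_molecule("d", multiplet(5, 2L, J = 7))
  s <- normalize_spectrum(simulate_molecule(mol, n_points = 8192), "max")
  lv <- as.integer(wpt_select_level(s))
  sm <- wptmix:::wpt_smooth(s$intensities, lv)
  sm_prev <- wptmix:::wpt_smooth(s$intensities, lv - 1L)
  expect_equal(brute_maxima_count(sm, 0.5), 1L)
  expect_equal(brute_maxima_count(sm_prev, 0.5), 2L)
})

test_that("a spectrum of pure singlets selects the shallowest depth", {
  mol <- synthetic_molecule("ss", list(multiplet(2, 1L), multiplet(7, 1L)))
  s <- normalize_spectrum(simulate_molecule(mol, n_points = 4096), "max")
  lv <- wpt_select_level(s)
  expect_equal(as.integer(lv), 1L)
  counts <- attr(lv, "counts")
  expect_true(all(counts == 2))
})

test_that("the selected depth reduces every multiplet to one shift peak", {
  for (n in c(4096, 8192, 16384)) {
    s <- normalize_spectrum(simulate_molecule(ref_molecule(), n_points = n),
                            "max")
    w <- wpt_spectrum(s)
    sh <- wpt_shift_spectrum(w)
    expect_equal(nrow(sh$peaks), 3)
    expect_equal(sh$peaks$ppm, c(2, 5, 8), tolerance = 0.01)
    # after smoothing, peak height tracks integrated multiplet area, so the
    # doublet (two full-height lines) towers over both other sites
    expect_equal(which.max(sh$peaks$height), 1L)
    expect_gt(sh$peaks$height[1], 1.5 * max(sh$peaks$height[2:3]))
  }
})

test_that("per-level maxima counts never increase for a noiseless multiplet input", {
  s <- normalize_spectrum(simulate_molecule(ref_molecule(), n_points = 8192),
                          "max")
  counts <- attr(wpt_select_level(s), "counts")
  expect_true(all(diff(counts) <= 0))
})

test_that("level selection rejects spectra without countable peaks", {
  flat <- nmr_spectrum(seq(0, 10, length.out = 1024), rep(0, 1024))
  expect_error(wpt_select_level(flat), "degenerate",
               class = "wptmix_config_error")
})

test_that("shift-invariant smoothing preserves a flat signal exactly", {
  y <- rep(1.7, 2048)
  for (lv in c(1, 4, 6))
    expect_equal(wptmix:::wpt_smooth(y, lv), y, tolerance = 1e-10)
})
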