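# Synthetic molecule, library and mixture generators.

test_that("multiplet lines follow the binomial intensity pattern and J spacing", {
  ln <- wptmix:::multiplet_lines(multiplet(4, 4L, J = 8, amplitude = 2), 500)
  expect_equal(ln$height / max(ln$height), choose(3, 0:3) / 3,
               tolerance = 1e-12)
  expect_equal(max(ln$height), 2)
  expect_equal(diff(ln$ppm), rep(8 / 500, 3), tolerance = 1e-12)
  expect_equal(mean(ln$ppm), 4, tolerance = 1e-12)   # centred on the shift
})

test_that("a simulated singlet equals the closed-form Lorentzian on the grid", {
  mol <- synthetic_molecule("s", multiplet(5, 1L, amplitude = 0.7,
                                           linewidth = 2))
  s <- simulate_molecule(mol, n_points = 2048)
  hw <- (2 / 500) / 2
  expect_equal(s$intensities,
               0.7 * hw^2 / ((s$shifts - 5)^2 + hw^2), tolerance = 1e-12)
})

test_that("noise is reproducible from its seed and scaled to the signal maximum", {
  mol <- ref_molecule()
  a <- simulate_molecule(mol, n_points = 1024, noise_sd = 0.01, seed = 3)
  b <- simulate_molecule(mol, n_points = 1024, noise_sd = 0.01, seed = 3)
  c <- simulate_molecule(mol, n_points = 1024, noise_sd = 0.01, seed = 4)
  clean <- simulate_molecule(mol, n_points = 1024)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
  resid <- a$intensities - clean$intensities
  expect_equal(sd(resid), 0.01 * max(clean$intensities), tolerance = 0.1)
})

test_that("lines extending outside the simulation window abort the simulation", {
  mol <- synthetic_molecule("edge", multiplet(9.99, 3L, J = 10))
  expect_error(simulate_molecule(mol), "outside the simulation window",
               class = "wptmix_config_error")
})

test_that("library generation is deterministic and honors its parameter ranges", {
  g1 <- generate_library(n_molecules = 6, seed = 9)
  g2 <- generate_library(n_molecules = 6, seed = 9)
  expect_identical(g1$spectra, g2$spectra)
  for (mol in g1$molecules) {
    k <- length(mol$multiplets)
    expect_true(k >= 2 && k <= 8)
    centers <- sort(vapply(mol$multiplets, `[[`, numeric(1), "center"))
    if (k > 1) expect_true(min(diff(centers)) >= 0.25)
    for (mp in mol$multiplets) {
      expect_true(mp$pattern >= 1 && mp$pattern <= 4)
      expect_true(mp$J >= 4 && mp$J <= 12)
    }
  }
  lens <- vapply(g1$spectra, length, numeric(1))
  expect_true(all(lens >= 4096 & lens <= 8192))
})

test_that("mixing renormalizes proportions and resamples onto the mean-length grid", {
  g <- generate_library(n_molecules = 3, seed = 5)
  mixed <- mix_spectra(g$spectra, c(2, 1, 1))
  expect_equal(mixed$meta$proportions, c(0.5, 0.25, 0.25))
  expect_length(mixed$shifts,
                as.integer(round(mean(vapply(g$spectra, length, numeric(1))))))
  # superposition: the mixture equals the weighted sum of the max-normalized
  # components interpolated on the common grid
  manual <- Reduce(`+`, lapply(seq_along(g$spectra), function(i) {
    s <- normalize_spectrum(g$spectra[[i]], "max")
    c(0.5, 0.25, 0.25)[i] *
      approx(s$shifts, s$intensities, xout = mixed$shifts,
             yleft = 0, yright = 0)$y
  }))
  expect_equal(mixed$intensities, manual, tolerance = 1e-12)
})

test_that("mixture manifests respect size and proportion constraints at scale", {
  mans <- wptmix:::sample_manifests(sprintf("m%02d", 1:20), 500,
                                    size_range = c(3, 7),
                                    proportion_range = c(0.15, 0.4), seed = 2)
  sizes <- vapply(mans, function(m) nrow(m$components), integer(1))
  expect_true(all(sizes >= 3 & sizes <= 7))
  expect_true(all(3:7 %in% sizes))   # every size occurs in 500 draws
  for (m in mans) {
    expect_equal(sum(m$components$proportion), 1, tolerance = 1e-12)
    expect_false(anyDuplicated(m$components$name) > 0)
  }
})

test_that("the augmented dataset restricts mixing to the subset and reproduces bit-for-bit", {
  g <- generate_library(n_molecules = 8, seed = 11)
  d1 <- generate_augmented_dataset(g$spectra, n_mixtures = 6,
                                   size_range = c(3, 4), subset = 5,
                                   noise_sd = 0.005, seed = 13)
  d2 <- generate_augmented_dataset(g$spectra, n_mixtures = 6,
                                   size_range = c(3, 4), subset = 5,
                                   noise_sd = 0.005, seed = 13)
  expect_identical(d1, d2)
  used <- unique(unlist(lapply(d1, function(it) it$manifest$components$name)))
  expect_true(all(used %in% names(g$spectra)[1:5]))
  expect_error(
    generate_augmented_dataset(g$spectra, n_mixtures = 2, subset = 9),
    "larger than the library", class = "wptmix_config_error")
})

test_that("dataset generation leaves the caller's random number stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_library(n_molecules = 3, seed = 7))
  expect_identical(.Random.seed, before)
})
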