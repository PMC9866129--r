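# Four-step mixture analysis: matching, design matrices, gradient descent
# and the staged prediction pipeline.

fake_library <- function(peaks_by_mol, domain = c(0, 10)) {
  records <- lapply(names(peaks_by_mol), function(nm) {
    pk <- peaks_by_mol[[nm]]
    list(name = nm,
         shift = structure(list(peaks = data.frame(ppm = pk,
                                                   height = rep(1, length(pk))),
                                source_level = 3L, molecule = nm),
                           class = "shift_spectrum"),
         level = 3L, domain = domain)
  })
  names(records) <- names(peaks_by_mol)
  structure(list(records = records, cfg = wpt_config(), version = "1.0"),
            class = "spectral_library")
}

fake_shift <- function(ppm, height = rep(1, length(ppm))) {
  structure(list(peaks = data.frame(ppm = ppm, height = height),
                 source_level = 3L, molecule = NULL),
            class = "shift_spectrum")
}

test_that("the matching probability is the matched fraction of a molecule's peaks", {
  lib <- fake_library(list(a = c(1.0, 2.0, 3.0),       # 2 of 3 match
                           b = c(1.005, 7.0),          # 1 of 2 match
                           c = c(5.0, 6.0)))           # 0 of 2 -> excluded
  li <- match_peaks(fake_shift(c(1.0, 2.01, 8.0)), lib, tol_ppm = 0.02)
  expect_equal(li$name, c("a", "b"))
  expect_equal(li$prob, c(2 / 3, 1 / 2))
  expect_identical(attr(li, "stage"), "LI")
})

test_that("shift-mode design matrices pick the nearest in-tolerance peak and zero outside the domain", {
  lib <- fake_library(list(a = c(2.0, 5.0), b = c(2.015, 9.0)),
                      domain = c(0, 10))
  lib$records$b$domain <- c(0, 6)   # 9.0 peak outside its own domain window
  mix <- fake_shift(c(2.0, 5.0, 9.0), height = c(1, 0.5, 0.3))
  dm <- build_design_matrix(mix, c("a", "b"), lib, mode = "shift",
                            tol_ppm = 0.02)
  expect_equal(dm$Y, c(1, 0.5, 0.3))
  expect_equal(dm$X[, "a"], c(1, 1, 0))         # no a-peak near 9.0
  expect_equal(dm$X[, "b"], c(1, 0, 0))         # 9.0 row zeroed by the domain
  expect_length(attr(dm, "zero_columns"), 0)
})

test_that("wpt-mode design matrices interpolate the library curves onto the mixture grid", {
  setup <- small_setup()
  lib <- setup$lib
  nm <- names(lib$records)[1:2]
  mixw <- lib$records[[nm[1]]]$wpt
  dm <- build_design_matrix(mixw, nm, lib, mode = "wpt")
  r2 <- lib$records[[nm[2]]]
  manual <- approx(r2$wpt$shifts, r2$wpt$intensities, xout = mixw$shifts,
                   yleft = 0, yright = 0)$y
  manual[mixw$shifts < r2$domain[1] | mixw$shifts > r2$domain[2]] <- 0
  expect_equal(dm$X[, 2], manual, tolerance = 1e-12)
  expect_equal(dm$Y, mixw$intensities)
})

test_that("unconstrained gradient descent converges to the least-squares solution", {
  set.seed(21)
  X <- matrix(runif(200 * 5, 0.1, 1), 200, 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  beta <- c(0.9, 0.1, 0.5, 0, 0.3)
  Y <- as.numeric(X %*% beta) + rnorm(200, sd = 0.01)
  dm <- structure(list(delta = seq_len(200), Y = Y, X = X,
                       candidates = colnames(X), mode = "shift"),
                  class = "design_matrix")
  th <- gradient_descent(dm, gd_config(alpha = 0.1, max_iter = 20000,
                                       tol = 1e-14, nonneg = FALSE))
  expect_lt(max(abs(as.numeric(th) - normal_equations(X, Y))), 1e-4)
  expect_true(attr(th, "converged"))
})

test_that("the non-negativity projection keeps all weights at or above zero", {
  set.seed(22)
  X <- matrix(runif(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y <- as.numeric(X %*% c(1, -0.5, 0.2))   # unconstrained optimum is negative
  dm <- structure(list(delta = seq_len(100), Y = Y, X = X,
                       candidates = colnames(X), mode = "shift"),
                  class = "design_matrix")
  th <- gradient_descent(dm, gd_config(alpha = 0.1, max_iter = 10000))
  expect_true(all(as.numeric(th) >= 0))
  expect_true(any(normal_equations(X, Y) < 0))
})

test_that("an excessive learning rate triggers the divergence guard", {
  set.seed(23)
  X <- matrix(runif(50 * 4), 50, 4, dimnames = list(NULL, paste0("c", 1:4)))
  Y <- runif(50)
  dm <- structure(list(delta = seq_len(50), Y = Y, X = X,
                       candidates = colnames(X), mode = "shift"),
                  class = "design_matrix")
  expect_error(gradient_descent(dm, gd_config(alpha = 500, nonneg = FALSE)),
               "diverged", class = "wptmix_config_error")
})

test_that("randomized learning rates are reproducible from the optimiser seed", {
  set.seed(24)
  X <- matrix(runif(80 * 4), 80, 4, dimnames = list(NULL, paste0("c", 1:4)))
  Y <- as.numeric(X %*% runif(4))
  dm <- structure(list(delta = seq_len(80), Y = Y, X = X,
                       candidates = colnames(X), mode = "wpt"),
                  class = "design_matrix")
  cfgA <- gd_config(alpha = c(0.01, 0.1), max_iter = 200, seed = 5)
  t1 <- gradient_descent(dm, cfgA)
  t2 <- gradient_descent(dm, cfgA)
  t3 <- gradient_descent(dm, gd_config(alpha = c(0.01, 0.1), max_iter = 200,
                                       seed = 6))
  expect_identical(t1, t2)
  expect_false(identical(as.numeric(t1), as.numeric(t3)))
})

test_that("each pipeline stage returns a subset of the previous stage", {
  setup <- small_setup()
  mix <- mix_spectra(setup$gen$spectra[c(1, 3, 5, 7)], c(1, 1, 1, 1))
  pred <- analyze_mixture(mix, setup$lib, seed = 2)
  expect_true(all(pred$LII$name %in% pred$LI$name))
  expect_true(all(pred$final$name %in% pred$LII$name))
  expect_lte(nrow(pred$final), 15)
})

test_that("a noiseless mixture's true components survive the elimination stage", {
  setup <- small_setup()
  truth <- names(setup$gen$spectra)[c(2, 4, 6)]
  mix <- mix_spectra(setup$gen$spectra[truth], c(0.5, 0.3, 0.2))
  pred <- analyze_mixture(mix, setup$lib, seed = 1)
  expect_true(all(truth %in% pred$LII$name))
  expect_true(all(truth %in% pred$LI$name))
})

test_that("fixed seeds make the full analysis bit-reproducible", {
  setup <- small_setup()
  mix <- mix_spectra(setup$gen$spectra[c(2, 5, 9)], c(1, 2, 1))
  p1 <- analyze_mixture(mix, setup$lib, seed = 77)
  p2 <- analyze_mixture(mix, setup$lib, seed = 77)
  expect_identical(p1, p2)
})

test_that("predictions serialize to JSON with all three candidate stages", {
  setup <- small_setup()
  mix <- mix_spectra(setup$gen$spectra[c(1, 2, 3)], c(1, 1, 1))
  pred <- analyze_mixture(mix, setup$lib, seed = 3)
  f <- tempfile(fileext = ".json")
  write_prediction(pred, f, mixture_id = "t")
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(js$level, pred$level)
  expect_equal(js$final$name, pred$final$name)
  expect_equal(js$LI$prob, pred$LI$prob, tolerance = 1e-12)
  unlink(f)
})
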