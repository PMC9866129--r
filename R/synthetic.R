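#' Describe one scalar-coupled multiplet
#'
#' First-order multiplets are modelled as `pattern` Lorentzian lines spaced
#' by the coupling constant `J` (converted to ppm with the spectrometer
#' frequency) with binomial relative intensities `choose(pattern - 1, i)`.
#'
#' @param center Chemical shift of the multiplet centre, ppm.
#' @param pattern Multiplicity: 1 = singlet, 2 = doublet, 3 = triplet, ...
#' @param J Scalar coupling constant in Hz; ignored for singlets.
#' @param amplitude Height of the tallest line, arbitrary units.
#' @param linewidth Full width at half maximum of each line, Hz.
#' @return A `multiplet` object.
#' @export
multiplet <- function(center, pattern = 1L, J = 7, amplitude = 1, linewidth = 1.5) {
  pattern <- as.integer(pattern)
  if (is.na(pattern) || pattern < 1L) stop_config("`pattern` must be >= 1")
  if (J < 0) stop_config("`J` must be >= 0")
  if (linewidth <= 0) stop_config("`linewidth` must be > 0")
  if (amplitude <= 0) stop_config("`amplitude` must be > 0")
  structure(list(center = center, pattern = pattern, J = J,
                 amplitude = amplitude, linewidth = linewidth),
            class = "multiplet")
}

#' Define a synthetic molecule as a set of multiplets
#'
#' @param name Molecule identifier.
#' @param multiplets List of [multiplet] objects (at least one).
#' @param field_mhz Spectrometer frequency in MHz used for the Hz-to-ppm
#'   conversion of couplings and linewidths.
#' @return A `synthetic_molecule` object.
#' @export
synthetic_molecule <- function(name, multiplets, field_mhz = 500) {
  if (inherits(multiplets, "multiplet")) multiplets <- list(multiplets)
  if (!length(multiplets)) stop_config("a molecule needs at least one multiplet")
  if (!all(vapply(multiplets, inherits, logical(1), "multiplet")))
    stop_config("`multiplets` must be a list of multiplet objects")
  structure(list(name = as.character(name), multiplets = multiplets,
                 field_mhz = field_mhz),
            class = "synthetic_molecule")
}

# Line positions (ppm) and heights for one multiplet at a given field.
multiplet_lines <- function(mp, field_mhz) {
  k <- mp$pattern
  rel <- choose(k - 1L, seq_len(k) - 1L)
  rel <- rel / max(rel)
  offs <- (seq_len(k) - (k + 1) / 2) * mp$J / field_mhz
  list(ppm = mp$center + offs, height = mp$amplitude * rel)
}

#' Simulate the 1H NMR spectrum of a synthetic molecule
#'
#' Sums Lorentzian lines for every multiplet on a uniform grid and optionally
#' adds Gaussian noise.
#'
#' @param mol A [synthetic_molecule].
#' @param n_points Grid length.
#' @param window ppm range `c(lo, hi)`; must contain all lines.
#' @param noise_sd Gaussian noise standard deviation, relative to the
#'   noise-free maximum intensity (0 disables noise).
#' @param seed Optional seed making the noise reproducible.
#' @return An [nmr_spectrum]; `meta` records the name and field strength.
#' @export
simulate_molecule <- function(mol, n_points = 4096, window = c(0, 10),
                              noise_sd = 0, seed = NULL) {
  stopifnot(inherits(mol, "synthetic_molecule"))
  grid <- seq(window[1L], window[2L], length.out = n_points)
  y <- numeric(n_points)
  for (mp in mol$multiplets) {
    ln <- multiplet_lines(mp, mol$field_mhz)
    ext <- range(ln$ppm)
    if (ext[1L] < window[1L] || ext[2L] > window[2L])
      stop_config("multiplet of '", mol$name, "' at ", mp$center,
                  " ppm extends outside the simulation window")
    hw <- (mp$linewidth / mol$field_mhz) / 2  # half width at half max, ppm
    for (i in seq_along(ln$ppm))
      y <- y + ln$height[i] * hw^2 / ((grid - ln$ppm[i])^2 + hw^2)
  }
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(n_points, sd = noise_sd * max(y)))
  }
  nmr_spectrum(grid, y, meta = list(name = mol$name, field_mhz = mol$field_mhz,
                                    noise_sd = noise_sd))
}

#' Generate a reproducible library of synthetic molecules and their spectra
#'
#' Draws, for each molecule, a number of multiplets, their centres (kept
#' apart by `min_separation` so that constructed lines remain resolvable),
#' multiplicities, couplings and amplitudes, then simulates each spectrum at
#' zero noise on its own uniform grid whose length is drawn from
#' `n_points_range` (so downstream mean-length resampling is exercised).
#'
#' @param n_molecules Number of molecules (>= 2).
#' @param seed Master seed; the same seed reproduces the library exactly.
#' @param n_multiplets_range Range of multiplets per molecule.
#' @param multiplicity_range Range of line multiplicities.
#' @param j_range Coupling-constant range, Hz.
#' @param amplitude_range Relative multiplet-height range.
#' @param linewidth Line full width at half maximum, Hz.
#' @param n_points_range Range of per-molecule grid lengths.
#' @param window Simulated ppm window.
#' @param centers_range ppm range in which multiplet centres are drawn
#'   (kept inside `window` with margin for splittings).
#' @param min_separation Minimum distance between multiplet centres within a
#'   molecule, ppm.
#' @param field_mhz Spectrometer frequency, MHz.
#' @return A list with `molecules` (list of [synthetic_molecule]) and
#'   `spectra` (named list of [nmr_spectrum]).
#' @export
generate_library <- function(n_molecules = 74, seed = 1,
                             n_multiplets_range = c(2, 8),
                             multiplicity_range = c(1, 4),
                             j_range = c(4, 12),
                             amplitude_range = c(0.3, 1),
                             linewidth = 1.5,
                             n_points_range = c(4096, 8192),
                             window = c(0, 10),
                             centers_range = c(0.3, 9.7),
                             min_separation = 0.25,
                             field_mhz = 500) {
  if (n_molecules < 2) stop_config("`n_molecules` must be >= 2")
  for (r in list(n_multiplets_range, multiplicity_range, j_range,
                 amplitude_range, n_points_range, centers_range))
    if (r[1L] > r[2L]) stop_config("degenerate parameter range: min > max")
  with_seed(seed, {
    molecules <- vector("list", n_molecules)
    spectra <- vector("list", n_molecules)
    names_v <- sprintf("mol%03d", seq_len(n_molecules))
    for (m in seq_len(n_molecules)) {
      k <- sample_range(n_multiplets_range[1L], n_multiplets_range[2L])
      centers <- draw_separated(k, centers_range, min_separation)
      mps <- lapply(seq_len(k), function(i) {
        multiplet(center = centers[i],
                  pattern = sample_range(multiplicity_range[1L],
                                         multiplicity_range[2L]),
                  J = stats::runif(1, j_range[1L], j_range[2L]),
                  amplitude = stats::runif(1, amplitude_range[1L],
                                           amplitude_range[2L]),
                  linewidth = linewidth)
      })
      mol <- synthetic_molecule(names_v[m], mps, field_mhz = field_mhz)
      n_pts <- sample_range(n_points_range[1L], n_points_range[2L])
      molecules[[m]] <- mol
      spectra[[m]] <- simulate_molecule(mol, n_points = n_pts, window = window,
                                        noise_sd = 0)
    }
    names(molecules) <- names_v
    names(spectra) <- names_v
    list(molecules = molecules, spectra = spectra)
  })
}

# Rejection-sample k centres keeping pairwise distance >= min_sep.
draw_separated <- function(k, rng, min_sep, max_tries = 10000L) {
  centers <- numeric(0)
  tries <- 0L
  while (length(centers) < k) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop_config("cannot place ", k, " multiplet centres ", min_sep,
                  " ppm apart in [", rng[1L], ", ", rng[2L], "]")
    cand <- stats::runif(1, rng[1L], rng[2L])
    if (!length(centers) || min(abs(centers - cand)) >= min_sep)
      centers <- c(centers, cand)
  }
  sort(centers)
}

#' Mix pure spectra into a synthetic mixture spectrum
#'
#' Each component is max-normalized, weighted by its (sum-normalized)
#' proportion, resampled onto a common uniform grid over the union of the
#' component ppm windows whose length is the rounded mean of the component
#' lengths, and summed.
#'
#' @param components List of [nmr_spectrum] (at least 2).
#' @param proportions Positive weights, one per component; normalized to sum
#'   to 1 internally.
#' @return The mixed [nmr_spectrum]; `meta$proportions` stores the
#'   normalized weights.
#' @export
mix_spectra <- function(components, proportions) {
  if (length(components) != length(proportions) || length(components) < 2L)
    stop_config("need >= 2 components with one proportion each")
  if (any(proportions <= 0)) stop_config("all proportions must be > 0")
  props <- proportions / sum(proportions)
  n_out <- as.integer(round(mean(vapply(components, length, numeric(1)))))
  lo <- min(vapply(components, function(s) s$shifts[1L], numeric(1)))
  hi <- max(vapply(components, function(s) s$shifts[length(s$shifts)], numeric(1)))
  grid <- seq(lo, hi, length.out = n_out)
  y <- numeric(n_out)
  for (i in seq_along(components)) {
    s <- normalize_spectrum(components[[i]], "max")
    yi <- stats::approx(s$shifts, s$intensities, xout = grid, yleft = 0,
                        yright = 0)$y
    y <- y + props[i] * yi
  }
  nmr_spectrum(grid, y,
               meta = list(proportions = props,
                           components = vapply(components, function(s)
                             s$meta$name %||% NA_character_, character(1))))
}

# Draw mixture manifests (component subsets + proportions) without
# simulating spectra; shared by generate_augmented_dataset and tests.
sample_manifests <- function(names_pool, n_mixtures, size_range = c(3, 7),
                             proportion_range = c(0.15, 0.4), seed = NULL) {
  if (size_range[2L] > length(names_pool))
    stop_config("largest mixture size exceeds the candidate pool (",
                length(names_pool), " molecules)")
  with_seed(seed, {
    lapply(seq_len(n_mixtures), function(i) {
      k <- sample_range(size_range[1L], size_range[2L])
      comp <- sample(names_pool, k)
      p <- stats::runif(k, proportion_range[1L], proportion_range[2L])
      p <- p / sum(p)
      list(mixture_id = sprintf("mix%04d", i),
           components = data.frame(name = comp, proportion = p,
                                   stringsAsFactors = FALSE))
    })
  })
}

#' Generate an augmented dataset of mixture spectra with ground truth
#'
#' Reproducibly draws `n_mixtures` manifests (mixture size uniform over
#' `size_range`, components sampled without replacement from `subset`,
#' proportions uniform over `proportion_range` then renormalized to sum to
#' 1), mixes the corresponding pure spectra with [mix_spectra], and adds
#' Gaussian noise relative to each mixed spectrum's maximum.
#'
#' @param spectra Named list of pure-molecule [nmr_spectrum] (the library
#'   input spectra).
#' @param n_mixtures Number of mixtures to generate.
#' @param size_range Inclusive range of mixture sizes.
#' @param proportion_range Range proportions are drawn from before
#'   renormalization.
#' @param subset Optional restriction of the mixing pool: a character vector
#'   of molecule names, or a single integer n meaning the first n molecules.
#'   Molecules outside the subset become known true negatives.
#' @param noise_sd Gaussian noise sd relative to each mixture's maximum.
#' @param seed Master seed; the full dataset is reproducible from it.
#' @return A list of `list(spectrum =, manifest =)` pairs; each manifest has
#'   `mixture_id`, `components` (name, proportion), `n_points` and `seed`.
#' @export
generate_augmented_dataset <- function(spectra, n_mixtures = 1000,
                                       size_range = c(3, 7),
                                       proportion_range = c(0.15, 0.4),
                                       subset = NULL, noise_sd = 0,
                                       seed = 1) {
  pool <- names(spectra)
  if (is.null(pool)) stop_config("`spectra` must be a named list")
  if (!is.null(subset)) {
    if (is.numeric(subset)) {
      if (subset > length(pool)) stop_config("subset larger than the library")
      pool <- pool[seq_len(subset)]
    } else {
      missing <- setdiff(subset, pool)
      if (length(missing))
        stop_config("subset names not in library: ",
                    paste(missing, collapse = ", "))
      pool <- subset
    }
  }
  manifests <- sample_manifests(pool, n_mixtures, size_range,
                                proportion_range, seed = seed)
  lapply(seq_along(manifests), function(i) {
    man <- manifests[[i]]
    comp <- man$components
    mixed <- mix_spectra(spectra[comp$name], comp$proportion)
    if (noise_sd > 0) {
      mixed$intensities <- with_seed(
        child_seed(seed, i),
        mixed$intensities +
          stats::rnorm(length(mixed$intensities),
                       sd = noise_sd * max(mixed$intensities)))
    }
    man$n_points <- length(mixed$shifts)
    man$seed <- seed
    mixed$meta$mixture_id <- man$mixture_id
    list(spectrum = mixed, manifest = man)
  })
}

#' Write a mixture manifest as JSON
#'
#' @param manifest A manifest from [generate_augmented_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(mixture_id = manifest$mixture_id,
         components = manifest$components,
         n_points = manifest$n_points %||% NA_integer_,
         seed = manifest$seed %||% NA_integer_),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
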