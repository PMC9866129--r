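# Scoring of composition predictions against ground-truth manifests and
# benchmark summaries (true/false positive rates by mixture size).

#' Score a predicted composition against the ground truth
#'
#' True positive rate = true assignments / actual composition size.
#' False positive rate = false assignments / (library size - true
#' assignments). Both are computed on name sets, so prediction order is
#' irrelevant.
#'
#' @param pred A `candidate_list` or character vector of predicted names.
#' @param truth A mixture manifest (from [generate_augmented_dataset]) or a
#'   character vector of true component names.
#' @param library_size Number of molecules in the library.
#' @return List with `tpr`, `fpr`, `n_true`, `n_false`, `mixture_size`.
#' @export
score_prediction <- function(pred, truth, library_size) {
  pred_names <- if (is.character(pred)) pred else pred$name
  truth_names <- if (is.character(truth)) truth else truth$components$name
  if (!length(truth_names)) stop_config("empty ground truth")
  if (library_size <= length(truth_names))
    stop_config("`library_size` must exceed the mixture size")
  tp <- length(intersect(pred_names, truth_names))
  fp <- length(setdiff(pred_names, truth_names))
  list(tpr = tp / length(truth_names),
       fpr = fp / (library_size - tp),
       n_true = tp, n_false = fp,
       mixture_size = length(truth_names))
}

#' Benchmark the analyzer over a dataset of mixtures with ground truth
#'
#' Runs [analyze_mixture] on every mixture, scores the candidate set both
#' after the elimination step (L II) and after the identification step
#' (final), and aggregates mean/median/sd of the true and false positive
#' rates overall and per mixture size.
#'
#' @param lib A `spectral_library`.
#' @param dataset List of `list(spectrum =, manifest =)` pairs, as produced
#'   by [generate_augmented_dataset].
#' @param tol_ppm Peak-matching tolerance.
#' @param seed Master seed; mixture `i` uses a per-mixture child seed for
#'   its step-4 learning-rate draws.
#' @return A `benchmark_summary`: `per_mixture` (data frame with stagewise
#'   tpr/fpr), `overall` and `by_size` aggregates per stage, `n_mixtures`,
#'   `n_failed`, `seed`.
#' @export
run_benchmark <- function(lib, dataset, tol_ppm = 0.02, seed = 1) {
  if (!length(dataset)) stop_config("empty dataset")
  lib_size <- length(lib$records)
  rows <- vector("list", length(dataset))
  failures <- character(0)
  for (i in seq_along(dataset)) {
    item <- dataset[[i]]
    res <- tryCatch(
      analyze_mixture(item$spectrum, lib, tol_ppm = tol_ppm,
                      seed = child_seed(seed, i)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(item$manifest$mixture_id, ": ",
                                     conditionMessage(res)))
      next
    }
    s2 <- score_prediction(res$LII, item$manifest, lib_size)
    s4 <- score_prediction(res$final, item$manifest, lib_size)
    rows[[i]] <- data.frame(
      mixture_id = item$manifest$mixture_id,
      mixture_size = s4$mixture_size,
      level = res$level,
      n_LI = nrow(res$LI), n_LII = nrow(res$LII), n_final = nrow(res$final),
      tpr_LII = s2$tpr, fpr_LII = s2$fpr,
      tpr_final = s4$tpr, fpr_final = s4$fpr,
      stringsAsFactors = FALSE)
  }
  per_mixture <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_mixture) || !nrow(per_mixture))
    stop_config("every mixture failed; first error: ", failures[1])
  agg <- function(df) list(
    tpr = stat_triple(df$tpr), fpr = stat_triple(df$fpr))
  stage_stats <- function(stage) {
    df <- data.frame(tpr = per_mixture[[paste0("tpr_", stage)]],
                     fpr = per_mixture[[paste0("fpr_", stage)]],
                     size = per_mixture$mixture_size)
    list(overall = agg(df),
         by_size = lapply(split(df, df$size), agg))
  }
  structure(list(per_mixture = per_mixture,
                 LII = stage_stats("LII"),
                 final = stage_stats("final"),
                 n_mixtures = length(dataset),
                 n_failed = length(failures),
                 failures = failures,
                 seed = seed, tol_ppm = tol_ppm),
            class = "benchmark_summary")
}

stat_triple <- function(x) list(mean = mean(x), median = stats::median(x),
                                sd = stats::sd(x))

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("<benchmark_summary> %d mixtures (%d failed)\n",
              x$n_mixtures, x$n_failed))
  fmt <- function(st) sprintf("tpr mean %.2f median %.2f sd %.2f | fpr mean %.2f median %.2f sd %.2f",
                              st$tpr$mean, st$tpr$median, st$tpr$sd,
                              st$fpr$mean, st$fpr$median, st$fpr$sd)
  cat("  after elimination (L II): ", fmt(x$LII$overall), "\n")
  cat("  final prediction:         ", fmt(x$final$overall), "\n")
  cat("  by mixture size (final):\n")
  for (sz in names(x$final$by_size))
    cat(sprintf("    %s molecules: %s\n", sz, fmt(x$final$by_size[[sz]])))
  invisible(x)
}

#' Write a benchmark summary as JSON
#'
#' Full-precision aggregates plus the per-mixture table.
#'
#' @param bm A `benchmark_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bm, path) {
  jsonlite::write_json(
    list(overall = list(LII = bm$LII$overall, final = bm$final$overall),
         by_size = list(LII = bm$LII$by_size, final = bm$final$by_size),
         n = bm$n_mixtures, n_failed = bm$n_failed, seed = bm$seed,
         tol_ppm = bm$tol_ppm, per_mixture = bm$per_mixture),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Direct raw-spectrum matching baseline
#'
#' Reference method: peak-pick the raw mixture spectrum and each molecule's
#' raw library spectrum with the same threshold machinery as the shift
#' spectra, then apply the [match_peaks] probability formula. No wavelet
#' processing is involved; used for before/after comparisons.
#'
#' @param mixture An [nmr_spectrum].
#' @param lib A `spectral_library`.
#' @param tol_ppm Matching tolerance, ppm.
#' @return A `candidate_list` (stage `"baseline"`) with the full ranked
#'   list; thresholding is left to the caller.
#' @export
baseline_direct_match <- function(mixture, lib, tol_ppm = 0.02) {
  stopifnot(inherits(mixture, "nmr_spectrum"),
            inherits(lib, "spectral_library"))
  thr <- lib$cfg$peak_threshold
  mix_pk <- find_peaks(mixture$shifts, mixture$intensities, thr)
  if (!nrow(mix_pk)) stop_config("no peaks in the mixture spectrum")
  probs <- vapply(lib$records, function(r) {
    mol_pk <- find_peaks(r$raw$shifts, r$raw$intensities, thr)
    if (!nrow(mol_pk)) return(0)
    p <- sum(vapply(mol_pk$ppm, function(q) any(abs(mix_pk$ppm - q) <= tol_ppm),
                    logical(1)))
    p / nrow(mol_pk)
  }, numeric(1))
  keep <- probs > 0
  candidate_list(names(probs)[keep], probs[keep], stage = "baseline")
}

#' Run the packaged benchmark protocol
#'
#' One call reproducing the study conditions end to end: generate a
#' 74-molecule synthetic library, compute its WPT shift library, draw
#' mixtures of 3-7 molecules from a 20-molecule subset at proportions
#' 0.15-0.4 (renormalized) with mild noise, analyze each one, and score.
#'
#' @param seed Master seed for library generation, dataset draws, and the
#'   per-mixture optimiser randomness.
#' @param n_mixtures Number of mixtures.
#' @param n_molecules Library size.
#' @param subset_size Size of the mixing subset (true-negative design).
#' @param noise_sd Relative noise added to each mixture spectrum.
#' @param tol_ppm Peak-matching tolerance.
#' @param cfg WPT configuration for the library and the mixtures.
#' @return The [run_benchmark] summary, with the library attached as
#'   attribute `"library"`.
#' @export
standard_benchmark <- function(seed = 1, n_mixtures = 100, n_molecules = 74,
                               subset_size = 20, noise_sd = 0.005,
                               tol_ppm = 0.02, cfg = wpt_config()) {
  gen <- generate_library(n_molecules = n_molecules, seed = child_seed(seed, 1))
  lib <- build_library(gen$spectra, cfg)
  dataset <- generate_augmented_dataset(gen$spectra, n_mixtures = n_mixtures,
                                        subset = subset_size,
                                        noise_sd = noise_sd,
                                        seed = child_seed(seed, 2))
  bm <- run_benchmark(lib, dataset, tol_ppm = tol_ppm,
                      seed = child_seed(seed, 3))
  attr(bm, "library") <- lib
  bm
}
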