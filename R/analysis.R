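# Four-step mixture composition analysis: wavelet conversion, library peak
# matching (L I), gradient-descent elimination on shift peaks (L II), and
# gradient-descent identification on the full WPT spectrum (final list).

# Ordered candidate list; ties broken by descending probability then
# ascending name so every downstream cut is deterministic.
candidate_list <- function(name, prob, stage) {
  df <- data.frame(name = as.character(name), prob = as.numeric(prob),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$prob, df$name), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, stage = stage, class = c("candidate_list", "data.frame"))
}

#' @export
print.candidate_list <- function(x, ...) {
  cat(sprintf("<candidate_list> stage %s, %d molecules\n",
              attr(x, "stage"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 15))
  if (nrow(x) > 15) cat("  ...\n")
  invisible(x)
}

#' Match mixture shift peaks against the library (stage L I)
#'
#' For every library molecule, `p` counts its shift peaks lying within
#' `tol_ppm` of any mixture shift peak, and the probability of presence is
#' `p / (number of shift peaks of the molecule)`. Molecules with zero
#' probability are excluded.
#'
#' @param mixture_shift A `shift_spectrum` of the mixture.
#' @param lib A `spectral_library`.
#' @param tol_ppm Matching tolerance in ppm.
#' @return A `candidate_list` (stage `"LI"`) of molecules with probability
#'   greater than zero, sorted by probability.
#' @export
match_peaks <- function(mixture_shift, lib, tol_ppm = 0.02) {
  stopifnot(inherits(mixture_shift, "shift_spectrum"),
            inherits(lib, "spectral_library"))
  if (!length(lib$records)) stop_config("empty library")
  if (!nrow(mixture_shift$peaks)) stop_config("mixture shift spectrum is empty")
  if (tol_ppm <= 0) stop_config("`tol_ppm` must be > 0")
  mix_ppm <- mixture_shift$peaks$ppm
  probs <- vapply(lib$records, function(r) {
    mol_ppm <- r$shift$peaks$ppm
    p <- sum(vapply(mol_ppm, function(q) any(abs(mix_ppm - q) <= tol_ppm),
                    logical(1)))
    p / length(mol_ppm)
  }, numeric(1))
  keep <- probs > 0
  candidate_list(names(probs)[keep], probs[keep], stage = "LI")
}

#' Build a target/design matrix pair for the optimisations
#'
#' Constructs the target vector `Y` on a chemical-shift grid and the matrix
#' `X` whose column `j` holds candidate `j`'s intensity at each grid shift,
#' with `x[i, j] = 0` whenever the shift lies outside the candidate's
#' spectral domain.
#'
#' * `mode = "shift"`: the grid is the mixture's shift-peak positions, `Y`
#'   their heights, and `x[i, j]` the height of candidate `j`'s nearest
#'   shift peak within `tol_ppm` (else 0).
#' * `mode = "wpt"`: the grid is the mixture's WPT grid, `Y` its WPT
#'   intensities, and `x[i, j]` the candidate's WPT intensity linearly
#'   interpolated at the grid shift.
#'
#' @param y_source The mixture `shift_spectrum` (mode `"shift"`) or WPT
#'   [nmr_spectrum] (mode `"wpt"`).
#' @param candidates A `candidate_list` (or character vector of names).
#' @param lib A `spectral_library`.
#' @param mode `"shift"` or `"wpt"`.
#' @param tol_ppm Peak-matching tolerance for mode `"shift"`.
#' @return A `design_matrix`: `delta`, `Y`, `X` (m x n), `candidates`,
#'   `mode`; all-zero columns are reported in attribute `"zero_columns"`.
#' @export
build_design_matrix <- function(y_source, candidates, lib,
                                mode = c("shift", "wpt"), tol_ppm = 0.02) {
  mode <- match.arg(mode)
  nms <- if (is.character(candidates)) candidates else candidates$name
  if (!length(nms)) stop_config("no candidates")
  missing <- setdiff(nms, names(lib$records))
  if (length(missing))
    stop_config("candidates not in library: ", paste(missing, collapse = ", "))
  if (mode == "shift") {
    stopifnot(inherits(y_source, "shift_spectrum"))
    delta <- y_source$peaks$ppm
    Y <- y_source$peaks$height
  } else {
    stopifnot(inherits(y_source, "nmr_spectrum"))
    delta <- y_source$shifts
    Y <- y_source$intensities
  }
  X <- matrix(0, nrow = length(delta), ncol = length(nms),
              dimnames = list(NULL, nms))
  for (j in seq_along(nms)) {
    r <- lib$records[[nms[j]]]
    inside <- delta >= r$domain[1L] & delta <= r$domain[2L]
    if (mode == "shift") {
      pk <- r$shift$peaks
      xj <- vapply(delta, function(d) {
        dist <- abs(pk$ppm - d)
        k <- which.min(dist)
        if (dist[k] <= tol_ppm) pk$height[k] else 0
      }, numeric(1))
    } else {
      xj <- stats::approx(r$wpt$shifts, r$wpt$intensities, xout = delta,
                          yleft = 0, yright = 0)$y
    }
    xj[!inside] <- 0
    X[, j] <- xj
  }
  zero_cols <- nms[colSums(abs(X)) == 0]
  structure(list(delta = delta, Y = Y, X = X, candidates = nms, mode = mode),
            zero_columns = zero_cols, class = "design_matrix")
}

#' Configuration for the gradient-descent optimiser
#'
#' @param alpha Learning rate: a single fixed value, or a length-2 range
#'   from which a rate is redrawn uniformly at every iteration.
#' @param max_iter Iteration cap.
#' @param tol Relative cost-change stopping tolerance.
#' @param seed Seed for the per-iteration learning-rate draws.
#' @param nonneg Project the weights onto `theta >= 0` after every update?
#' @return A `gd_config` object.
#' @export
gd_config <- function(alpha = 0.1, max_iter = 5000, tol = 1e-8, seed = NULL,
                      nonneg = TRUE) {
  if (any(alpha <= 0)) stop_config("`alpha` must be positive")
  if (!length(alpha) %in% 1:2) stop_config("`alpha` must have length 1 or 2")
  if (max_iter < 1) stop_config("`max_iter` must be >= 1")
  if (tol <= 0) stop_config("`tol` must be > 0")
  structure(list(alpha = alpha, max_iter = as.integer(max_iter), tol = tol,
                 seed = seed, nonneg = isTRUE(nonneg)),
            class = "gd_config")
}

#' Linear gradient descent on a design matrix
#'
#' Minimises the mean squared residual `J(theta) = sum((Y - X theta)^2) / m`
#' by the iteration `theta <- theta - alpha * (2/m) * t(X) (X theta - Y)`.
#' Columns of `X` are scaled to unit maximum internally (so one learning
#' rate works across heterogeneous intensity scales) and the returned
#' weights are expressed on the original column scale. Stops when the
#' relative cost change drops below `tol` or after `max_iter` iterations.
#'
#' @param dm A `design_matrix`.
#' @param cfg A [gd_config].
#' @param theta0 Starting weights (default: the null vector).
#' @return Named numeric vector of weights with attributes `cost`,
#'   `iterations` and `converged`.
#' @export
gradient_descent <- function(dm, cfg = gd_config(), theta0 = NULL) {
  stopifnot(inherits(dm, "design_matrix"))
  X <- dm$X
  Y <- dm$Y
  m <- length(Y)
  n <- ncol(X)
  if (is.null(theta0)) theta0 <- numeric(n)
  if (length(theta0) != n) stop_config("`theta0` must have one entry per candidate")
  scale <- apply(abs(X), 2, max)
  scale[scale == 0] <- 1   # all-zero columns stay zero regardless
  Xs <- sweep(X, 2, scale, "/")
  theta <- theta0 * scale
  alphas <- if (length(cfg$alpha) == 2L) {
    with_seed(cfg$seed, stats::runif(cfg$max_iter, cfg$alpha[1L], cfg$alpha[2L]))
  } else rep(cfg$alpha, cfg$max_iter)
  r <- as.numeric(Xs %*% theta) - Y
  cost <- sum(r * r) / m
  cost0 <- max(cost, .Machine$double.eps)
  it <- 0L
  converged <- FALSE
  while (it < cfg$max_iter) {
    it <- it + 1L
    grad <- as.numeric(crossprod(Xs, r)) * (2 / m)
    theta <- theta - alphas[it] * grad
    if (cfg$nonneg) theta[theta < 0] <- 0
    r <- as.numeric(Xs %*% theta) - Y
    new_cost <- sum(r * r) / m
    if (new_cost > 10 * cost0)
      stop_config("gradient descent diverged (cost grew 10-fold); ",
                  "use a smaller learning rate")
    if (abs(cost - new_cost) <= cfg$tol * max(cost, .Machine$double.eps)) {
      cost <- new_cost
      converged <- TRUE
      break
    }
    cost <- new_cost
  }
  out <- theta / scale
  names(out) <- dm$candidates
  attr(out, "cost") <- cost
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}

#' Elimination step: optimise L I against the mixture shift spectrum
#'
#' Runs [gradient_descent] (fixed learning rate 0.1, null start, design
#' matrix in shift mode) and retains the candidates whose optimised weight
#' is non-zero, sorted descending.
#'
#' @param li Stage-`"LI"` `candidate_list`.
#' @param mixture_shift The mixture `shift_spectrum`.
#' @param lib A `spectral_library`.
#' @param tol_ppm Peak-matching tolerance used for the design matrix.
#' @param cfg A [gd_config]; defaults to `alpha = 0.1`.
#' @param zero_tol Weights at or below this value count as zero.
#' @return A `candidate_list` (stage `"LII"`).
#' @export
step3_eliminate <- function(li, mixture_shift, lib, tol_ppm = 0.02,
                            cfg = gd_config(alpha = 0.1), zero_tol = 1e-9) {
  if (!nrow(li)) stop_config("L I is empty")
  dm <- build_design_matrix(mixture_shift, li, lib, mode = "shift",
                            tol_ppm = tol_ppm)
  theta <- gradient_descent(dm, cfg)
  keep <- theta > zero_tol
  candidate_list(names(theta)[keep], theta[keep], stage = "LII")
}

#' Identification step: optimise the top 15 of L II against the WPT spectrum
#'
#' Takes the `n_top` highest-probability entries of L II, builds the design
#' matrix in WPT mode, and runs [gradient_descent] with the learning rate
#' redrawn every iteration from a uniform distribution on
#' `[0.01, 0.1]`. Candidates with optimised weight above `prob_threshold`
#' form the final composition prediction.
#'
#' @param lii Stage-`"LII"` `candidate_list`.
#' @param mixture_wpt The mixture WPT [nmr_spectrum].
#' @param lib A `spectral_library`.
#' @param cfg A [gd_config]; defaults to `alpha = c(0.01, 0.1)`. Set
#'   `cfg$seed` for bit-reproducible predictions.
#' @param n_top Number of top L II entries forwarded (15).
#' @param prob_threshold Final acceptance threshold on the weights (0.1).
#' @return A `candidate_list` (stage `"final"`).
#' @export
step4_identify <- function(lii, mixture_wpt, lib,
                           cfg = gd_config(alpha = c(0.01, 0.1)),
                           n_top = 15L, prob_threshold = 0.1) {
  if (!nrow(lii)) stop_config("L II is empty")
  top <- utils::head(lii, n_top)
  dm <- build_design_matrix(mixture_wpt, top, lib, mode = "wpt")
  theta <- gradient_descent(dm, cfg)
  keep <- theta > prob_threshold
  candidate_list(names(theta)[keep], theta[keep], stage = "final")
}

#' Run the full four-step composition analysis on a mixture spectrum
#'
#' 1. Max-normalize the mixture, select the multiplet-collapse level, and
#'    compute its WPT and WPT shift spectra.
#' 2. Match the shift peaks against the library into L I.
#' 3. Eliminate by gradient descent on the shift-peak design matrix (L II).
#' 4. Identify among the top 15 of L II by gradient descent on the WPT
#'    design matrix; weights above 0.1 form the final prediction.
#'
#' @param mixture An [nmr_spectrum] of the mixture.
#' @param lib A `spectral_library`.
#' @param tol_ppm Peak-matching tolerance, ppm.
#' @param seed Seed controlling the step-4 learning-rate draws; fixed seeds
#'   reproduce the prediction exactly.
#' @param cfg_step3,cfg_step4 Optional [gd_config] overrides.
#' @return A `mixture_prediction`: `LI`, `LII`, `final` (candidate lists),
#'   `shift`, `wpt`, `level`, `tol_ppm`, `seed`.
#' @export
analyze_mixture <- function(mixture, lib, tol_ppm = 0.02, seed = NULL,
                            cfg_step3 = NULL, cfg_step4 = NULL) {
  stopifnot(inherits(mixture, "nmr_spectrum"),
            inherits(lib, "spectral_library"))
  mixture <- normalize_spectrum(mixture, "max")
  w <- wpt_spectrum(mixture, lib$cfg)
  sh <- wpt_shift_spectrum(w, lib$cfg)
  empty <- candidate_list(character(0), numeric(0), stage = "final")
  li <- match_peaks(sh, lib, tol_ppm = tol_ppm)
  if (!nrow(li)) {
    warning("no library molecule matches the mixture; empty prediction",
            call. = FALSE)
    out <- list(LI = li, LII = empty, final = empty)
  } else {
    cfg3 <- cfg_step3 %||% gd_config(alpha = 0.1)
    lii <- step3_eliminate(li, sh, lib, tol_ppm = tol_ppm, cfg = cfg3)
    if (!nrow(lii)) {
      out <- list(LI = li, LII = lii, final = empty)
    } else {
      cfg4 <- cfg_step4 %||% gd_config(alpha = c(0.01, 0.1), seed = seed)
      fin <- step4_identify(lii, w, lib, cfg = cfg4)
      out <- list(LI = li, LII = lii, final = fin)
    }
  }
  structure(c(out, list(shift = sh, wpt = w,
                        level = w$meta$wpt_level,
                        tol_ppm = tol_ppm, seed = seed)),
            class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, ...) {
  cat(sprintf("<mixture_prediction> level %d | L I: %d | L II: %d | final: %d\n",
              x$level, nrow(x$LI), nrow(x$LII), nrow(x$final)))
  if (nrow(x$final)) {
    cat("final composition:\n")
    print.data.frame(as.data.frame(x$final))
  }
  invisible(x)
}

#' Serialize a prediction to JSON
#'
#' @param pred A `mixture_prediction`.
#' @param path Output path.
#' @param mixture_id Optional identifier recorded in the file.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(pred, path, mixture_id = NULL) {
  jsonlite::write_json(
    list(mixture_id = mixture_id, level = pred$level, tol_ppm = pred$tol_ppm,
         seed = pred$seed,
         LI = as.data.frame(pred$LI), LII = as.data.frame(pred$LII),
         final = as.data.frame(pred$final)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
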