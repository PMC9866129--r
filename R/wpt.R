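# Wavelet packet approximation cascade used to collapse scalar-coupling
# multiplets into singlets. Only the low-pass (approximation) branch feeds
# the downstream analysis; detail components are kept as diagnostics.

# Daubechies-9 analysis low-pass filter (18 taps, orthonormal, sum = sqrt(2)).
DB9_DEC_LO <- c(
   3.9347320316271603e-05, -2.5196318894271012e-04,  2.3038576352319597e-04,
   1.8476468830562265e-03, -4.2815036824634303e-03, -4.7232047577513972e-03,
   2.2361662123679096e-02,  2.5094711483145197e-04, -6.7632829061329974e-02,
   3.0725681479333380e-02,  1.4854074933810638e-01, -9.6840783222976456e-02,
  -2.9327378327917492e-01,  1.3319738582500756e-01,  6.5728807805130052e-01,
   6.0482312369011115e-01,  2.4383467461259034e-01,  3.8077947363878345e-02)

# Filter bank derived from the low-pass prototype by the usual quadrature
# mirror relations for orthogonal wavelets.
wavelet_filters <- function(wavelet = "db9") {
  if (!identical(wavelet, "db9"))
    stop_config("unknown wavelet '", wavelet, "'; only 'db9' is available")
  lo <- DB9_DEC_LO
  hi <- (-1)^seq_along(lo) * rev(lo)
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = length(lo),
       # group delay at DC of the low-pass branch (first moment of the
       # filter); used to align decimated coefficients with the ppm axis
       delay = sum(seq_along(lo) * lo) / sum(lo) - 1)
}

#' Configuration for the wavelet packet engine
#'
#' @param wavelet Analysis wavelet name; `"db9"` (Daubechies, 9 vanishing
#'   moments) is the only built-in filter.
#' @param max_level Cap on the decomposition depth; defaults at run time to
#'   the deepest level that retains at least 32 approximation coefficients.
#' @param boundary Signal extension rule; `"symmetric"` (half-point
#'   reflection) is the only supported mode.
#' @param singlet_threshold Fraction of the maximum intensity above which a
#'   local maximum counts as a peak during level selection.
#' @param peak_threshold Fraction of the maximum intensity above which a
#'   peak is retained in the shift spectrum.
#' @return A `wpt_config` object.
#' @export
wpt_config <- function(wavelet = "db9", max_level = NULL,
                       boundary = "symmetric",
                       singlet_threshold = 0.05, peak_threshold = 0.01) {
  wavelet_filters(wavelet)  # validates the name
  if (!identical(boundary, "symmetric"))
    stop_config("unsupported boundary mode '", boundary, "'")
  if (singlet_threshold <= 0 || singlet_threshold >= 1 ||
      peak_threshold <= 0 || peak_threshold >= 1)
    stop_config("thresholds must lie strictly between 0 and 1")
  structure(list(wavelet = wavelet, max_level = max_level,
                 boundary = boundary,
                 singlet_threshold = singlet_threshold,
                 peak_threshold = peak_threshold),
            class = "wpt_config")
}

# Half-point symmetric extension by p samples each side.
sym_extend <- function(x, p) {
  n <- length(x)
  if (p > n) stop_config("signal too short for the requested extension")
  c(rev(x[seq_len(p)]), x, rev(x[seq(n - p + 1L, n)]))
}

# Full linear convolution (sum_j g[j] * s[k - j + 1]).
conv_full <- function(s, g) {
  y <- stats::convolve(s, rev(g), type = "open")
  as.numeric(y)
}

#' One analysis step of the filter bank
#'
#' Splits a signal into approximation (low-pass) and detail (high-pass)
#' coefficients: symmetric extension by one filter length minus one, full
#' convolution with the analysis filters, dyadic downsampling. Output
#' length is `floor((n + filter_length - 1) / 2)`.
#'
#' @param x Numeric signal.
#' @param wavelet Wavelet name.
#' @return List with `a` (approximation) and `d` (detail) coefficients.
#' @export
wpt_analyze_step <- function(x, wavelet = "db9") {
  f <- wavelet_filters(wavelet)
  L <- f$length
  xe <- sym_extend(x, L - 1L)
  la <- (length(x) + L - 1L) %/% 2L
  idx <- seq(L + 1L, by = 2L, length.out = la)
  list(a = conv_full(xe, f$dec_lo)[idx],
       d = conv_full(xe, f$dec_hi)[idx])
}

#' One synthesis step of the filter bank
#'
#' Exact inverse of [wpt_analyze_step]: upsampling, convolution with the
#' reconstruction filters, and boundary trimming recover the original
#' signal to floating-point accuracy.
#'
#' @param a Approximation coefficients.
#' @param d Detail coefficients.
#' @param n Length of the original signal.
#' @param wavelet Wavelet name.
#' @return The reconstructed numeric signal of length `n`.
#' @export
wpt_synthesize_step <- function(a, d, n, wavelet = "db9") {
  f <- wavelet_filters(wavelet)
  up <- function(v) {
    u <- numeric(2L * length(v))
    u[seq(1L, by = 2L, length.out = length(v))] <- v
    u
  }
  full <- conv_full(up(a), f$rec_lo) + conv_full(up(d), f$rec_hi)
  full[(f$length - 2L) + seq_len(n)]
}

# Deepest level keeping at least `min_coeff` approximation coefficients.
default_max_level <- function(n, min_coeff = 32L) {
  max(1L, floor(log2(n / min_coeff)))
}

#' Multilevel approximation decomposition of a spectrum
#'
#' Applies the low-pass analysis branch `level` times. Coefficient
#' amplitudes are rescaled by `2^(-level/2)` so a flat signal keeps its
#' value, and each coefficient is assigned the chemical shift of the centre
#' of its support via the filter group delay, so peak positions are
#' preserved across levels.
#'
#' @param s An [nmr_spectrum].
#' @param cfg A [wpt_config].
#' @param level Decomposition depth; 0 returns the input unchanged.
#' @param store_details Keep the per-level detail coefficients (diagnostic)?
#' @return A `wpt_decomposition`: `level`, `approximation` (rescaled),
#'   `ppm_axis`, `n_original`, `window`, and optionally `details`.
#' @export
wpt_decompose <- function(s, cfg = wpt_config(), level, store_details = FALSE) {
  stopifnot(inherits(s, "nmr_spectrum"))
  level <- as.integer(level)
  n <- length(s$shifts)
  lmax <- cfg$max_level %||% default_max_level(n)
  if (level < 0L) stop_config("`level` must be >= 0")
  if (level > lmax)
    stop_config("level ", level, " too deep for a ", n, "-point signal ",
                "(max ", lmax, ")")
  f <- wavelet_filters(cfg$wavelet)
  a <- s$intensities
  details <- if (store_details) vector("list", level) else NULL
  k <- 0L
  while (k < level) {
    st <- wpt_analyze_step(a, cfg$wavelet)
    a <- st$a
    if (store_details) details[[k + 1L]] <- st$d
    k <- k + 1L
  }
  a <- a * 2^(-level / 2)
  dppm <- (s$shifts[n] - s$shifts[1L]) / (n - 1L)
  # coefficient i (1-based) sits at original fractional index
  # 2^level * i - (2^level - 1) * delay
  pos <- 2^level * seq_along(a) - (2^level - 1) * f$delay
  ppm_axis <- s$shifts[1L] + (pos - 1) * dppm
  structure(list(level = level, approximation = a, ppm_axis = ppm_axis,
                 n_original = n, window = range(s$shifts),
                 details = details),
            class = "wpt_decomposition")
}

# Shift-invariant (undecimated, "a trous") low-pass cascade. Each stage
# convolves with the analysis low-pass filter upsampled by 2^(j-1) under
# symmetric extension, compensates the filter group delay by an integer
# shift (tracking the fractional residual so the total misalignment stays
# below half a sample), and the result is rescaled by 2^(-level/2) so a
# flat signal keeps its value. Unlike the decimated approximation, whose
# coefficients sample the oscillatory scaling function and therefore look
# jagged for lines narrower than the equivalent kernel, this version is a
# smooth function on the original grid with peak positions preserved.
wpt_smooth <- function(x, level, wavelet = "db9", all_levels = FALSE) {
  if (level == 0L && !all_levels) return(x)
  f <- wavelet_filters(wavelet)
  L <- f$length
  apex <- kernel_apex(wavelet, level)
  y <- x
  n <- length(x)
  res <- 0
  out <- if (all_levels) vector("list", level) else NULL
  for (j in seq_len(level)) {
    hop <- 2^(j - 1L)
    h <- numeric((L - 1L) * hop + 1L)
    h[seq(1L, by = hop, length.out = L)] <- f$dec_lo
    p <- length(h) - 1L
    shift <- apex[j] - (if (j > 1L) apex[j - 1L] else 0) + res
    s <- round(shift)
    res <- shift - s
    full <- conv_full(sym_extend(y, p), h)
    y <- full[p + s + seq_len(n)]
    if (all_levels) out[[j]] <- y * 2^(-j / 2)
  }
  if (all_levels) out else y * 2^(-level / 2)
}

# Apex (mode) position, 0-based and parabolic-refined, of the cumulative
# iterated low-pass kernel at each level. Aligning by the kernel apex (not
# the DC group delay) keeps narrow-line peak positions fixed across levels
# despite the asymmetry of extremal-phase Daubechies filters. Cached per
# wavelet.
.wpt_cache <- new.env(parent = emptyenv())

kernel_apex <- function(wavelet, level) {
  key <- paste0(wavelet, ":", level)
  hit <- get0(key, envir = .wpt_cache)
  if (!is.null(hit)) return(hit)
  f <- wavelet_filters(wavelet)
  L <- f$length
  k <- 1
  apex <- numeric(level)
  for (j in seq_len(level)) {
    hop <- 2^(j - 1L)
    h <- numeric((L - 1L) * hop + 1L)
    h[seq(1L, by = hop, length.out = L)] <- f$dec_lo
    k <- conv_full(k, h)
    i <- which.max(k)
    off <- 0
    if (i > 1L && i < length(k)) {
      denom <- k[i - 1L] - 2 * k[i] + k[i + 1L]
      if (denom < 0) off <- 0.5 * (k[i - 1L] - k[i + 1L]) / denom
    }
    apex[j] <- i - 1L + off
  }
  assign(key, apex, envir = .wpt_cache)
  apex
}

# ---- peak picking ----------------------------------------------------------

# Topographic prominence of a local maximum at index i: walk outwards on
# each side until a strictly higher sample (or the boundary) is reached and
# record the lowest point passed; the prominence is the drop to the higher
# of the two side minima.
peak_prominence <- function(y, i) {
  n <- length(y)
  side_min <- function(dir) {
    lo <- y[i]
    j <- i + dir
    while (j >= 1L && j <= n) {
      if (y[j] > y[i]) return(lo)
      if (y[j] < lo) lo <- y[j]
      j <- j + dir
    }
    lo
  }
  y[i] - max(side_min(-1L), side_min(1L))
}

# Local maxima of a sampled curve above rel_threshold * max(y), filtered by
# relative topographic prominence (suppresses wavelet ringing side lobes
# and unresolved shoulders) and grouped into contiguous above-threshold
# regions. Apex positions and heights are refined by parabolic
# interpolation.
# `satellite_window`/`satellite_frac`: a peak is discarded as a kernel
# side-lobe when a much taller peak (height ratio above 1/satellite_frac)
# lies within satellite_window ppm; the iterated Daubechies-9 kernel
# carries satellites of up to ~15% of the parent height within a few
# kernel widths, so the smoothed spectra are cleaned with a window scaled
# to the decomposition level.
find_peaks <- function(x, y, rel_threshold, min_prominence = 0.5,
                       satellite_window = 0, satellite_frac = 0.3) {
  m <- max(y)
  if (m <= 0) return(empty_peaks())
  thr <- rel_threshold * m
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1L], -Inf)
  idx <- which(y >= thr & y >= left & y > right)
  if (!length(idx)) return(empty_peaks())
  prom <- vapply(idx, function(i) peak_prominence(y, i), numeric(1))
  idx <- idx[prom >= min_prominence * y[idx]]
  if (!length(idx)) return(empty_peaks())
  # region id = which contiguous above-threshold run the apex belongs to
  r <- rle(y >= thr)
  run_end <- cumsum(r$lengths)
  run_id <- cumsum(r$values)  # counts only above-threshold runs
  region <- vapply(idx, function(i) {
    run_id[which(run_end >= i)[1L]]
  }, numeric(1))
  pos <- numeric(length(idx)); ht <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (i > 1L && i < n) {
      denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      off <- if (denom < 0) 0.5 * (y[i - 1L] - y[i + 1L]) / denom else 0
      off <- max(-0.5, min(0.5, off))
      step <- if (off >= 0) x[i + 1L] - x[i] else x[i] - x[i - 1L]
      pos[j] <- x[i] + off * step
      ht[j] <- y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * off
    } else {
      pos[j] <- x[i]; ht[j] <- y[i]
    }
  }
  keep <- rep(TRUE, length(idx))
  if (satellite_window > 0 && length(idx) > 1L) {
    for (j in seq_along(idx)) {
      near <- abs(pos - pos[j]) <= satellite_window
      if (any(ht[near] * satellite_frac > ht[j])) keep[j] <- FALSE
    }
  }
  data.frame(ppm = pos[keep], height = ht[keep], index = idx[keep],
             region = as.integer(region[keep]))
}

# TRUE when every contiguous above-threshold region of `y` has exactly one
# strict local maximum (literal unimodality, no prominence filtering).
regions_unimodal <- function(y, rel_threshold) {
  thr <- rel_threshold * max(y)
  r <- rle(y >= thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    seg <- y[starts[k]:ends[k]]
    m <- length(seg)
    if (m < 3L) next
    n_max <- sum(seg[2:(m - 1L)] >= seg[1:(m - 2L)] &
                   seg[2:(m - 1L)] > seg[3:m])
    if (n_max > 1L) return(FALSE)
  }
  TRUE
}

empty_peaks <- function() {
  data.frame(ppm = numeric(0), height = numeric(0), index = integer(0),
             region = integer(0))
}

# Peak count and per-region unimodality of an approximation vector.
peak_summary <- function(x, y, rel_threshold, satellite_window = 0) {
  pk <- find_peaks(x, y, rel_threshold, satellite_window = satellite_window)
  if (!nrow(pk)) return(list(count = 0L, unimodal = FALSE, peaks = pk))
  per_region <- table(pk$region)
  list(count = nrow(pk), unimodal = all(per_region == 1L), peaks = pk)
}

#' Select the decomposition level that collapses all multiplets
#'
#' Walks down the approximation cascade counting prominent local maxima
#' above `singlet_threshold`. While scalar couplings are being smoothed
#' out the count drops level by level; once every multiplet has collapsed
#' to a singlet it stabilises over several consecutive levels, and much
#' deeper it can fall again when unrelated resonance sites merge. The
#' selected level is the start of the earliest constant-count run of
#' length at least two whose count lies below the raw (level-0) count:
#' the first depth at which the count has both decreased (couplings were
#' actually removed) and stopped decreasing (no coupling structure
#' remains). Within that run the selection advances to the first level
#' whose above-threshold regions are literally unimodal, because a
#' just-merged multiplet can keep a shallow double apex (below the
#' prominence cut) for one more level.
#' A spectrum of pure singlets never drops below its raw count,
#' so level 1 is returned. Heavily crowded spectra (dense mixtures) may
#' show no stable run at all because multiplet collapse blends directly
#' into site merging; the count curve then decreases at every level, fast
#' while couplings vanish and slowly afterwards, and the selected level
#' falls back to the elbow of the curve (the maximum of its second
#' difference), i.e. the depth where the fast decrease ends.
#'
#' @param s An [nmr_spectrum] with at least one peak above the threshold.
#' @param cfg A [wpt_config].
#' @return The selected level (integer) with attribute `counts` (per-level
#'   peak counts, level 0 first).
#' @export
wpt_select_level <- function(s, cfg = wpt_config()) {
  stopifnot(inherits(s, "nmr_spectrum"))
  n <- length(s$shifts)
  lmax <- cfg$max_level %||% default_max_level(n)
  if (max(s$intensities) <= 0)
    stop_config("degenerate input: no positive intensity")
  s0 <- peak_summary(s$shifts, s$intensities, cfg$singlet_threshold)
  if (s0$count == 0L)
    stop_config("degenerate input: no peak above the singlet threshold")
  counts <- integer(lmax + 1L)
  counts[1L] <- s0$count
  smooth_levels <- wpt_smooth(s$intensities, lmax, cfg$wavelet,
                              all_levels = TRUE)
  dppm <- (s$shifts[n] - s$shifts[1L]) / (n - 1L)
  for (L in seq_len(lmax))
    counts[L + 1L] <- peak_summary(s$shifts, smooth_levels[[L]],
                                   cfg$singlet_threshold,
                                   satellite_window = 6 * 2^L * dppm)$count
  cl <- counts[-1L]                      # counts at levels 1..lmax
  r <- rle(cl)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  stable <- r$lengths >= 2L
  below <- r$values < counts[1L]
  pick_run <- if (any(stable & below)) {
    which(stable & below)[1L]
  } else if (any(stable)) {
    # never dropped below the raw count: the input is already all singlets
    which(stable)[1L]
  } else NA_integer_
  best <- if (!is.na(pick_run)) {
    # within the chosen constant-count run, advance to the first level whose
    # above-threshold regions carry no residual fine structure (a just-merged
    # multiplet can keep a shallow double apex for one more level)
    rs <- run_start[pick_run]
    uni <- vapply(seq(rs, run_end[pick_run]), function(L)
      regions_unimodal(smooth_levels[[L]], cfg$singlet_threshold), logical(1))
    if (any(uni)) rs + which(uni)[1L] - 1L else rs
  } else if (lmax >= 3L) {
    # no stability anywhere (densely crowded input): elbow of the monotone
    # count curve
    d2 <- cl[seq_len(lmax - 2L)] - 2 * cl[seq(2L, lmax - 1L)] +
      cl[seq(3L, lmax)]
    which.max(d2) + 1L
  } else {
    which.min(cl)
  }
  structure(as.integer(best), counts = counts)
}

#' Compute the WPT spectrum of an NMR spectrum
#'
#' The low-pass approximation component at the selected (or given) level on
#' the original uniform ppm grid, computed with the shift-invariant variant
#' of the cascade so the result is a smooth curve in which every multiplet
#' of the input appears as a single broad peak.
#'
#' @param s An [nmr_spectrum].
#' @param cfg A [wpt_config].
#' @param level Decomposition depth; selected with [wpt_select_level] when
#'   `NULL`.
#' @return An [nmr_spectrum] on the same grid as `s`; `meta$wpt_level`
#'   records the depth.
#' @export
wpt_spectrum <- function(s, cfg = wpt_config(), level = NULL) {
  if (is.null(level)) level <- wpt_select_level(s, cfg)
  level <- as.integer(level)
  n <- length(s$shifts)
  lmax <- cfg$max_level %||% default_max_level(n)
  if (level > lmax)
    stop_config("level ", level, " too deep for a ", n, "-point signal")
  y <- wpt_smooth(s$intensities, level, cfg$wavelet)
  nmr_spectrum(s$shifts, y, meta = c(s$meta, list(wpt_level = level)))
}

#' Extract the WPT shift spectrum (sparse peak list)
#'
#' Every local maximum above `peak_threshold` times the maximum of the WPT
#' spectrum is reduced to a (position, height) pair; apex positions are
#' parabolic-interpolated.
#'
#' @param w A WPT spectrum from [wpt_spectrum] (or any spectrum whose
#'   above-threshold regions are unimodal).
#' @param cfg A [wpt_config].
#' @return A `shift_spectrum`: `peaks` (data frame with `ppm`, `height`),
#'   `source_level`, `molecule`.
#' @export
wpt_shift_spectrum <- function(w, cfg = wpt_config()) {
  stopifnot(inherits(w, "nmr_spectrum"))
  lvl <- w$meta$wpt_level %||% 0L
  dppm <- (max(w$shifts) - min(w$shifts)) / (length(w$shifts) - 1L)
  pk <- find_peaks(w$shifts, w$intensities, cfg$peak_threshold,
                   satellite_window = 6 * 2^lvl * dppm)
  if (!nrow(pk))
    stop_config("no peak above the threshold; cannot build a shift spectrum")
  pk <- pk[order(pk$ppm), c("ppm", "height")]
  rownames(pk) <- NULL
  structure(list(peaks = pk,
                 source_level = w$meta$wpt_level %||% NA_integer_,
                 molecule = w$meta$name %||% NULL),
            class = "shift_spectrum")
}

#' @export
print.shift_spectrum <- function(x, ...) {
  cat(sprintf("<shift_spectrum> %d peaks, level %s%s\n", nrow(x$peaks),
              x$source_level,
              if (!is.null(x$molecule)) paste0(", molecule ", x$molecule) else ""))
  invisible(x)
}
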