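#' Construct a 1D NMR spectrum object
#'
#' A spectrum is a pair of equal-length numeric vectors: chemical shifts in
#' ppm and the corresponding absorption intensities (arbitrary units). The
#' axis is always stored ascending; inputs given in the conventional NMR
#' display order (high ppm first) are reordered, with intensities permuted
#' consistently.
#'
#' @param shifts Numeric vector of chemical shifts (ppm), strictly monotonic.
#' @param intensities Numeric vector of intensities, same length as `shifts`;
#'   must be finite.
#' @param meta Named list of free-form provenance (molecule name, field
#'   strength in MHz, source path, ...).
#' @return An object of class `nmr_spectrum` with elements `shifts`,
#'   `intensities` and `meta`.
#' @export
nmr_spectrum <- function(shifts, intensities, meta = list()) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities))
    stop_config("`shifts` and `intensities` must have the same length")
  if (length(shifts) < 16L)
    stop_config("a spectrum needs at least 16 points, got ", length(shifts))
  if (anyNA(shifts) || any(!is.finite(shifts)))
    stop_config("`shifts` contains NA or non-finite values")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop_config("`intensities` contains NA or non-finite values")
  d <- diff(shifts)
  if (all(d < 0)) {
    shifts <- rev(shifts)
    intensities <- rev(intensities)
  } else if (!all(d > 0)) {
    stop_config("`shifts` must be strictly monotonic")
  }
  structure(list(shifts = shifts, intensities = intensities,
                 meta = as.list(meta)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f..%.3f ppm, max intensity %.4g\n",
              length(x$shifts), min(x$shifts), max(x$shifts),
              max(x$intensities)))
  if (!is.null(x$meta$name)) cat("  molecule:", x$meta$name, "\n")
  invisible(x)
}

#' @export
length.nmr_spectrum <- function(x) length(x$shifts)

#' Read a spectrum from a two-column text file or JCAMP-DX
#'
#' CSV/TSV files hold two numeric columns (ppm, intensity); a single header
#' line is auto-detected and skipped. The JCAMP-DX reader supports
#' single-block `##XYDATA=(X++(Y..Y))` real spectra only.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"jcamp"`. `"auto"`
#'   dispatches on the file extension (`.jdx`/`.dx` to JCAMP, `.tsv`/`.txt`
#'   to tab/whitespace, anything else to comma).
#' @return An [nmr_spectrum] with `meta$source` recording `path`.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "tsv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jdx", "dx", "jcamp")) "jcamp"
      else if (ext %in% c("tsv", "txt")) "tsv" else "csv"
  }
  if (format == "jcamp") return(read_jcamp(path))
  sep <- if (format == "tsv") "" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_config("empty file: ", path)
  parse_one <- function(ln) {
    parts <- if (identical(sep, ",")) strsplit(ln, ",", fixed = TRUE)[[1]]
      else strsplit(trimws(ln), "[[:space:]]+")[[1]]
    suppressWarnings(as.numeric(trimws(parts)))
  }
  start <- 1L
  first <- parse_one(lines[[1L]])
  if (anyNA(first)) start <- 2L  # header row
  n <- length(lines) - start + 1L
  if (n < 1L) stop_config("no data rows in ", path)
  ppm <- numeric(n); int <- numeric(n)
  for (i in seq_len(n)) {
    v <- parse_one(lines[[start + i - 1L]])
    if (length(v) < 2L || anyNA(v[1:2]))
      stop_config("cannot parse line ", start + i - 1L, " of ", path, ": '",
                  lines[[start + i - 1L]], "'")
    ppm[i] <- v[1L]; int[i] <- v[2L]
  }
  nmr_spectrum(ppm, int, meta = list(source = path))
}

# Minimal JCAMP-DX reader: one block, XYDATA=(X++(Y..Y)), AFFN numbers.
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_titles <- sum(grepl("^##TITLE=", lines))
  if (n_titles > 1L)
    stop_config("multi-block JCAMP-DX files are not supported: ", path)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0("^##", key, "="), "", hit[[1L]])))
  }
  xfac <- get_field("XFACTOR"); if (is.na(xfac)) xfac <- 1
  yfac <- get_field("YFACTOR"); if (is.na(yfac)) yfac <- 1
  i0 <- grep("^##XYDATA=", lines)
  if (!length(i0)) stop_config("no ##XYDATA block in ", path)
  i1 <- grep("^##END", lines)
  i1 <- i1[i1 > i0[[1L]]]
  if (!length(i1)) i1 <- length(lines) + 1L
  body <- lines[(i0[[1L]] + 1L):(i1[[1L]] - 1L)]
  ppm <- numeric(0); int <- numeric(0)
  for (ln in body) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    if (anyNA(v) || length(v) < 2L)
      stop_config("cannot parse JCAMP data line: '", ln, "'")
    x0 <- v[1L] * xfac
    ys <- v[-1L] * yfac
    # per-line x increment recovered later from first values; store raw
    ppm <- c(ppm, x0 + seq_along(ys) - 1)  # placeholder spacing, fixed below
    int <- c(int, ys)
  }
  # Recompute x spacing from FIRSTX/LASTX/NPOINTS when available.
  firstx <- get_field("FIRSTX"); lastx <- get_field("LASTX")
  npts <- get_field("NPOINTS")
  if (!is.na(firstx) && !is.na(lastx) && !is.na(npts) && npts == length(int)) {
    ppm <- seq(firstx, lastx, length.out = npts)
  } else {
    stop_config("JCAMP file lacks consistent FIRSTX/LASTX/NPOINTS: ", path)
  }
  nmr_spectrum(ppm, int, meta = list(source = path, format = "jcamp"))
}

#' Write a spectrum to a two-column text file
#'
#' @param s An [nmr_spectrum].
#' @param path Output path.
#' @param sep Column separator, `","` (CSV) or `"\t"` (TSV).
#' @param header Write a `ppm<sep>intensity` header line?
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = ",", header = TRUE) {
  stopifnot(inherits(s, "nmr_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(paste("ppm", "intensity", sep = sep), con)
  writeLines(paste(format(s$shifts, digits = 15, trim = TRUE, scientific = FALSE),
                   format(s$intensities, digits = 15, trim = TRUE),
                   sep = sep), con)
  invisible(path)
}

#' Resample a spectrum onto a uniform grid
#'
#' Linear interpolation onto `n_points` equally spaced shifts spanning the
#' original ppm range; the endpoint intensities are preserved exactly.
#'
#' @param s An [nmr_spectrum].
#' @param n_points Target length, at least 16.
#' @return A resampled [nmr_spectrum].
#' @export
resample_spectrum <- function(s, n_points) {
  stopifnot(inherits(s, "nmr_spectrum"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 16L)
    stop_config("`n_points` must be an integer >= 16")
  grid <- seq(s$shifts[1L], s$shifts[length(s$shifts)], length.out = n_points)
  y <- stats::approx(s$shifts, s$intensities, xout = grid, rule = 2)$y
  nmr_spectrum(grid, y, meta = s$meta)
}

#' Normalize spectrum intensities
#'
#' `"max"` scales the maximum intensity to 1; `"area"` scales the trapezoidal
#' integral over the ppm axis to 1.
#'
#' @param s An [nmr_spectrum] with a positive maximum intensity.
#' @param mode `"max"` or `"area"`.
#' @return A scaled copy; `meta$normalized` records the mode.
#' @export
normalize_spectrum <- function(s, mode = c("max", "area")) {
  stopifnot(inherits(s, "nmr_spectrum"))
  mode <- match.arg(mode)
  if (max(s$intensities) <= 0)
    stop_config("cannot normalize: spectrum has no positive intensity")
  denom <- if (mode == "max") max(s$intensities) else trapz(s$shifts, s$intensities)
  if (denom <= 0) stop_config("cannot normalize: non-positive ", mode)
  out <- s
  out$intensities <- s$intensities / denom
  out$meta$normalized <- mode
  out
}

# Trapezoidal integral over an arbitrary monotone grid.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
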