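# Construction, serialization and querying of the per-molecule WPT shift
# spectral library.

LIBRARY_FORMAT_VERSION <- "1.0"

#' Build a WPT shift spectral library
#'
#' For each named pure-molecule spectrum: max-normalize, select the
#' multiplet-collapse decomposition level independently, and store the raw
#' spectrum, the WPT spectrum, the shift peak list, the level, and the
#' spectral domain (the ppm range where the WPT intensity reaches the peak
#' threshold, used for the out-of-domain zeroing rule of the design
#' matrices).
#'
#' @param spectra Named list of [nmr_spectrum] objects, or a list of
#'   `(name, spectrum)` handled via its names.
#' @param cfg A [wpt_config] applied to every molecule.
#' @param strict If `TRUE` (default) a molecule that fails level selection
#'   aborts the build; otherwise it is skipped with a warning.
#' @return A `spectral_library`: `records` (per-molecule lists with `name`,
#'   `raw`, `wpt`, `shift`, `level`, `domain`), `cfg`, `version`.
#' @export
build_library <- function(spectra, cfg = wpt_config(), strict = TRUE) {
  nms <- names(spectra)
  if (is.null(nms) || any(!nzchar(nms)))
    stop_config("`spectra` must be a fully named list")
  if (anyDuplicated(nms))
    stop_config("duplicate molecule names: ",
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  records <- list()
  for (nm in nms) {
    rec <- tryCatch(build_record(nm, spectra[[nm]], cfg),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (strict) stop_config("molecule '", nm, "': ", conditionMessage(rec))
      warning("skipping molecule '", nm, "': ", conditionMessage(rec),
              call. = FALSE)
    } else records[[nm]] <- rec
  }
  structure(list(records = records, cfg = cfg,
                 version = LIBRARY_FORMAT_VERSION),
            class = "spectral_library")
}

build_record <- function(name, s, cfg) {
  stopifnot(inherits(s, "nmr_spectrum"))
  s <- normalize_spectrum(s, "max")
  s$meta$name <- name
  level <- wpt_select_level(s, cfg)
  w <- wpt_spectrum(s, cfg, level = level)
  sh <- wpt_shift_spectrum(w, cfg)
  dom <- spectral_domain(w, cfg$peak_threshold)
  list(name = name, raw = s, wpt = w, shift = sh,
       level = as.integer(level), domain = dom)
}

# [first, last] ppm where the intensity reaches rel_threshold * max.
spectral_domain <- function(s, rel_threshold) {
  thr <- rel_threshold * max(s$intensities)
  idx <- which(s$intensities >= thr)
  c(s$shifts[min(idx)], s$shifts[max(idx)])
}

#' @export
print.spectral_library <- function(x, ...) {
  lv <- vapply(x$records, `[[`, integer(1), "level")
  cat(sprintf("<spectral_library> %d molecules, wavelet %s, levels %s..%s\n",
              length(x$records), x$cfg$wavelet,
              if (length(lv)) min(lv) else NA, if (length(lv)) max(lv) else NA))
  invisible(x)
}

#' @export
length.spectral_library <- function(x) length(x$records)

#' Save a spectral library to disk
#'
#' Writes a human-readable JSON index (`library.json`: version,
#' configuration, per-molecule level, domain and shift peaks) plus one CSV
#' per molecule holding the raw and WPT intensity vectors.
#'
#' @param lib A [build_library] result.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  idx <- list(
    version = lib$version,
    cfg = list(wavelet = lib$cfg$wavelet,
               max_level = lib$cfg$max_level,
               boundary = lib$cfg$boundary,
               singlet_threshold = lib$cfg$singlet_threshold,
               peak_threshold = lib$cfg$peak_threshold),
    molecules = lapply(unname(lib$records), function(r) {
      list(name = r$name, level = r$level,
           domain = as.numeric(r$domain),
           source_level = r$shift$source_level,
           peaks = r$shift$peaks,
           file = paste0(r$name, ".csv"))
    }))
  jsonlite::write_json(idx, file.path(path, "library.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (r in lib$records) {
    dt <- data.table::data.table(ppm = r$raw$shifts,
                                 raw = r$raw$intensities,
                                 wpt = r$wpt$intensities)
    data.table::fwrite(dt, file.path(path, paste0(r$name, ".csv")))
  }
  invisible(path)
}

#' Load a spectral library saved by [save_library]
#'
#' @param path Directory containing `library.json` and per-molecule CSVs.
#' @return A `spectral_library`.
#' @export
load_library <- function(path) {
  idx_file <- file.path(path, "library.json")
  if (!file.exists(idx_file)) stop_config("no library.json under ", path)
  idx <- jsonlite::read_json(idx_file, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (!identical(idx$version, LIBRARY_FORMAT_VERSION))
    stop_config("library format version '", idx$version,
                "' is incompatible with this build (expected ",
                LIBRARY_FORMAT_VERSION, ")")
  ml <- idx$cfg$max_level
  if (!length(ml)) ml <- NULL   # JSON null round-trips as an empty list
  cfg <- wpt_config(wavelet = idx$cfg$wavelet,
                    max_level = ml,
                    boundary = idx$cfg$boundary %||% "symmetric",
                    singlet_threshold = idx$cfg$singlet_threshold,
                    peak_threshold = idx$cfg$peak_threshold)
  mols <- idx$molecules
  records <- list()
  for (i in seq_len(nrow(mols))) {
    nm <- mols$name[i]
    dt <- data.table::fread(file.path(path, mols$file[i]), showProgress = FALSE)
    raw <- nmr_spectrum(dt$ppm, dt$raw, meta = list(name = nm))
    wpt <- nmr_spectrum(dt$ppm, dt$wpt,
                        meta = list(name = nm, wpt_level = mols$level[i]))
    peaks <- as.data.frame(mols$peaks[[i]])
    sh <- structure(list(peaks = peaks[order(peaks$ppm), , drop = FALSE],
                         source_level = mols$source_level[i],
                         molecule = nm),
                    class = "shift_spectrum")
    rownames(sh$peaks) <- NULL
    records[[nm]] <- list(name = nm, raw = raw, wpt = wpt, shift = sh,
                          level = as.integer(mols$level[i]),
                          domain = as.numeric(mols$domain[[i]]))
  }
  structure(list(records = records, cfg = cfg, version = idx$version),
            class = "spectral_library")
}
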