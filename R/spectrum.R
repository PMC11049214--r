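#' Construct a Raman/SERS spectrum
#'
#' A `raman_spectrum` is the package's basic container: a strictly
#' increasing wavenumber axis (Raman shift, cm^-1), one intensity value per
#' axis point (arbitrary units), and an optional [spectrum_meta()] record
#' describing the sample.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1. Sorted
#'   ascending if not already; must contain no duplicates.
#' @param intensities Numeric vector of intensities (a.u.), same length as
#'   `wavenumbers`; all values must be finite.
#' @param meta Optional [spectrum_meta()] record (or `NULL`).
#' @return An object of class `raman_spectrum`.
#' @examples
#' s <- raman_spectrum(400:1800, rexp(1401))
#' s
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers))) {
    stop("wavenumbers must all be finite", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must all be finite", call. = FALSE)
  }
  if (anyDuplicated(wavenumbers)) {
    stop("duplicate wavenumbers are not allowed", call. = FALSE)
  }
  if (is.unsorted(wavenumbers)) {
    ord <- order(wavenumbers)
    wavenumbers <- wavenumbers[ord]
    intensities <- intensities[ord]
  }
  if (!is.null(meta)) meta <- as_spectrum_meta(meta)
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities, meta = meta),
    class = "raman_spectrum"
  )
}

#' Sample metadata for a spectrum
#'
#' @param protein One of `"Ngb"` (neuroglobin), `"CytC"` (cytochrome c) or
#'   `"other"`.
#' @param variant Free-form variant label, e.g. `"WT"` or `"E60K/E87K"`.
#'   Must be non-empty.
#' @param redox Iron redox state: `"oxidized"`, `"reduced"` or `"unknown"`.
#' @param modality Acquisition modality: `"RRS"` (resonance Raman) or
#'   `"SERS"` (surface-enhanced Raman).
#' @param replicate Positive integer replicate index.
#' @return An object of class `spectrum_meta`.
#' @export
spectrum_meta <- function(protein = c("Ngb", "CytC", "other"),
                          variant = "WT",
                          redox = c("oxidized", "reduced", "unknown"),
                          modality = c("RRS", "SERS"),
                          replicate = 1L) {
  protein <- match.arg(protein)
  redox <- match.arg(redox)
  modality <- match.arg(modality)
  variant <- as.character(variant)
  if (length(variant) != 1L || is.na(variant) || !nzchar(variant)) {
    stop("variant must be a non-empty label", call. = FALSE)
  }
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) {
    stop("replicate must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(protein = protein, variant = variant, redox = redox,
         modality = modality, replicate = replicate),
    class = "spectrum_meta"
  )
}

as_spectrum_meta <- function(x) {
  if (inherits(x, "spectrum_meta")) return(x)
  if (!is.list(x)) stop("meta must be a spectrum_meta or a named list", call. = FALSE)
  spectrum_meta(
    protein = x$protein %||% "other",
    variant = x$variant %||% "WT",
    redox = x$redox %||% "unknown",
    modality = x$modality %||% "RRS",
    replicate = x$replicate %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm-1\n",
              length(x$wavenumbers), rng[1], rng[2]))
  if (!is.null(x$meta)) {
    m <- x$meta
    cat(sprintf("  %s %s, %s, %s, replicate %d\n",
                m$protein, m$variant, m$redox, m$modality, m$replicate))
  }
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, intensity = x$intensities)
}

#' @export
plot.raman_spectrum <- function(x, ...,
                                xlab = expression(paste("Raman shift (", cm^-1, ")")),
                                ylab = "Intensity (a.u.)", type = "l") {
  graphics::plot(x$wavenumbers, x$intensities, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

sidecar_path <- function(path) {
  base <- sub("\\.[^./\\\\]*$", "", path)
  paste0(base, ".meta.json")
}

#' Read a spectrum from a text or CSV file
#'
#' Two dialects are supported: whitespace-delimited two-column text
#' (wavenumber, intensity) and CSV with the header
#' `wavenumber_cm-1,intensity`. If a metadata sidecar
#' `<basename>.meta.json` exists next to the file it is read automatically;
#' an explicit `meta` argument takes precedence. Rows are re-sorted to an
#' ascending wavenumber axis if needed.
#'
#' @param path Path to the data file.
#' @param dialect `"two_column_text"` or `"csv_with_header"`.
#' @param meta Optional [spectrum_meta()] (overrides any sidecar).
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path,
                          dialect = c("two_column_text", "csv_with_header"),
                          meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (dialect == "two_column_text") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    if (length(keep) == 0L) stop("no data rows in ", path, call. = FALSE)
    parts <- strsplit(trimws(lines[keep]), "[ \t,;]+")
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad)) {
      stop(sprintf("cannot parse line %d of %s", keep[bad[1]], path), call. = FALSE)
    }
    wn <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    it <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    bad <- which(is.na(wn) | is.na(it))
    if (length(bad)) {
      stop(sprintf("non-numeric value on line %d of %s", keep[bad[1]], path),
           call. = FALSE)
    }
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("wavenumber_cm-1", "intensity")
    if (!all(need %in% names(df))) {
      stop("CSV must have header 'wavenumber_cm-1,intensity'", call. = FALSE)
    }
    wn <- suppressWarnings(as.numeric(df[["wavenumber_cm-1"]]))
    it <- suppressWarnings(as.numeric(df[["intensity"]]))
    bad <- which(is.na(wn) | is.na(it))
    if (length(bad)) {
      # +1 for the header row
      stop(sprintf("non-numeric value on line %d of %s", bad[1] + 1L, path),
           call. = FALSE)
    }
  }

  if (is.null(meta)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  }
  raman_spectrum(wn, it, meta = meta)
}

#' Write a spectrum to a text or CSV file
#'
#' The inverse of [read_spectrum()]: values are written with enough digits
#' that a read/write round trip reproduces the spectrum to double
#' precision. If the spectrum carries metadata, a `<basename>.meta.json`
#' sidecar is written alongside.
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output path.
#' @param dialect `"two_column_text"` or `"csv_with_header"`.
#' @return The output path, invisibly.
#' @export
write_spectrum <- function(spectrum, path,
                           dialect = c("two_column_text", "csv_with_header")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spectrum, "raman_spectrum"))
  rows <- sprintf(
    if (dialect == "csv_with_header") "%.15g,%.15g" else "%.15g %.15g",
    spectrum$wavenumbers, spectrum$intensities
  )
  if (dialect == "csv_with_header") rows <- c("wavenumber_cm-1,intensity", rows)
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  if (!is.null(spectrum$meta)) {
    jsonlite::write_json(unclass(spectrum$meta), sidecar_path(path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Resample a spectrum onto a uniform wavenumber grid
#'
#' Linear interpolation onto `seq(start, stop, by = step)`. The requested
#' range must lie inside the recorded range; no extrapolation is performed.
#' Metadata is preserved.
#'
#' @param spectrum A [raman_spectrum()].
#' @param start,stop Grid limits in cm^-1.
#' @param step Grid spacing in cm^-1 (> 0).
#' @return A [raman_spectrum()] on the uniform grid.
#' @export
resample_to_grid <- function(spectrum, start = 400, stop = 1800, step = 1) {
  stopifnot(inherits(spectrum, "raman_spectrum"), step > 0, start < stop)
  rng <- range(spectrum$wavenumbers)
  if (start < rng[1] || stop > rng[2]) {
    stop(sprintf(
      "requested grid [%g, %g] outside recorded range [%g, %g]; no extrapolation",
      start, stop, rng[1], rng[2]), call. = FALSE)
  }
  grid <- seq(start, stop, by = step)
  yi <- stats::approx(spectrum$wavenumbers, spectrum$intensities,
                      xout = grid, method = "linear")$y
  raman_spectrum(grid, yi, meta = spectrum$meta)
}

grid_step <- function(spectrum) {
  d <- diff(spectrum$wavenumbers)
  if (max(d) - min(d) > 1e-6 * stats::median(d)) return(NA_real_)
  stats::median(d)
}

is_uniform_grid <- function(spectrum) !is.na(grid_step(spectrum))
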