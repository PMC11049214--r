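#' Asymmetric least squares baseline subtraction
#'
#' Estimates the smooth fluorescence-type background under a Raman/SERS
#' spectrum with a Whittaker smoother carrying asymmetric weights: points
#' above the current baseline (peaks) get weight `asymmetry`, points below
#' get `1 - asymmetry`, and the weights are re-estimated until they stop
#' changing or `max_iter` is reached. The result is a smooth curve that
#' hugs the lower envelope of the spectrum; peak apices are left intact.
#'
#' @param spectrum A [raman_spectrum()] on a uniform grid (see
#'   [resample_to_grid()]).
#' @param smoothness Penalty weight on the squared second differences of
#'   the baseline (dimensionless; larger = stiffer). Default `1e5` suits a
#'   1 cm^-1 grid and slowly varying fluorescence backgrounds.
#' @param asymmetry Weight given to points above the baseline, in (0, 1).
#'   Small values (default 0.01) make the fit ignore peaks.
#' @param max_iter Maximum number of reweighting iterations.
#' @return A list with elements `corrected` (the baseline-subtracted
#'   [raman_spectrum()]; slightly negative values in noise troughs are
#'   retained, not clipped) and `baseline` (the estimated background as a
#'   [raman_spectrum()]).
#' @references Eilers, P.H.C. and Boelens, H.F.M. (2005) Baseline
#'   correction with asymmetric least squares smoothing.
#' @export
subtract_baseline <- function(spectrum, smoothness = 1e5, asymmetry = 0.01,
                              max_iter = 10L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (!is_uniform_grid(spectrum)) {
    stop("spectrum is not on a uniform grid; run resample_to_grid() first",
         call. = FALSE)
  }
  if (!(smoothness > 0)) stop("smoothness must be positive", call. = FALSE)
  if (!(asymmetry > 0 && asymmetry < 1)) {
    stop("asymmetry must lie in (0, 1)", call. = FALSE)
  }
  y <- spectrum$intensities
  z <- als_baseline(y, lambda = smoothness, p = asymmetry,
                    max_iter = as.integer(max_iter))
  list(
    corrected = raman_spectrum(spectrum$wavenumbers, y - z, meta = spectrum$meta),
    baseline = raman_spectrum(spectrum$wavenumbers, z, meta = spectrum$meta)
  )
}

# cache for the (length, lambda)-specific penalty matrix: building the
# second-difference penalty dominates the cost when many equal-length
# spectra are processed in a loop
.als_cache <- new.env(parent = emptyenv())

als_penalty <- function(m, lambda) {
  key <- sprintf("%d_%.6g", m, lambda)
  got <- .als_cache[[key]]
  if (!is.null(got)) return(got)
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(m - 2L), 3L),
    j = c(seq_len(m - 2L), seq_len(m - 2L) + 1L, seq_len(m - 2L) + 2L),
    x = rep(c(1, -2, 1), each = m - 2L),
    dims = c(m - 2L, m)
  )
  P <- lambda * Matrix::crossprod(D)
  .als_cache[[key]] <- P
  P
}

als_baseline <- function(y, lambda, p, max_iter) {
  m <- length(y)
  if (m < 16L) stop("need at least 16 points for baseline estimation", call. = FALSE)
  P <- als_penalty(m, lambda)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(max_iter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(x = w) + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

#' Normalize a spectrum to unit total intensity
#'
#' Scales the intensities so that their sum over `[range_start,
#' range_stop]` equals 1, the convention used when overlaying spectra of
#' different absolute signal strength. Because every conformational index
#' in this package is a ratio of two intensities from the same spectrum,
#' normalization leaves all downstream ratio metrics unchanged.
#'
#' @param spectrum A [raman_spectrum()].
#' @param range_start,range_stop Wavenumber limits (cm^-1) of the
#'   normalization window; defaults cover the whole working range.
#' @return The rescaled [raman_spectrum()].
#' @export
normalize_total <- function(spectrum, range_start = -Inf, range_stop = Inf) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  sel <- spectrum$wavenumbers >= range_start & spectrum$wavenumbers <= range_stop
  if (!any(sel)) stop("normalization range contains no points", call. = FALSE)
  total <- sum(spectrum$intensities[sel])
  if (!(total > 0)) {
    stop("sum of intensities over the range is not positive; cannot normalize",
         call. = FALSE)
  }
  raman_spectrum(spectrum$wavenumbers, spectrum$intensities / total,
                 meta = spectrum$meta)
}
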