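#' Define a marker band
#'
#' A band definition names a heme vibrational mode, its nominal Raman
#' shift, and the half-width of the search window used when locating its
#' apex in a measured spectrum.
#'
#' @param name Short identifier, e.g. `"nu4_ox"` or `"ruffling_570"`.
#' @param nominal Nominal position in cm^-1, within the 400-1800 working
#'   range.
#' @param half_window Half-width of the apex search window in cm^-1,
#'   between 3 and 15. Default 8; tighter windows are used for marker sets
#'   whose members lie within ~10 cm^-1 of each other.
#' @param assignment Free-text mode assignment.
#' @return A one-row `data.frame` with columns `name`, `nominal`,
#'   `half_window`, `assignment`.
#' @export
band_def <- function(name, nominal, half_window = 8, assignment = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(nominal >= 400 && nominal <= 1800)) {
    stop("nominal position must lie in [400, 1800] cm-1", call. = FALSE)
  }
  if (!(half_window >= 3 && half_window <= 15)) {
    stop("half_window must lie in [3, 15] cm-1", call. = FALSE)
  }
  data.frame(name = name, nominal = as.numeric(nominal),
             half_window = as.numeric(half_window),
             assignment = assignment, stringsAsFactors = FALSE)
}

band_table <- function(...) do.call(rbind, list(...))

#' Marker-band table for a protein/redox condition
#'
#' Returns the set of heme marker bands used to characterize one
#' (protein, redox) condition: the nu4 normalizer of the matching redox
#' state, the heme-type markers (1306/1342 cm^-1 for heme b, 1313 cm^-1
#' for heme c), the porphyrin breathing band at 748 cm^-1, the CH3
#' side-radical and asymmetric pyrrole half-ring bands, the methine-bridge
#' planarity bands (1586/1590, 1638 cm^-1), and - for reduced cytochrome c
#' only - the ruffling (570 cm^-1) and C-S (640 cm^-1) bands.
#'
#' Adjacent marker sets (1306 vs 1313, and the nu4 family
#' 1365/1368/1371/1375) get a 5 cm^-1 half-window to prevent
#' cross-capture; all other bands use the 8 cm^-1 default.
#'
#' @param protein `"Ngb"` or `"CytC"`.
#' @param redox `"oxidized"` or `"reduced"`.
#' @return A `data.frame` of band definitions (see [band_def()]).
#' @export
default_band_table <- function(protein, redox) {
  key <- paste(protein, redox, sep = "/")
  switch(key,
    "Ngb/oxidized" = band_table(
      band_def("allbond_748", 748, 8, "all porphyrin ring bonds"),
      band_def("ch3", 1128, 8, "CH3 side-radical vibrations"),
      band_def("pyrrole_asym", 1168, 8, "asymmetric pyrrole half-ring"),
      band_def("heme_b_1306", 1306, 5, "heme b marker"),
      band_def("nu4_ox", 1375, 5, "nu4, symmetric pyrrole half-ring (Fe3+)"),
      band_def("methine_1586", 1586, 8, "methine bridge"),
      band_def("methine_1638", 1638, 8, "methine bridge")
    ),
    "Ngb/reduced" = band_table(
      band_def("allbond_748", 748, 8, "all porphyrin ring bonds"),
      band_def("ch3", 1128, 8, "CH3 side-radical vibrations"),
      band_def("pyrrole_asym", 1168, 8, "asymmetric pyrrole half-ring"),
      band_def("heme_b_1306", 1306, 5, "heme b marker"),
      band_def("heme_b_red_1342", 1342, 8, "heme b marker, reduced state"),
      band_def("nu4_red", 1368, 5, "nu4, symmetric pyrrole half-ring (Fe2+)"),
      band_def("methine_1586", 1586, 8, "methine bridge")
    ),
    "CytC/oxidized" = band_table(
      band_def("allbond_748", 748, 8, "all porphyrin ring bonds"),
      band_def("ch3", 1126, 8, "CH3 side-radical vibrations"),
      band_def("pyrrole_asym", 1170, 8, "asymmetric pyrrole half-ring"),
      band_def("heme_c_1313", 1313, 5, "heme c marker"),
      band_def("nu4_ox", 1371, 5, "nu4, symmetric pyrrole half-ring (Fe3+)"),
      band_def("methine_1586", 1586, 8, "methine bridge"),
      band_def("methine_1638", 1638, 8, "methine bridge")
    ),
    "CytC/reduced" = band_table(
      band_def("ruffling_570", 570, 8, "out-of-plane ruffling marker"),
      band_def("cs_640", 640, 8, "C-S stretch, Cys thioether links"),
      band_def("allbond_748", 748, 8, "all porphyrin ring bonds"),
      band_def("ch3", 1126, 8, "CH3 side-radical vibrations"),
      band_def("pyrrole_asym", 1170, 8, "asymmetric pyrrole half-ring"),
      band_def("heme_c_1313", 1313, 5, "heme c marker"),
      band_def("nu4_red", 1365, 5, "nu4, symmetric pyrrole half-ring (Fe2+)"),
      band_def("methine_1590", 1590, 8, "methine bridge")
    ),
    stop(sprintf("no band table for protein '%s' in redox state '%s'",
                 protein, redox), call. = FALSE)
  )
}

# indices of interior local maxima of y (strictly above at least one
# neighbour, not below either)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  up <- y[i] >= y[i - 1L] & y[i] >= y[i + 1L]
  strict <- y[i] > y[i - 1L] | y[i] > y[i + 1L]
  i[up & strict]
}

#' Quantify marker bands in a baseline-corrected spectrum
#'
#' For each band in `table`, locates the tallest interior local maximum
#' within `nominal +/- half_window` and reports its position and
#' baseline-corrected height (peak intensity is the apex height, not a
#' fitted area). If the window contains no interior local maximum, or the
#' apex intensity is negative, the in-window maximum is still reported but
#' flagged `found = FALSE` so that downstream ratio computations can
#' refuse it.
#'
#' @param spectrum A baseline-corrected [raman_spectrum()].
#' @param table A band table from [default_band_table()] or built with
#'   [band_def()].
#' @return A `data.frame` with one row per band: `band`, `nominal`,
#'   `position`, `height`, `found`.
#' @export
quantify_bands <- function(spectrum, table) {
  stopifnot(inherits(spectrum, "raman_spectrum"), is.data.frame(table))
  wn <- spectrum$wavenumbers
  y <- spectrum$intensities
  out <- vector("list", nrow(table))
  for (k in seq_len(nrow(table))) {
    lo <- table$nominal[k] - table$half_window[k]
    hi <- table$nominal[k] + table$half_window[k]
    if (lo < wn[1] || hi > wn[length(wn)]) {
      stop(sprintf("band '%s' window [%g, %g] not covered by spectrum",
                   table$name[k], lo, hi), call. = FALSE)
    }
    idx <- which(wn >= lo & wn <= hi)
    yw <- y[idx]
    lm <- local_maxima(yw)
    # a window-edge point can never be confirmed as a genuine apex
    lm <- lm[lm > 1L & lm < length(yw)]
    if (length(lm)) {
      best <- lm[which.max(yw[lm])]
      found <- yw[best] >= 0
    } else {
      best <- which.max(yw)
      found <- FALSE
    }
    out[[k]] <- data.frame(
      band = table$name[k], nominal = table$nominal[k],
      position = wn[idx[best]],
      height = yw[best],
      found = found, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect peaks by topographic prominence
#'
#' Screens a corrected spectrum for all interior local maxima whose
#' prominence (apex height minus the higher of the two flanking minima,
#' each taken between the apex and the nearest higher terrain or the
#' spectrum edge) reaches `min_prominence` times the maximum intensity.
#'
#' @param spectrum A baseline-corrected [raman_spectrum()].
#' @param min_prominence Prominence threshold as a fraction of the maximum
#'   intensity (> 0; values above 1 necessarily silence every peak).
#' @return A `data.frame` with columns `position` and `height`, sorted by
#'   position; zero rows when nothing qualifies.
#' @export
detect_peaks <- function(spectrum, min_prominence = 0.05) {
  stopifnot(inherits(spectrum, "raman_spectrum"), min_prominence > 0)
  wn <- spectrum$wavenumbers
  y <- spectrum$intensities
  cand <- local_maxima(y)
  if (!length(cand) || max(y) <= 0) {
    return(data.frame(position = numeric(0), height = numeric(0)))
  }
  thr <- min_prominence * max(y)
  prom <- vapply(cand, function(i) peak_prominence(y, i), 0)
  cand <- cand[prom >= thr]
  data.frame(position = wn[cand], height = y[cand])
}

# topographic prominence of the local maximum at index i: apex height
# minus the higher of the two flanking minima, each taken between the
# apex and the nearest higher terrain (or the trace edge)
peak_prominence <- function(y, i) {
  h <- y[i]
  left <- if (i > 1L) {
    seg <- y[1:(i - 1L)]
    higher <- which(seg > h)
    min(seg[if (length(higher)) (max(higher) + 1L):(i - 1L) else seq_along(seg)])
  } else h
  right <- if (i < length(y)) {
    seg <- y[(i + 1L):length(y)]
    higher <- which(seg > h)
    min(seg[if (length(higher)) 1L:(min(higher) - 1L) else seq_along(seg)])
  } else h
  h - max(left, right)
}
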