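#' Conformational intensity-ratio indices for one spectrum
#'
#' Computes the nu4-normalized ratio indices that characterize heme
#' conformation, from a table of band measurements (see
#' [quantify_bands()]):
#'
#' * `planarity` - methine-bridge over nu4 intensity; a decrease signals
#'   out-of-plane heme distortion (lower probability of the planar
#'   conformation). Uses I1638/I1375 (Ngb oxidized), I1586/I1368 (Ngb
#'   reduced; the 1638 band merges into 1586 upon reduction), I1638/I1371
#'   (CytC oxidized) or I1590/I1365 (CytC reduced).
#' * `pyrrole_mobility` - asymmetric over symmetric pyrrole half-ring
#'   intensity (I1168 or I1170 over nu4); a decrease signals reduced
#'   in-plane pyrrole mobility.
#' * `ch3_rigidity` - CH3 side-radical over nu4 intensity (I1128 or I1126
#'   over nu4); a decrease signals a more rigid heme microenvironment.
#' * `ruffling` - I570/I748, reduced cytochrome c only; tracks the
#'   probability of the ruffled heme conformation.
#' * `cs_mobility` - I640/I1365, reduced cytochrome c only; tracks
#'   mobility around the heme-cysteine thioether bonds.
#'
#' The nu4 band of the matching redox state is the sole normalizer for
#' all indices except `ruffling`, because its position and intensity do
#' not depend on out-of-plane heme deformation. Ratios not defined for
#' the condition are omitted (`NULL`), never zero-filled.
#'
#' @param measurements A `data.frame` from [quantify_bands()] covering the
#'   condition's band table.
#' @param protein `"Ngb"` or `"CytC"`.
#' @param redox `"oxidized"` or `"reduced"`.
#' @return An object of class `conformation_metrics`: a list with the
#'   ratio fields above plus `provenance` (numerator/denominator band
#'   names per ratio).
#' @export
compute_metrics <- function(measurements, protein, redox) {
  stopifnot(is.data.frame(measurements))
  defs <- ratio_definitions(protein, redox)

  get_height <- function(band, role) {
    row <- measurements[measurements$band == band, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop(sprintf("measurements do not cover band '%s'", band), call. = FALSE)
    }
    if (role == "denominator") {
      if (!row$found || row$height <= 0) {
        stop(sprintf("denominator band '%s' not found or non-positive", band),
             call. = FALSE)
      }
    }
    max(row$height, 0)
  }

  out <- list()
  prov <- list()
  for (metric in names(defs)) {
    num <- defs[[metric]][1]
    den <- defs[[metric]][2]
    out[[metric]] <- get_height(num, "numerator") / get_height(den, "denominator")
    prov[[metric]] <- c(numerator = num, denominator = den)
  }
  out$provenance <- prov
  out$protein <- protein
  out$redox <- redox
  class(out) <- "conformation_metrics"
  out
}

ratio_definitions <- function(protein, redox) {
  key <- paste(protein, redox, sep = "/")
  nu4 <- if (redox == "oxidized") "nu4_ox" else "nu4_red"
  base <- switch(key,
    "Ngb/oxidized" = list(planarity = c("methine_1638", nu4)),
    "Ngb/reduced" = list(planarity = c("methine_1586", nu4)),
    "CytC/oxidized" = list(planarity = c("methine_1638", nu4)),
    "CytC/reduced" = list(planarity = c("methine_1590", nu4)),
    stop(sprintf("no ratio definitions for protein '%s' in redox state '%s'",
                 protein, redox), call. = FALSE)
  )
  base$pyrrole_mobility <- c("pyrrole_asym", nu4)
  base$ch3_rigidity <- c("ch3", nu4)
  if (key == "CytC/reduced") {
    base$ruffling <- c("ruffling_570", "allbond_748")
    base$cs_mobility <- c("cs_640", nu4)
  }
  base
}

#' @export
print.conformation_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("<conformation_metrics> %s, %s\n", x$protein, x$redox))
  for (m in setdiff(names(x), c("provenance", "protein", "redox"))) {
    pv <- x$provenance[[m]]
    cat(sprintf("  %-17s %s  (%s / %s)\n", m, format(x[[m]], digits = digits),
                pv["numerator"], pv["denominator"]))
  }
  invisible(x)
}

#' @export
as.data.frame.conformation_metrics <- function(x, ...) {
  metrics <- setdiff(names(x), c("provenance", "protein", "redox"))
  data.frame(metric = metrics,
             value = vapply(metrics, function(m) x[[m]], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

# pull the height of the tallest interior local maximum of a corrected
# spectrum inside [lo, hi]; NA when none exists
window_apex <- function(spectrum, lo, hi) {
  wn <- spectrum$wavenumbers
  if (lo < wn[1] || hi > wn[length(wn)]) {
    stop(sprintf("spectrum does not cover [%g, %g] cm-1", lo, hi), call. = FALSE)
  }
  idx <- which(wn >= lo & wn <= hi)
  yw <- spectrum$intensities[idx]
  lm <- local_maxima(yw)
  lm <- lm[lm > 1L & lm < length(yw)]
  if (!length(lm)) return(c(position = NA_real_, height = NA_real_))
  best <- lm[which.max(yw[lm])]
  c(position = wn[idx[best]], height = yw[best])
}

# like window_apex, but reports the apex's topographic prominence
# measured on the full trace, which is robust against noise bumps riding
# on the flank of a neighbouring band
window_apex_prominence <- function(spectrum, lo, hi) {
  wn <- spectrum$wavenumbers
  if (lo < wn[1] || hi > wn[length(wn)]) {
    stop(sprintf("spectrum does not cover [%g, %g] cm-1", lo, hi), call. = FALSE)
  }
  y <- spectrum$intensities
  idx <- which(wn >= lo & wn <= hi)
  sub <- local_maxima(y)
  sub <- sub[sub %in% idx[-c(1L, length(idx))]]
  if (!length(sub)) return(NA_real_)
  best <- sub[which.max(y[sub])]
  peak_prominence(y, best)
}

#' Classify the heme type of a spectrum
#'
#' Compares the 1306 cm^-1 (heme b) and 1313 cm^-1 (heme c) marker
#' candidates by apex prominence: whichever is clearly more prominent
#' wins; when the prominence ratio falls within [0.8, 1.25] the call is
#' `indeterminate`, unless the reduced-state heme b marker at 1342 cm^-1
#' is also present, which casts a deciding vote for heme b.
#'
#' @param x A baseline-corrected [raman_spectrum()] covering 1290-1350
#'   cm^-1, or a measurement table from [quantify_bands()] containing the
#'   marker bands.
#' @return `"heme_b"`, `"heme_c"` or `"indeterminate"`.
#' @export
classify_heme_type <- function(x) {
  if (inherits(x, "raman_spectrum")) {
    h_b <- window_apex_prominence(x, 1306 - 5, 1306 + 5)
    h_c <- window_apex_prominence(x, 1313 - 4, 1313 + 4)
    p1342 <- tryCatch(window_apex_prominence(x, 1342 - 8, 1342 + 8),
                      error = function(e) NA_real_)
    scale <- max(x$intensities, 0)
    has_1342 <- is.finite(p1342) && p1342 > 0.05 * scale
  } else if (is.data.frame(x)) {
    pick <- function(band) {
      row <- x[x$band == band, , drop = FALSE]
      if (nrow(row) == 1L && row$found) row$height else NA_real_
    }
    h_b <- pick("heme_b_1306")
    h_c <- pick("heme_c_1313")
    has_1342 <- isTRUE(is.finite(pick("heme_b_red_1342")))
  } else {
    stop("x must be a raman_spectrum or a measurement data.frame", call. = FALSE)
  }
  ok_b <- is.finite(h_b) && h_b > 0
  ok_c <- is.finite(h_c) && h_c > 0
  if (!ok_b && !ok_c) return(if (has_1342) "heme_b" else "indeterminate")
  if (ok_b && !ok_c) return("heme_b")
  if (!ok_b && ok_c) return("heme_c")
  r <- h_b / h_c
  if (r > 1.25) return("heme_b")
  if (r < 0.8) return("heme_c")
  if (has_1342) "heme_b" else "indeterminate"
}

#' Classify the iron redox state of a spectrum
#'
#' Locates the nu4 apex (tallest interior local maximum in 1358-1382
#' cm^-1). The nu4 mode sits near 1375/1371 cm^-1 when the heme iron is
#' ferric and shifts to 1368/1365 cm^-1 upon reduction, so an apex at or
#' above 1370 cm^-1 is called `oxidized` and below 1370 cm^-1 `reduced`
#' (the boundary itself counts as oxidized).
#'
#' @param x A baseline-corrected [raman_spectrum()] covering 1355-1385
#'   cm^-1, or a measurement table from [quantify_bands()] containing a
#'   found nu4 band.
#' @return `"oxidized"`, `"reduced"` or `"indeterminate"`.
#' @export
classify_redox <- function(x) {
  if (inherits(x, "raman_spectrum")) {
    apex <- window_apex(x, 1358, 1382)
    pos <- apex["position"]
  } else if (is.data.frame(x)) {
    row <- x[x$band %in% c("nu4_ox", "nu4_red") & x$found, , drop = FALSE]
    if (nrow(row) == 0L) return("indeterminate")
    pos <- row$position[which.max(row$height)]
  } else {
    stop("x must be a raman_spectrum or a measurement data.frame", call. = FALSE)
  }
  if (!is.finite(pos)) return("indeterminate")
  if (pos >= 1370) "oxidized" else "reduced"
}
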