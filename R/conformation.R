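#' Heme conformation analysis of a replicated spectrum cohort
#'
#' Runs the full analysis chain on a set of labelled spectra: asymmetric
#' least squares baseline subtraction, total-intensity normalization,
#' marker-band quantification against the condition's band table,
#' nu4-normalized conformational ratio indices per replicate, per-variant
#' means with standard errors, and exact Mann-Whitney comparisons of
#' every variant against the reference and of all variant pairs.
#'
#' Ratios are computed per replicate spectrum, never on averaged
#' spectra; averaging happens only at the statistics layer, matching the
#' mean +/- SEM over independent replicate reporting convention.
#'
#' @param spectra A list of [raman_spectrum()] objects, each carrying
#'   [spectrum_meta()] with protein, variant, redox and replicate.
#'   Non-uniform axes are resampled to a 1 cm^-1 grid first.
#' @param reference Reference variant label (default `"WT"`).
#' @param smoothness,asymmetry,max_iter Baseline parameters, see
#'   [subtract_baseline()].
#' @param normalize Normalize each corrected spectrum to unit total
#'   intensity before quantification? Ratios are unaffected either way.
#' @param holm Add Holm-adjusted p-values to the comparison table?
#' @return An object of class `heme_conformation` with components
#'   `metrics` (tidy per-replicate table: variant, redox, modality,
#'   replicate, metric, value), `summary` (per-variant mean/SEM/n),
#'   `comparisons` (see [compare_all()]; `NULL` when only one variant is
#'   present), and `reference`.
#' @examples
#' cohort <- generate_cohort(
#'   conformation_state("Ngb", "oxidized"),
#'   variant_deltas = list(E60K = list(planarity = 0.8)),
#'   n_replicates = 3, seed = 7
#' )
#' fit <- heme_conformation(cohort)
#' fit
#' @export
heme_conformation <- function(spectra, reference = "WT",
                              smoothness = 1e5, asymmetry = 0.01,
                              max_iter = 10L, normalize = TRUE,
                              holm = FALSE) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "raman_spectrum")))
  rows <- list()
  for (s in spectra) {
    if (is.null(s$meta)) {
      stop("every spectrum needs metadata (protein, variant, redox, replicate)",
           call. = FALSE)
    }
    m <- s$meta
    if (!is_uniform_grid(s)) {
      rng <- range(s$wavenumbers)
      s <- resample_to_grid(s, ceiling(rng[1]), floor(rng[2]), 1)
    }
    corrected <- subtract_baseline(s, smoothness = smoothness,
                                   asymmetry = asymmetry,
                                   max_iter = max_iter)$corrected
    if (normalize) corrected <- normalize_total(corrected)
    tab <- default_band_table(m$protein, m$redox)
    meas <- quantify_bands(corrected, tab)
    met <- compute_metrics(meas, m$protein, m$redox)
    df <- as.data.frame(met)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = m$variant, redox = m$redox, modality = m$modality,
      replicate = m$replicate, metric = df$metric, value = df$value,
      stringsAsFactors = FALSE
    )
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  variants <- unique(metrics$variant)
  comparisons <- NULL
  if (length(variants) >= 2L && reference %in% variants) {
    comparisons <- compare_all(metrics, reference = reference, holm = holm)
  }
  structure(
    list(metrics = metrics, summary = summarize_metrics(metrics),
         comparisons = comparisons, reference = reference,
         n_spectra = length(spectra), call = match.call()),
    class = "heme_conformation"
  )
}

#' @export
print.heme_conformation <- function(x, ...) {
  cat(sprintf("<heme_conformation> %d spectra, %d variants, %d metrics\n",
              x$n_spectra, length(unique(x$metrics$variant)),
              length(unique(x$metrics$metric))))
  cat(sprintf("  reference: %s\n", x$reference))
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons[x$comparisons$marker != "ns", , drop = FALSE]
    cat(sprintf("  %d comparisons, %d significant at p < 0.05\n",
                nrow(x$comparisons), nrow(sig)))
  }
  invisible(x)
}

#' @export
summary.heme_conformation <- function(object, ...) {
  cat("Per-variant metric means (mean +/- SEM over replicates):\n\n")
  print(object$summary, row.names = FALSE, digits = 4)
  if (!is.null(object$comparisons)) {
    sig <- object$comparisons[object$comparisons$marker != "ns", , drop = FALSE]
    cat("\nSignificant comparisons (Mann-Whitney, two-sided):\n\n")
    if (nrow(sig)) print(sig, row.names = FALSE, digits = 4)
    else cat("  none at p < 0.05\n")
  }
  invisible(object$summary)
}

#' @export
coef.heme_conformation <- function(object, ...) {
  s <- object$summary
  variants <- unique(s$variant)
  metrics <- unique(s$metric)
  out <- matrix(NA_real_, length(variants), length(metrics),
                dimnames = list(variants, metrics))
  for (i in seq_len(nrow(s))) out[s$variant[i], s$metric[i]] <- s$mean[i]
  out
}

#' @export
plot.heme_conformation <- function(x, metric = NULL, ...) {
  s <- x$summary
  metrics <- unique(s$metric)
  if (!is.null(metric)) metrics <- intersect(metrics, metric)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(metrics)),
                       mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in metrics) {
    sub <- s[s$metric == m, , drop = FALSE]
    ord <- order(sub$variant != x$reference, sub$variant)
    sub <- sub[ord, , drop = FALSE]
    up <- sub$mean + ifelse(is.na(sub$sem), 0, sub$sem)
    mid <- graphics::barplot(sub$mean, names.arg = sub$variant, las = 2,
                             main = m, ylab = "ratio",
                             ylim = c(0, 1.15 * max(up)), ...)
    ok <- !is.na(sub$sem) & sub$sem > 0
    if (any(ok)) {
      graphics::arrows(mid[ok], sub$mean[ok] - sub$sem[ok],
                       mid[ok], sub$mean[ok] + sub$sem[ok],
                       angle = 90, code = 3, length = 0.04)
    }
  }
  invisible(x)
}
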