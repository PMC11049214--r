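# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: profiles are written out from their closed
# forms and the Mann-Whitney null distribution is enumerated directly.

# exact two-sided Mann-Whitney p by full enumeration of the C(n+m, n)
# group labelings (valid for tie-free samples)
mw_enum_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  labelings <- utils::combn(n + m, n)
  us <- apply(labelings, 2, function(ii) sum(ranks[ii]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

oracle_lorentz <- function(x, center, fwhm, height) {
  height / (1 + ((x - center) / (fwhm / 2))^2)
}

oracle_gauss <- function(x, center, fwhm, height) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  height * exp(-(x - center)^2 / (2 * sigma^2))
}

oracle_pseudo_voigt <- function(x, center, fwhm, height, mixing = 0.5) {
  mixing * oracle_lorentz(x, center, fwhm, height) +
    (1 - mixing) * oracle_gauss(x, center, fwhm, height)
}

# flat-metadata convenience
meta_for <- function(protein, redox, variant = "WT", replicate = 1L) {
  spectrum_meta(protein = protein, variant = variant, redox = redox,
                modality = if (redox == "oxidized") "SERS" else "RRS",
                replicate = replicate)
}

# measurement table with every band of a condition set to one height
flat_measurements <- function(protein, redox, height = 0.4) {
  tab <- default_band_table(protein, redox)
  data.frame(band = tab$name, nominal = tab$nominal, position = tab$nominal,
             height = height, found = TRUE, stringsAsFactors = FALSE)
}
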