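Package: hemeraman
Title: Quantitative Raman and SERS Analysis of Heme-Protein Conformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying heme conformation from resonance Raman
    (RRS) and surface-enhanced Raman (SERS) spectra of heme proteins such as
    neuroglobin and cytochrome c. Provides spectrum input/output with
    metadata sidecars, asymmetric least squares baseline subtraction,
    total-intensity normalization, marker-band quantification against
    curated band tables, nu4-normalized conformational intensity-ratio
    indices (heme planarity, pyrrole mobility, methyl-side rigidity,
    ruffling, C-S mobility), heme-type and redox-state classification,
    exact Mann-Whitney group comparisons for small replicate counts, and a
    pseudo-Voigt synthetic spectrum generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
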