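---
title: "Quantifying heme conformation from Raman and SERS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heme conformation from Raman and SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(hemeraman)
```

## The measurement problem

Resonance Raman (RRS) and surface-enhanced Raman (SERS) spectra of heme
proteins resolve individual vibrational modes of the porphyrin ring. The
intensity of a mode tracks the probability of the corresponding group
vibration, so changes in heme geometry — loss of planarity, ruffling,
stiffening of the protein pocket around the methyl side radicals —
register as changes in relative band intensities. For six-coordinate
heme proteins such as neuroglobin (Ngb, heme *b*) and cytochrome *c*
(Cyt *c*, heme *c*), a small set of marker bands carries most of the
conformational signal:

| band (cm⁻¹)       | assignment                                  | role |
|--------------------|---------------------------------------------|------|
| 748                | all porphyrin ring bonds ("breathing")      | reference for ruffling index |
| 1126/1128          | CH₃ side-radical vibrations                 | microenvironment rigidity |
| 1168/1170          | asymmetric pyrrole half-ring                | in-plane pyrrole mobility |
| 1306, 1342         | heme *b* markers (1342: reduced state only) | heme typing |
| 1313               | heme *c* marker                             | heme typing |
| 1365–1375          | ν₄, symmetric pyrrole half-ring             | redox marker and normalizer |
| 1586/1590, 1638    | methine-bridge stretches                    | heme planarity |
| 570 (heme *c*, Fe²⁺) | out-of-plane ruffling marker              | ruffling index |
| 640 (heme *c*)     | C–S stretch of the Cys thioether links      | C–S mobility index |

The ν₄ mode is the linchpin: its position reports the iron redox state
(≈1375/1371 cm⁻¹ ferric, shifting to ≈1368/1365 cm⁻¹ on reduction) while
its intensity is insensitive to out-of-plane heme deformation, which
makes it the natural internal normalizer for every conformation-sensitive
band. All indices this package computes are therefore dimensionless
intensity ratios:

* **planarity** — methine-bridge over ν₄ (I₁₆₃₈/I₁₃₇₅ for oxidized Ngb,
  I₁₅₈₆/I₁₃₆₈ reduced Ngb, I₁₆₃₈/I₁₃₇₁ oxidized Cyt *c*, I₁₅₉₀/I₁₃₆₅
  reduced Cyt *c*). Decrease ⇒ out-of-plane distortion. In the reduced
  state the 1638 cm⁻¹ band merges into the 1586 cm⁻¹ band, so the single
  merged band is used — no attempt is made to deconvolve it.
* **pyrrole mobility** — I₁₁₆₈(or ₁₁₇₀)/ν₄. Decrease ⇒ less in-plane
  pyrrole ring mobility.
* **CH₃ rigidity** — I₁₁₂₈(or ₁₁₂₆)/ν₄. Decrease ⇒ more rigid heme
  microenvironment.
* **ruffling** — I₅₇₀/I₇₄₈ and **C–S mobility** — I₆₄₀/I₁₃₆₅, both
  defined only for reduced Cyt *c*.

A deliberate design choice: *peak intensity means apex height, not
fitted area*. Ratios are formed from the baseline-corrected intensity at
the apex of each band, matching the I_x notation in common use, and no
multi-peak deconvolution is attempted anywhere. Ratios are computed per
replicate spectrum, never on averaged spectra; averaging happens only in
the statistics layer.

## Pipeline and parameters

`heme_conformation()` chains the stages; each is also exported on its
own.

**Grid.** The working axis is 400–1800 cm⁻¹ at 1 cm⁻¹, which covers
every band above with margin. Instrument grids differ, so
`resample_to_grid()` (linear interpolation, no extrapolation) is applied
to non-uniform input first. The 1 cm⁻¹ step bounds position accuracy:
a recovered apex can never be closer than the grid allows.

**Baseline.** Fluorescence-type backgrounds are removed by asymmetric
least squares (ALS): a Whittaker smoother whose weights are small
(`asymmetry`, default 0.01) above the running baseline and large (0.99)
below it, iterated to convergence (`max_iter` = 10 suffices; the weights
almost always freeze after 4–6 passes). `smoothness` (default 1e5 on the
1 cm⁻¹ grid) sets the stiffness penalty on second differences. These
defaults follow the common practice for Raman fluorescence backgrounds;
with them, a pure quadratic background is removed to well under 1 % of
its range and a 12 cm⁻¹-wide Lorentzian riding on it keeps its apex
height to within 5 %. Two properties worth knowing:

* ALS bites slightly into peaks — the baseline under a band is pulled up
  by roughly 1 % of band amplitude per pass at these defaults. Applying
  the correction twice therefore shifts apex heights by ≈1 % for bands
  of FWHM ≲ 12 cm⁻¹ and slightly more for wider or heavily
  Lorentzian-tailed bands. Since every index is a ratio of two
  similarly-bitten heights, the bias largely cancels.
* Negative post-correction intensities in noise troughs are retained,
  not clipped, to keep the noise model unbiased.

**Normalization.** `normalize_total()` rescales so intensities sum to 1
over a window (the convention used when overlaying spectra). All ratio
indices are exactly invariant under this (and any positive) rescaling,
so normalization placement is immaterial for the metrics — it exists for
comparable plotting.

**Band quantification.** `quantify_bands()` searches `nominal ±
half_window` for the tallest *interior* local maximum. The default
half-window is 8 cm⁻¹, tightened to 5 cm⁻¹ for the closely spaced marker
families (1306 vs 1313; the ν₄ family 1365/1368/1371/1375) so that
neighbouring markers cannot capture each other — the nearest distinct
bands in those families sit ~7 cm⁻¹ apart. A window without a genuine
interior maximum (or with a negative apex) is reported with `found =
FALSE`; ratio computation refuses an unusable ν₄ denominator rather than
silently producing nonsense.

**Classification.** `classify_redox()` calls a ν₄ apex at ≥ 1370 cm⁻¹
oxidized and below it reduced (the boundary counts as oxidized — a pure
convention, stated so it is testable). `classify_heme_type()` compares
the 1306 vs 1313 cm⁻¹ candidates by topographic *prominence* rather than
raw height: at realistic noise a bump riding on the flank of the
neighbouring marker can rival it in height but never in prominence.
Prominence ratios between 0.8 and 1.25 are called indeterminate unless
the reduced heme *b* marker at 1342 cm⁻¹ (prominence above 5 % of the
trace maximum) breaks the tie.

**Statistics.** Group comparisons use the two-sided Mann–Whitney test,
exact by construction whenever the combined sample is ≤ 16 and tie-free
— at the study's n = 5 vs 5 the attainable two-sided levels are
multiples of 2/252 ≈ 0.0079, so "p < 0.05" means U ≤ 2 and the test is
conservative (true size 8/252 ≈ 0.032). With ties or larger samples it
falls back to the normal approximation with tie and continuity
corrections; two completely tied samples return p = 1. Mutant-vs-reference
comparisons carry hash markers (# p < 0.05, ## p < 0.01), mutant-vs-mutant
pairs star markers. Raw p-values are reported — the convention here is
per-comparison significance — with Holm adjustment available as an
opt-in column. "Error of the mean" is the standard error, SD/√n.

## The synthetic generator

No public deposited spectra exist for the kind of mutant-panel
measurement campaign this package targets, so
`generate_spectrum()`/`generate_cohort()` produce surrogate data with
the band structure above: pseudo-Voigt profiles (FWHM 14 cm⁻¹, mixing
0.5) at the nominal marker positions, a smooth background (quadratic
plus an exponential tail toward the low-wavenumber edge, emulating
detector roll-off and residual fluorescence), and additive Gaussian
noise. Default amplitudes put ν₄ at 1.0 and the 748 cm⁻¹ band close
behind, with the reduced-state tables carrying the characteristic
intensity gains of 748, CH₃, the heme-type markers and the methine
region; `noise_sigma = 0.02` then corresponds to SNR 50 on the strongest
band. Replicates differ by independent noise and by log-normal per-band
amplitude jitter with 5 % relative SD — a modest hand-to-hand
variability typical of replicate biological preparations.

Conformational effects enter *multiplicatively* on band amplitudes
(`conformation_state`): a planarity multiplier scales the methine bands,
a rigidity-inverse multiplier the CH₃ band, and so on, while ν₄, 748 and
the heme-type markers stay fixed as invariant references. Because the
indices are ratios against those references, a multiplier p maps onto
its index linearly, which makes parameter recovery directly testable.

`variant_effect_presets()` encodes the mutant panels the analysis is
designed to resolve (Ngb E60K, E87K, K67E, K95E, E60K/E87K; Cyt *c*
K25E, K72E, K25E/K72E). Only effect *directions* are anchored in
observation — such panels are reported as annotated bar charts, not
numeric ratios — so magnitudes are this package's own, chosen once
under two constraints:
they preserve the reported ordering (the double mutant E60K/E87K shows
the strongest planarity loss; reduced E87K and Cyt *c* K72E stay
WT-like), and effects reported as significant are sized to be reliably
detectable by the exact test at n = 5 (planarity multipliers 0.60–0.75).
An effect too small to detect at n = 5 would contradict the reported
outcome, so this sizing is a consistency requirement, not a free lunch.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: SERS enhancement physics and its
site-to-site variability, cosmic-ray spikes, wavenumber calibration
error, band-shape changes (only amplitudes vary), correlated baseline
drift between replicates, and any absolute intensity scale. Conclusions
from the synthetic suite concern the *analysis chain*, not the
spectroscopy.

## Numerical choices and degenerate inputs

* Apex ties on a plateau: a point qualifies as a local maximum if it is
  ≥ both neighbours and > at least one; an all-flat window has no
  maximum and is reported `found = FALSE` (a zero spectrum quantifies to
  all-zero heights, nothing found).
* The ν₄ denominator must be a found, positive apex; otherwise the
  metric computation errors by band name.
* Exact-test fallback: `NaN` from a zero-variance tie situation is
  mapped to p = 1.
* Duplicate wavenumbers are rejected at construction; descending axes
  are sorted with intensities co-sorted.
* `resample_to_grid()` refuses any request outside the recorded range —
  no extrapolation, ever.
* Single-replicate groups summarize with `sem = NA` rather than 0.
* Baseline estimation needs ≥ 16 points; short toy spectra are fine
  everywhere else.

## Problem sizes used in the shipped checks

The validation suite runs entirely on generated data: cohorts of 5
replicates per variant; 20 seeds for the parameter-recovery sweep over
planarity multipliers {0.5, 0.75, 1.0}; 200 simulated campaigns for the
direction-of-effect rates (flagging each configured Ngb planarity
decrease in ≥ 95 % of campaigns, flagging the null mutant K72E in ≤ 10 %);
2000 null draws for the empirical size of the exact test. These sizes
give stable rates (binomial SE ≈ 1.5 % at 200 draws) while keeping the
whole suite to a few minutes on one core.

## A worked example

```{r example}
cohort <- generate_cohort(
  conformation_state("Ngb", "oxidized"),
  variant_deltas = variant_effect_presets("Ngb", "oxidized"),
  n_replicates = 5, seed = 42
)
fit <- heme_conformation(cohort)
summary(fit)
```

```{r plot, fig.height = 4}
plot(fit, metric = "planarity")
```

## Known limitations

* Apex positions of weak bands (e.g. the 640 cm⁻¹ C–S band at local SNR
  ≈ 15) jitter by a few cm⁻¹ per replicate; report positions as medians
  over replicates, as `heme_conformation()`'s underlying measurements
  allow and the shipped checks do.
* The merged 1586/1638 region in reduced spectra is treated as one band;
  planarity comparisons across redox states are therefore not on a
  common scale and are never made by this package.
* ALS baseline parameters are a reproducible default, not a
  reconstruction of any particular instrument's workflow; absolute ratio
  values shift by a few percent under other defensible baselines, while
  within-cohort *comparisons* are robust because the bias is shared.
* The oxidized Cyt *c* ν₄ window is centred at 1371 cm⁻¹ (the position
  the ratio definitions use); spectra whose oxidized ν₄ sits at 1375
  cm⁻¹ are still captured by the ±5 cm⁻¹ window.
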