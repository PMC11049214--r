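test_that("state multipliers scale only the bands they govern", {
  cfg <- generator_config("Ngb", "oxidized")
  wt <- conformation_state("Ngb", "oxidized")

  # identity at the wild-type reference
  expect_equal(state_to_band_amplitudes(wt, cfg), cfg$base_amplitudes)

  # planarity hits the methine bands and nothing else
  st <- conformation_state("Ngb", "oxidized", planarity = 0.6)
  amps <- state_to_band_amplitudes(st, cfg)
  base <- cfg$base_amplitudes
  expect_equal(amps[["methine_1638"]], 0.6 * base[["methine_1638"]])
  expect_equal(amps[["methine_1586"]], 0.6 * base[["methine_1586"]])
  expect_equal(amps[["nu4_ox"]], base[["nu4_ox"]])
  expect_equal(amps[["allbond_748"]], base[["allbond_748"]])

  # rigidity_inverse on reduced CytC scales only the CH3 band, field by field
  cfg_c <- generator_config("CytC", "reduced")
  st_c <- conformation_state("CytC", "reduced", rigidity_inverse = 0.7)
  amps_c <- state_to_band_amplitudes(st_c, cfg_c)
  base_c <- cfg_c$base_amplitudes
  for (band in names(base_c)) {
    expected <- if (band == "ch3") 0.7 * base_c[[band]] else base_c[[band]]
    expect_equal(amps_c[[band]], expected)
  }

  # validation: multiplier range, unknown bands, condition mismatch
  expect_error(conformation_state("Ngb", "oxidized", planarity = 0), "0, 3")
  expect_error(conformation_state("Ngb", "oxidized", ruffling = 3.5), "0, 3")
  expect_error(generator_config("Ngb", "oxidized",
                                base_amplitudes = c(bogus_band = 1)),
               "unknown band")
  expect_error(state_to_band_amplitudes(st_c, cfg), "different conditions")
})

test_that("generate_spectrum is deterministic and faithful to its model", {
  cfg <- generator_config("Ngb", "oxidized")
  st <- conformation_state("Ngb", "oxidized")

  # same seed, bit-identical output
  s1 <- generate_spectrum(st, cfg, seed = 123)
  s2 <- generate_spectrum(st, cfg, seed = 123)
  expect_identical(s1$intensities, s2$intensities)
  expect_false(identical(
    s1$intensities, generate_spectrum(st, cfg, seed = 124)$intensities
  ))

  # all amplitudes zero, no noise: the pure background curve
  amps0 <- cfg$base_amplitudes * 0
  cfg0 <- generator_config("Ngb", "oxidized", base_amplitudes = amps0,
                           noise_sigma = 0)
  s0 <- generate_spectrum(st, cfg0, seed = 1)
  grid <- s0$wavenumbers
  t <- (grid - 400) / 1400
  expected <- 0.6 - 0.3 * t + 0.1 * t^2 + 0.8 * exp(-(grid - 400) / 300)
  expect_equal(s0$intensities, expected)

  # noiseless apex positions land within 1 cm-1 of the nominal positions
  cfg_q <- generator_config("CytC", "reduced", noise_sigma = 0)
  sq <- generate_spectrum(conformation_state("CytC", "reduced"), cfg_q,
                          seed = 1)
  corr <- subtract_baseline(sq)$corrected
  q <- quantify_bands(corr, default_band_table("CytC", "reduced"))
  expect_true(all(q$found))
  expect_true(all(abs(q$position - q$nominal) <= 1))

  # metadata is populated from the state; oxidized samples are SERS
  expect_equal(s1$meta$protein, "Ngb")
  expect_equal(s1$meta$redox, "oxidized")
  expect_equal(s1$meta$modality, "SERS")
  expect_equal(sq$meta$modality, "RRS")
})

test_that("cohorts are replicated, jittered, and deterministic", {
  wt <- conformation_state("Ngb", "oxidized")
  deltas <- variant_effect_presets("Ngb", "oxidized")

  # 6 variants (WT + 5 mutants) x 5 replicates = 30 spectra
  cohort <- generate_cohort(wt, deltas, n_replicates = 5, seed = 10)
  expect_length(cohort, 30)
  labels <- vapply(cohort, function(s) s$meta$variant, "")
  expect_equal(sort(unique(labels)),
               sort(c("WT", "K95E", "K67E", "E60K", "E87K", "E60K/E87K")))
  expect_true(all(table(labels) == 5))

  # zero jitter and zero noise make replicates of a variant identical
  cfg0 <- generator_config("Ngb", "oxidized", noise_sigma = 0)
  still <- generate_cohort(wt, list(E60K = list(planarity = 0.8)),
                           n_replicates = 3, replicate_jitter = 0,
                           config = cfg0, seed = 4)
  wt_reps <- Filter(function(s) s$meta$variant == "WT", still)
  expect_identical(wt_reps[[1]]$intensities, wt_reps[[2]]$intensities)
  expect_identical(wt_reps[[2]]$intensities, wt_reps[[3]]$intensities)

  # full determinism under a seed
  again <- generate_cohort(wt, deltas, n_replicates = 5, seed = 10)
  expect_identical(lapply(cohort, `[[`, "intensities"),
                   lapply(again, `[[`, "intensities"))

  expect_error(generate_cohort(wt, list(), n_replicates = 5), "non-empty")
  expect_error(generate_cohort(wt, deltas, n_replicates = 1), ">= 2")
  expect_error(generate_cohort(wt, list(X = list(nonsense = 2))),
               "unknown state field")
})

test_that("generated spectra reproduce the oxidized/reduced signatures", {
  mk <- function(protein, redox) {
    cfg <- generator_config(protein, redox)
    s <- generate_spectrum(conformation_state(protein, redox), cfg, seed = 5)
    subtract_baseline(s)$corrected
  }
  ngb_ox <- mk("Ngb", "oxidized"); ngb_red <- mk("Ngb", "reduced")
  cyt_ox <- mk("CytC", "oxidized"); cyt_red <- mk("CytC", "reduced")

  nu4_pos <- function(s) {
    q <- quantify_bands(s, band_def("nu4", 1371.5, 13.5))
    q$position
  }
  # nu4 shifts down upon reduction
  expect_gte(nu4_pos(ngb_ox), 1370)
  expect_lt(nu4_pos(ngb_red), 1370)
  expect_gte(nu4_pos(cyt_ox), 1370)
  expect_lt(nu4_pos(cyt_red), 1370)

  # the reduced heme b marker at 1342 appears only in reduced Ngb:
  # tall there, nothing but noise in the oxidized spectrum
  h1342 <- function(s) quantify_bands(s, band_def("m1342", 1342, 8))$height
  expect_gt(h1342(ngb_red), 0.5)
  expect_lt(h1342(ngb_ox), 0.15)

  # heme-type markers: 1306 for Ngb, 1313 for CytC
  expect_equal(classify_heme_type(ngb_ox), "heme_b")
  expect_equal(classify_heme_type(cyt_ox), "heme_c")

  # reduction boosts the 748, CH3 and methine-region intensities
  h <- function(s, name, pos, hw = 8) {
    quantify_bands(s, band_def(name, pos, hw))$height
  }
  expect_gt(h(ngb_red, "b748", 748), h(ngb_ox, "b748", 748))
  expect_gt(h(ngb_red, "ch3", 1128), h(ngb_ox, "ch3", 1128))
  expect_gt(h(ngb_red, "methine", 1586), h(ngb_ox, "methine", 1586))
})
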