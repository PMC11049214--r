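test_that("ratio indices follow the condition-specific definitions", {
  # equal heights everywhere -> every ratio is exactly 1
  for (cond in list(c("Ngb", "oxidized"), c("Ngb", "reduced"),
                    c("CytC", "oxidized"), c("CytC", "reduced"))) {
    m <- compute_metrics(flat_measurements(cond[1], cond[2], 0.4),
                         cond[1], cond[2])
    expect_equal(m$planarity, 1)
    expect_equal(m$pyrrole_mobility, 1)
    expect_equal(m$ch3_rigidity, 1)
  }

  # ruffling and C-S mobility exist only for reduced cytochrome c
  red_c <- compute_metrics(flat_measurements("CytC", "reduced"),
                           "CytC", "reduced")
  expect_equal(red_c$ruffling, 1)
  expect_equal(red_c$cs_mobility, 1)
  ox_c <- compute_metrics(flat_measurements("CytC", "oxidized"),
                          "CytC", "oxidized")
  expect_null(ox_c$ruffling)
  expect_null(ox_c$cs_mobility)
  ngb <- compute_metrics(flat_measurements("Ngb", "reduced"), "Ngb", "reduced")
  expect_null(ngb$ruffling)

  # provenance records the planarity numerator per condition
  expect_equal(unname(compute_metrics(flat_measurements("Ngb", "oxidized"),
    "Ngb", "oxidized")$provenance$planarity["numerator"]), "methine_1638")
  expect_equal(unname(ngb$provenance$planarity["numerator"]), "methine_1586")
  expect_equal(unname(red_c$provenance$planarity["numerator"]), "methine_1590")

  # unusable nu4 denominator and missing coverage are refused by name
  bad <- flat_measurements("Ngb", "oxidized")
  bad$found[bad$band == "nu4_ox"] <- FALSE
  expect_error(compute_metrics(bad, "Ngb", "oxidized"), "nu4_ox")
  expect_error(
    compute_metrics(flat_measurements("Ngb", "oxidized"), "CytC", "reduced"),
    "cover"
  )
})

test_that("planarity tracks the methine amplitude through the full chain", {
  amps <- c(
    allbond_748 = 0.9, ch3 = 0.45, pyrrole_asym = 0.4, heme_b_1306 = 0.35,
    nu4_ox = 1.0, methine_1586 = 0.55, methine_1638 = 0.5
  )
  cfg <- generator_config("Ngb", "oxidized", base_amplitudes = amps,
                          noise_sigma = 0)
  st <- conformation_state("Ngb", "oxidized")
  s <- generate_spectrum(st, cfg, seed = 1)
  corr <- subtract_baseline(s)$corrected
  met <- compute_metrics(
    quantify_bands(corr, default_band_table("Ngb", "oxidized")),
    "Ngb", "oxidized"
  )
  # amplitude ratio 0.5; small band-overlap and baseline residuals allowed
  expect_lt(abs(met$planarity - 0.5), 0.05 * 0.5)

  # reducing the methine amplitude by 40% strictly lowers planarity
  st2 <- conformation_state("Ngb", "oxidized", planarity = 0.6)
  s2 <- generate_spectrum(st2, cfg, seed = 1)
  met2 <- compute_metrics(
    quantify_bands(subtract_baseline(s2)$corrected,
                   default_band_table("Ngb", "oxidized")),
    "Ngb", "oxidized"
  )
  expect_lt(met2$planarity, met$planarity)
})

test_that("every ratio is exactly invariant under positive rescaling", {
  cfg <- generator_config("CytC", "reduced")
  s <- generate_spectrum(conformation_state("CytC", "reduced"), cfg, seed = 9)
  corr <- subtract_baseline(s)$corrected
  tab <- default_band_table("CytC", "reduced")
  m1 <- compute_metrics(quantify_bands(corr, tab), "CytC", "reduced")
  scaled <- raman_spectrum(corr$wavenumbers, 13.7 * corr$intensities,
                           meta = corr$meta)
  m2 <- compute_metrics(quantify_bands(scaled, tab), "CytC", "reduced")
  for (f in c("planarity", "pyrrole_mobility", "ch3_rigidity",
              "ruffling", "cs_mobility")) {
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-12)
  }
})

test_that("heme-type and redox classifiers reproduce the marker logic", {
  mk <- function(protein, redox) {
    cfg <- generator_config(protein, redox)
    s <- generate_spectrum(conformation_state(protein, redox), cfg,
                           seed = 21)
    subtract_baseline(s)$corrected
  }
  ngb_ox <- mk("Ngb", "oxidized")
  ngb_red <- mk("Ngb", "reduced")
  cyt_ox <- mk("CytC", "oxidized")
  cyt_red <- mk("CytC", "reduced")

  expect_equal(classify_heme_type(ngb_ox), "heme_b")
  expect_equal(classify_heme_type(ngb_red), "heme_b")
  expect_equal(classify_heme_type(cyt_ox), "heme_c")
  expect_equal(classify_heme_type(cyt_red), "heme_c")

  expect_equal(classify_redox(ngb_ox), "oxidized")
  expect_equal(classify_redox(ngb_red), "reduced")
  expect_equal(classify_redox(cyt_ox), "oxidized")
  expect_equal(classify_redox(cyt_red), "reduced")

  # flat spectrum: no markers at all
  grid <- seq(400, 1800, 1)
  flat <- raman_spectrum(grid, rep(0, length(grid)))
  expect_equal(classify_heme_type(flat), "indeterminate")
  expect_equal(classify_redox(flat), "indeterminate")

  # boundary rule: a nu4 apex exactly at 1370 counts as oxidized
  edge <- raman_spectrum(grid, oracle_pseudo_voigt(grid, 1370, 14, 1))
  expect_equal(classify_redox(edge), "oxidized")
  just_below <- raman_spectrum(grid, oracle_pseudo_voigt(grid, 1369, 14, 1))
  expect_equal(classify_redox(just_below), "reduced")

  # measurement-table interface agrees with the spectrum interface
  q <- quantify_bands(ngb_red, default_band_table("Ngb", "reduced"))
  expect_equal(classify_heme_type(q), "heme_b")
  expect_equal(classify_redox(q), "reduced")
})
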