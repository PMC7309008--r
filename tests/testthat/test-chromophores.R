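test_that("table interpolation is exact at nodes and linear between them", {
  tab <- chromophore_table(c(600, 610, 620), c(100, 200, 400),
                           c(1000, 900, 700))
  expect_equal(interpolate_extinction(tab, 610),
               c(eps_hbo2 = 200, eps_hb = 900))
  expect_equal(interpolate_extinction(tab, 605),
               c(eps_hbo2 = 150, eps_hb = 950))
  expect_error(interpolate_extinction(tab, 599), "outside")
  expect_error(interpolate_extinction(tab, 621), "outside")
})

test_that("bundled synthetic table anchors the canonical channel values", {
  tab <- hemoglobin_extinction()
  expect_equal(unname(interpolate_extinction(tab, 660)),
               c(319.6, 3226.56), tolerance = 1e-6)
  expect_equal(unname(interpolate_extinction(tab, 940)),
               c(1214, 693.44), tolerance = 1e-6)
  # physiological orderings that make dual-wavelength oximetry work
  expect_gt(interpolate_extinction(tab, 660)[["eps_hb"]],
            interpolate_extinction(tab, 660)[["eps_hbo2"]])
  expect_gt(interpolate_extinction(tab, 940)[["eps_hbo2"]],
            interpolate_extinction(tab, 940)[["eps_hb"]])
})

test_that("near-monochromatic source on a flat detector recovers the table value", {
  tab <- hemoglobin_extinction()
  grid <- fine_grid(0.05, 600, 1000)
  flat <- detector_spectrum(synthetic_detector("flat"), grid)
  for (lam in c(660, 940)) {
    led <- evaluate_band(gaussian_band(lam, 1), grid)
    eff <- effective_extinction(tab, led, flat)
    ref <- interpolate_extinction(tab, lam)
    expect_lt(abs(eff[["eps_hbo2"]] - ref[["eps_hbo2"]]) /
                ref[["eps_hbo2"]], 0.005)
    expect_lt(abs(eff[["eps_hb"]] - ref[["eps_hb"]]) /
                ref[["eps_hb"]], 0.005)
  }
})

test_that("a constant extinction table yields that constant for any pairing", {
  w <- seq(500, 1100, 1)
  tab <- chromophore_table(w, rep(42, length(w)), rep(7, length(w)))
  grid <- fine_grid()
  led <- evaluate_band(gaussian_band(880, 60), grid)
  pd <- detector_spectrum(synthetic_detector("ramp", grid), grid)
  eff <- effective_extinction(tab, led, pd)
  expect_equal(eff[["eps_hbo2"]], 42, tolerance = 1e-10)
  expect_equal(eff[["eps_hb"]], 7, tolerance = 1e-10)
})

test_that("linear extinction under a symmetric weight evaluates at the weight centroid", {
  tab <- linear_extinction()
  grid <- fine_grid(0.05)
  led <- evaluate_band(gaussian_band(800, 40), grid)
  flat <- detector_spectrum(synthetic_detector("flat"), grid)
  eff <- effective_extinction(tab, led, flat)
  # independent quadrature oracle: centroid of the weight, then the line
  cw <- centroid_wavelength(led)
  expect_equal(eff[["eps_hbo2"]], 2 * cw + 100, tolerance = 1e-6)
  expect_equal(eff[["eps_hb"]], -1.5 * cw + 2500, tolerance = 1e-6)
})

test_that("effective extinction is invariant under rescaling and stays within bounds", {
  tab <- hemoglobin_extinction()
  grid <- fine_grid()
  led <- evaluate_band(gaussian_band(700, 30), grid)
  pd <- detector_spectrum(synthetic_detector("gaussian"), grid)
  eff <- effective_extinction(tab, led, pd)
  led5 <- ox_spectrum(led$wavelength, led$value * 5)
  pd3 <- ox_spectrum(pd$wavelength, pd$value * 0.3, kind = "sensitivity")
  expect_equal(effective_extinction(tab, led5, pd3), eff)

  supp <- led$wavelength[led$value > 1e-6]
  supp <- supp[supp >= 400 & supp <= 1100]
  eps_rng <- range(interpolate_extinction(tab, supp)[, "eps_hb"])
  expect_gte(eff[["eps_hb"]], eps_rng[1])
  expect_lte(eff[["eps_hb"]], eps_rng[2])
})

test_that("disjoint pairing raises a degenerate-pairing error", {
  tab <- hemoglobin_extinction()
  led <- evaluate_band(gaussian_band(660, 10), seq(600, 720, 0.5))
  pd <- ox_spectrum(seq(900, 1000, 0.5),
                    rep(1, length(seq(900, 1000, 0.5))),
                    kind = "sensitivity")
  expect_error(suppressWarnings(effective_extinction(tab, led, pd)),
               "degenerate pairing")
})

test_that("shift table: monochromatic pair on a flat detector has zero shifts", {
  tab <- hemoglobin_extinction()
  p <- source_detector_pair(
    light_source("r", gaussian_band(660, 0.5)),
    light_source("i", gaussian_band(940, 0.5)),
    synthetic_detector("flat"))
  st <- shift_table(p, tab, grid = fine_grid(0.05, 600, 1000))
  expect_true(all(abs(st$shift_hbo2) < 0.5))
  expect_true(all(abs(st$shift_hb) < 2))
})

test_that("a detector peaking below the IR source pulls epsilon toward shorter wavelengths", {
  tab <- linear_extinction()   # monotone eps makes the sign readable
  det <- photodetector("below", gaussian_band(850, 100))
  p <- source_detector_pair(light_source("r", gaussian_band(660, 20)),
                            light_source("i", gaussian_band(940, 50)), det)
  st <- shift_table(p, tab, grid = fine_grid(0.1))
  ir <- st[st$channel == "ir", ]
  eb <- effective_band_exact(gaussian_band(940, 50), gaussian_band(850, 100))
  # effective epsilon should equal the line at the shifted effective center
  expect_lt(eb$lambda_eff, 940)
  expect_equal(ir$eps_hbo2_eff, 2 * eb$lambda_eff + 100, tolerance = 1e-3)
  # sign rule: eps moves the way the line moves when lambda drops
  expect_lt(ir$shift_hbo2, 0)   # increasing line, shift down
  expect_gt(ir$shift_hb, 0)     # decreasing line, shift up
})

test_that("shift magnitude grows with source FWHM, other things equal", {
  tab <- hemoglobin_extinction()
  det <- synthetic_detector("midpeak")
  grid <- default_grid()
  pd <- detector_spectrum(det, grid)
  for (lam in c(660, 940)) {
    shifts <- vapply(c(10, 30, 50), function(f) {
      led <- evaluate_band(gaussian_band(lam, f), grid)
      eff <- effective_extinction(tab, led, pd)
      ref <- interpolate_extinction(tab, lam)
      abs(eff[["eps_hb"]] - ref[["eps_hb"]])
    }, numeric(1))
    expect_true(all(diff(shifts) > 0))
  }
})
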