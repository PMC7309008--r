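test_that("absorbance follows the Beer-Lambert definition", {
  expect_equal(absorbance(1, 1), 0)
  expect_equal(absorbance(exp(-1), 1), 1)
  # single chromophore forward then inverted: eps=1, c=2, d=3 -> A = 6
  expect_equal(absorbance(exp(-1 * 2 * 3), 1), 6)
  expect_error(absorbance(0, 1), "positive")
})

test_that("Beer-Lambert SpO2 reproduces direct substitutions", {
  eps <- toy_eps(hb1 = 2, hbo21 = 1, hb2 = 1, hbo22 = 2)
  expect_equal(spo2_bll(eps, 1), 50)
  # numerator vanishes at R = eps_hb_red / eps_hb_ir
  expect_equal(spo2_bll(eps, 2), 0)
  eps2 <- toy_eps()
  expect_equal(spo2_bll(eps2, 3000 / 700), 0)
})

test_that("Beer-Lambert SpO2 is strictly decreasing in R for physiological orderings", {
  eps <- nominal_coefficients(hemoglobin_extinction())
  r <- seq(0.3, 3, length.out = 200)
  expect_true(all(diff(spo2_bll(eps, r)) < 0))
})

test_that("the singular ratio is rejected", {
  eps <- toy_eps(hb1 = 2, hbo21 = 1, hb2 = 2, hbo22 = 1)
  # denominator: 1 - R
  expect_error(spo2_bll(eps, 1), "singularity")
})

test_that("the default linear line gives the textbook values", {
  line <- calibration_line()
  expect_identical(spo2_linear(line, 0), 110)
  expect_identical(spo2_linear(line, 1), 85)
  expect_identical(spo2_linear(line, 0.4), 100)
  expect_equal(spo2_linear(line, 0, clamp = TRUE), 100)
  expect_equal(coef(line), c(a = -25, b = 110))
  expect_equal(predict(line, 0.4), 100)
})

test_that("ratio_at_spo2 inverts the Beer-Lambert formula", {
  eps <- nominal_coefficients(hemoglobin_extinction())
  for (s in c(70, 90, 97, 100))
    expect_equal(spo2_bll(eps, ratio_at_spo2(eps, s)), s)
})

test_that("least squares recovers an exactly linear relation", {
  # a coefficient set that makes the BLL formula exactly linear in R:
  # eps_hbo2_ir == eps_hb_ir makes the denominator constant
  eps <- toy_eps(hb1 = 2000, hbo21 = 1000, hb2 = 500, hbo22 = 500)
  # SpO2 = 100*(2000 - 500 R)/1000 = 200 - 50 R
  line <- fit_linear_calibration(eps, r_range = c(0.5, 2.5))
  expect_equal(coef(line)[["a"]], -50, tolerance = 1e-10)
  expect_equal(coef(line)[["b"]], 200, tolerance = 1e-10)
})

test_that("a narrow-range fit approximates the tangent of the BLL curve", {
  eps <- nominal_coefficients(hemoglobin_extinction())
  r0 <- 0.8
  line <- fit_linear_calibration(eps, r_range = c(r0 - 0.005, r0 + 0.005))
  h <- 1e-6
  slope <- (spo2_bll(eps, r0 + h) - spo2_bll(eps, r0 - h)) / (2 * h)
  expect_equal(coef(line)[["a"]], slope, tolerance = 1e-4)
})

test_that("fitting the canonical channels yields a negative slope and b > 100", {
  eps <- nominal_coefficients(hemoglobin_extinction())
  line <- fit_linear_calibration(eps)
  expect_lt(coef(line)[["a"]], 0)
  expect_gt(coef(line)[["b"]], 100)
})

test_that("error profile matches spreadsheet-style substitution at chosen points", {
  eps <- toy_eps()          # hb1 3000, hbo21 300, hb2 700, hbo22 1200
  line <- calibration_line()  # 110 - 25 R
  rr <- c(0.5, 1, 2)
  prof <- error_profile(eps, line, r_grid = rr)
  # independent arithmetic: bll = 100*(3000 - 700 R)/(2700 + 500 R)
  bll <- 100 * (3000 - 700 * rr) / (2700 + 500 * rr)
  lin <- 110 - 25 * rr
  expect_equal(prof$spo2_bll, bll)
  expect_equal(prof$spo2_linear, lin)
  expect_equal(prof$delta_spo2, (bll - lin) / bll * 100)
  # sign convention: approximation above the BLL gives a negative error
  expect_true(all(prof$delta_spo2[lin > bll] < 0))
})

test_that("error profile windows on the Beer-Lambert saturation", {
  eps <- nominal_coefficients(hemoglobin_extinction())
  prof <- error_profile(eps)
  expect_true(any(prof$in_window))
  expect_true(all(prof$spo2_bll[prof$in_window] >= 90 &
                    prof$spo2_bll[prof$in_window] <= 100))
  df <- as.data.frame(prof)
  expect_named(df, c("r", "spo2_bll", "spo2_linear", "delta_spo2",
                     "in_window"))
})

test_that("a line equal to the BLL curve gives an identically zero profile", {
  eps <- toy_eps(hb1 = 2000, hbo21 = 1000, hb2 = 500, hbo22 = 500)
  line <- calibration_line(a = -50, b = 200)   # exact linear BLL
  prof <- error_profile(eps, line, r_grid = seq(0.5, 2.5, length.out = 50))
  expect_true(all(abs(prof$delta_spo2) < 1e-10))
})

test_that("window maximum ignores errors outside the window", {
  eps <- nominal_coefficients(hemoglobin_extinction())
  prof <- error_profile(eps)
  m <- max_abs_error_in_window(prof)
  expect_lt(m, max(abs(prof$delta_spo2)))  # big errors live at low SpO2
  expect_equal(m, max(abs(prof$delta_spo2[prof$in_window])))
  # single-point window
  one <- error_profile(eps, r_grid = ratio_at_spo2(eps, 95))
  expect_equal(max_abs_error_in_window(one),
               abs(one$delta_spo2[1]))
})

test_that("model-swap antisymmetry holds up to the denominator ratio", {
  eps <- toy_eps()
  prof <- error_profile(eps, r_grid = seq(0.5, 2, length.out = 30))
  swapped <- (prof$spo2_linear - prof$spo2_bll) / prof$spo2_linear * 100
  expect_equal(swapped,
               -prof$delta_spo2 * prof$spo2_bll / prof$spo2_linear)
})

test_that("monochromatic consistency: narrow sources + flat detector track the table", {
  tab <- hemoglobin_extinction()
  grid <- fine_grid(0.05, 600, 1000)
  p <- source_detector_pair(
    light_source("r", gaussian_band(660, 0.3)),
    light_source("i", gaussian_band(940, 0.3)),
    synthetic_detector("flat"))
  eff <- effective_coefficients(p, tab, grid)
  mono <- nominal_coefficients(tab)
  rg <- seq(0.3, 3, length.out = 100)
  expect_equal(spo2_bll(eff, rg), spo2_bll(mono, rg), tolerance = 1e-3)
})

test_that("effective-vs-monochromatic disagreement grows with source FWHM", {
  tab <- hemoglobin_extinction()
  grid <- default_grid()
  det <- synthetic_detector("midpeak")
  mono <- nominal_coefficients(tab)
  rg <- seq(ratio_at_spo2(mono, 100), ratio_at_spo2(mono, 90),
            length.out = 50)
  dev_for <- function(fr, fi) {
    p <- source_detector_pair(light_source("r", gaussian_band(660, fr)),
                              light_source("i", gaussian_band(940, fi)),
                              det)
    eps <- effective_coefficients(p, tab, grid)
    max(abs(spo2_bll(eps, rg) - spo2_bll(mono, rg)))
  }
  red_sweep <- vapply(c(5, 20, 35, 50), dev_for, numeric(1), fi = 50)
  ir_sweep <- vapply(c(10, 30, 50, 70), function(f) dev_for(20, f),
                     numeric(1))
  expect_true(all(diff(red_sweep) > 0))
  expect_true(all(diff(ir_sweep) > 0))
})
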