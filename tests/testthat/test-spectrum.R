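test_that("Gaussian band evaluation matches the closed form", {
  b <- gaussian_band(660, 20)
  s <- evaluate_band(b, c(620, 650, 660, 670))
  expect_equal(s$value[3], 1)                      # peak
  expect_equal(s$value[c(2, 4)], c(0.5, 0.5))      # half max at +-fwhm/2
  expect_equal(s$value[1], 2^-16)                  # exp(-4 ln2 (40/20)^2)
  expect_error(evaluate_band(b, c(660, 650)), "ascending")
  expect_error(gaussian_band(660, 0), "fwhm")
})

test_that("half-maximum identity holds exactly for random bands", {
  set.seed(42)
  for (i in 1:25) {
    ctr <- runif(1, 500, 1000)
    fw <- runif(1, 5, 120)
    amp <- runif(1, 0.1, 3)
    b <- gaussian_band(ctr, fw, amp)
    s <- evaluate_band(b, sort(c(ctr - fw / 2, ctr, ctr + fw / 2)))
    expect_equal(s$value, c(amp / 2, amp, amp / 2))
  }
})

test_that("normalization scales to unit maximum and is idempotent", {
  s <- ox_spectrum(c(1, 2, 3), c(0, 2, 4))
  n <- normalize_spectrum(s)
  expect_equal(n$value, c(0, 0.5, 1))
  expect_equal(normalize_spectrum(n)$value, n$value)
  expect_error(normalize_spectrum(ox_spectrum(1:3, c(0, 0, 0))),
               "all-zero")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(ox_spectrum(c(1, 1, 2), c(1, 1, 1)), "ascending")
  expect_error(ox_spectrum(1:3, c(1, -1, 1)), "non-negative")
  expect_error(ox_spectrum(1:3, c(1, NA, 1)), "finite")
  expect_error(ox_spectrum(1:3, 1:2), "length")
})

test_that("resampling interpolates linearly and zero-pads outside", {
  s <- ox_spectrum(seq(600, 700, 10), seq(0, 10, 1))  # linear ramp
  same <- resample_to_grid(s, s$wavelength)
  expect_equal(same$value, s$value)
  half <- resample_to_grid(s, seq(600, 700, 5))
  expect_equal(half$value, seq(0, 10, 0.5))  # linear functions exact
  ext <- resample_to_grid(s, seq(500, 800, 50))
  expect_equal(ext$value[ext$wavelength < 600], c(0, 0))
  expect_equal(ext$value[ext$wavelength > 700], c(0, 0))
  expect_error(resample_to_grid(ox_spectrum(660, 1), 600:700),
               "single-point")
})

test_that("spectral product has the closed-form Gaussian-product peak", {
  grid <- fine_grid()
  a <- evaluate_band(gaussian_band(660, 20), grid)
  ones <- ox_spectrum(range(grid), c(1, 1))
  expect_equal(spectral_product(a, ones)$value,
               resample_to_grid(a, spectral_product(a, ones)$wavelength)$value)

  b <- evaluate_band(gaussian_band(800, 100), grid)
  p <- spectral_product(a, b)
  # closed-form product mean: 660 + (800-660) * 20^2/(20^2+100^2)
  mean_cf <- 660 + 140 * 400 / 10400
  step <- stats::median(diff(p$wavelength))
  expect_lt(abs(p$wavelength[which.max(p$value)] - mean_cf), step + 1e-9)
  expect_true(all(p$value >= 0))

  far <- evaluate_band(gaussian_band(400, 5), seq(380, 420, 0.5))
  near <- evaluate_band(gaussian_band(900, 5), seq(880, 920, 0.5))
  expect_warning(pz <- spectral_product(far, near), "disjoint")
  expect_true(all(pz$value == 0))
})

test_that("peak/FWHM extraction round-trips a band at 0.6 nm resolution", {
  grid <- seq(560, 760, by = 0.6)   # peak not on a grid node
  s <- evaluate_band(gaussian_band(660, 20), grid)
  pf <- peak_fwhm(s)
  expect_lt(abs(pf[["peak"]] - 660), 0.6)
  expect_lt(abs(pf[["fwhm"]] - 20), 0.6)
})

test_that("a sub-half-maximum stray peak does not disturb the FWHM", {
  grid <- fine_grid(0.6)
  v <- evaluate_band(gaussian_band(660, 20), grid)$value +
    evaluate_band(gaussian_band(940, 60, 0.3), grid)$value
  pf <- peak_fwhm(ox_spectrum(grid, v))
  expect_lt(abs(pf[["peak"]] - 660), 0.6)
  expect_lt(abs(pf[["fwhm"]] - 20), 0.6)
})

test_that("extraction fails cleanly without a half-maximum crossing", {
  ramp <- ox_spectrum(seq(600, 700, 1), seq(0, 1, 0.01))
  expect_error(peak_fwhm(ramp), "half-maximum crossing")
})

test_that("ties at the maximum resolve to the lowest wavelength", {
  s <- ox_spectrum(c(1, 2, 3, 4, 5), c(0, 1, 1, 1, 0))
  expect_equal(peak_fwhm(s)[["peak"]], 2)
})

test_that("band -> extract round trip is within one grid step", {
  set.seed(7)
  step <- 0.5
  for (i in 1:20) {
    ctr <- runif(1, 600, 950)
    fw <- runif(1, 10 * step, 80)   # fwhm >= 10 grid steps
    g <- seq(ctr - 4 * fw, ctr + 4 * fw, by = step)
    pf <- peak_fwhm(evaluate_band(gaussian_band(ctr, fw), g))
    expect_lt(abs(pf[["peak"]] - ctr), step + 1e-12)
    expect_lt(abs(pf[["fwhm"]] - fw), step + 1e-12)
  }
})

test_that("zero-skew band reduces exactly to the Gaussian band", {
  grid <- seq(800, 1080, 0.6)
  a <- evaluate_skewed_band(skewed_band(940, 42, 0), grid)
  b <- evaluate_band(gaussian_band(940, 42), grid)
  expect_identical(a$value, b$value)
})

test_that("skewed bands are normalized, peaked at the mode, and lean with the skew", {
  grid <- seq(700, 1200, 0.2)
  for (sk in c(-4, -1.5, 1.5, 4)) {
    s <- evaluate_skewed_band(skewed_band(940, 42, sk), grid)
    expect_equal(max(s$value), 1)
    expect_lt(abs(s$wavelength[which.max(s$value)] - 940), 0.2 + 1e-9)
    cw <- centroid_wavelength(s)
    expect_equal(sign(cw - 940), sign(sk))
  }
})

test_that("skewed band keeps its requested FWHM", {
  grid <- seq(700, 1200, 0.1)
  s <- evaluate_skewed_band(skewed_band(940, 42, 3), grid)
  expect_lt(abs(peak_fwhm(s)[["fwhm"]] - 42), 0.2)
})
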