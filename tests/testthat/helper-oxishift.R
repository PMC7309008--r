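# Shared fixtures, built in code.

# fine grid around the red/IR oximetry region
fine_grid <- function(step = 0.2, from = 550, to = 1050) {
  seq(from, to, by = step)
}

# toy extinction table, linear in wavelength per chromophore, over a range
linear_extinction <- function(from = 500, to = 1100, by = 1,
                              a1 = 2, b1 = 100, a2 = -1.5, b2 = 2500) {
  w <- seq(from, to, by = by)
  chromophore_table(w, a1 * w + b1, pmax(a2 * w + b2, 0),
                    source_tag = "toy-linear")
}

# named monochromatic-style coefficient set for direct SpO2 algebra
toy_eps <- function(hb1 = 3000, hbo21 = 300, hb2 = 700, hbo22 = 1200) {
  list(eps_hb_red = hb1, eps_hbo2_red = hbo21,
       eps_hb_ir = hb2, eps_hbo2_ir = hbo22)
}

# literal copy of the bundled component table for cell-for-cell checks
component_table_literal <- function() {
  data.frame(
    name = c("LHQ974", "SFH4050", "SFH4248", "VSMD66694", "VSMD66694",
             "SMT660/890", "SMT660/890", "SFH7050", "SFH7050", "SFH7050",
             "LED #1", "LED #1", "LED #2", "LED #2"),
    channel = c("red", "ir", "ir", "red", "ir", "red", "ir",
                "green", "red", "ir", "red", "ir", "red", "ir"),
    ds_lambda_dom = c(643, 850, 940, NA, NA, NA, NA, 530, 655, 940,
                      660, 905, NA, NA),
    ds_lambda_peak = c(660, 860, 950, 660, 940, 650, 890, 525, 660, 950,
                       NA, NA, NA, NA),
    ds_fwhm = c(20, 30, 42, 20, 40, 20, 75, 34, 17, 42, NA, NA, NA, NA),
    meas_lambda_peak = c(657, 857, 956, 662, 934, 657, 883, 532, 664,
                         954, 660, 899, 664, 895),
    meas_fwhm = c(19, 21, 35, 16, 57, 16, 46, 33, 15, 44, 21, 68, 22,
                  62))
}
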