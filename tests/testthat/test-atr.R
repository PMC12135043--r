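cfg_si_d2o <- optical_config(n1 = 3.42, n2 = 1.42, beta_inc = 60,
                             wavenumber = 2887)

test_that("penetration depth follows the evanescent-wave formula", {
  expect_equal(penetration_depth(cfg_si_d2o), 212.0956, tolerance = 1e-4)
  cfg2 <- optical_config(3.42, 1.42, 60, 1640)
  expect_equal(penetration_depth(cfg2), 373.3659, tolerance = 1e-4)
  expect_error(optical_config(n1 = 1.0, n2 = 1.42), "n1 > n2")
  # above-critical geometry is required, not just n1 > n2
  shallow <- optical_config(3.42, 1.42, 60)
  shallow$beta_inc <- 20  # below the 24.5 degree critical angle
  expect_error(penetration_depth(shallow), "critical angle")
})

test_that("interfacial field intensities match the two-phase thick-film formulas", {
  f <- interface_field_intensities(cfg_si_d2o)
  expect_equal(f$ex2, 0.98730, tolerance = 1e-4)
  expect_equal(f$ey2, 1.20831, tolerance = 1e-4)
  expect_equal(f$ez2, 1.28197, tolerance = 1e-4)
  # Ex2 vanishes exactly at the critical angle
  crit <- asin(1.42 / 3.42) * 180 / pi
  fc <- interface_field_intensities(optical_config(3.42, 1.42, crit + 1e-9))
  expect_lt(fc$ex2, 1e-6)
  # algebraic identity Ez2/Ex2 = sin2(b)/(sin2(b) - n21^2) for any config
  set.seed(3)
  for (i in 1:10) {
    n1 <- runif(1, 1.5, 4); n2 <- runif(1, 1.0, n1 - 0.2)
    bc <- asin(n2 / n1) * 180 / pi
    b <- runif(1, bc + 1, 89)
    fi <- interface_field_intensities(optical_config(n1, n2, b))
    s2 <- sin(b * pi / 180)^2
    expect_equal(fi$ez2 / fi$ex2, s2 / (s2 - (n2 / n1)^2), tolerance = 1e-10)
  }
})

test_that("three-phase thin-film mode rescales only the normal component", {
  f2 <- interface_field_intensities(cfg_si_d2o)
  cfg3 <- optical_config(3.42, 1.42, 60, 2887, n_film = 1.45)
  f3 <- interface_field_intensities(cfg3)
  expect_equal(f3$ex2, f2$ex2)
  expect_equal(f3$ey2, f2$ey2)
  expect_equal(f3$ez2, f2$ez2 * (1.42 / 1.45)^2)
})

test_that("band deconvolution recovers a single noiseless Gaussian to 4 digits", {
  truth <- band_model(2850, 12, 0, 0.05, 0.03)
  wn <- seq(2800, 2900, by = 0.25)
  spec <- polarized_spectrum(wn,
                             0.05 * pseudo_voigt(wn, 2850, 12, 0),
                             0.03 * pseudo_voigt(wn, 2850, 12, 0))
  fit <- deconvolve_bands(spec, band_model(2852, 10, 0, 0.02, 0.02),
                          c(2800, 2900), baseline_order = 0)
  expect_equal(fit$center, 2850, tolerance = 1e-4)
  expect_equal(fit$width, 12, tolerance = 1e-4)
  expect_equal(fit$amplitude_p, 0.05, tolerance = 1e-4)
  expect_equal(fit$amplitude_s, 0.03, tolerance = 1e-4)
  expect_equal(fit$area_p, truth$area_p, tolerance = 1e-4)
})

test_that("overlapping CH2 stretching bands are recovered within 2% in area", {
  bands <- data.frame(center = c(2850, 2921), width = c(14, 18),
                      shape_mix = c(0.3, 0.3), strength = c(0.02, 0.03),
                      theta_dip = c(67, 62))
  g <- gen_polarized_spectra(bands, cfg_si_d2o, noise_sd = 1e-4, seed = 5)
  seeds <- band_model(c(2848, 2923), c(12, 16), 0.2, 0.01, 0.01)
  fit <- deconvolve_bands(g$spectrum, seeds, c(2800, 3000))
  truth_area_p <- .pv_area_for_test(g$truth$amplitude_p, bands$width,
                                    bands$shape_mix)
  truth_area_s <- .pv_area_for_test(g$truth$amplitude_s, bands$width,
                                    bands$shape_mix)
  expect_true(all(abs(fit$area_p - truth_area_p) / truth_area_p < 0.02))
  expect_true(all(abs(fit$area_s - truth_area_s) / truth_area_s < 0.02))
})

test_that("a six-band CH-region fit leaves residuals at the noise level", {
  bands <- data.frame(
    center = c(2850, 2871, 2897, 2921, 2937, 2958),
    width = c(14, 16, 22, 18, 16, 14),
    shape_mix = 0.3,
    strength = c(0.020, 0.006, 0.010, 0.030, 0.009, 0.012),
    theta_dip = c(67, 60, 55, 62, 55, 50))
  g <- gen_polarized_spectra(bands, cfg_si_d2o, noise_sd = 1e-4,
                             baseline_p = c(0.002, 0.001),
                             baseline_s = c(0.001, -0.001), seed = 6)
  seeds <- band_model(bands$center + 1, bands$width - 2, 0.25, 0.01, 0.01)
  fit <- deconvolve_bands(g$spectrum, seeds, c(2800, 3000))
  expect_lt(attr(fit, "rms_residual"), 1.5e-4)
})

test_that("deconvolution rejects malformed inputs", {
  wn <- seq(2800, 2900, by = 1)
  spec <- polarized_spectrum(wn, rep(0, length(wn)), rep(0, length(wn)))
  expect_error(deconvolve_bands(spec, band_model(2950, 10), c(2800, 2900)),
               "inside the fit window")
  expect_error(deconvolve_bands(spec, band_model(2850, 10), c(2900, 2800)),
               "lo < hi")
})

test_that("dichroic ratio is the p/s area ratio", {
  b <- band_model(2850, 12, 0, amplitude_p = 2, amplitude_s = 1)
  expect_equal(dichroic_ratio(b), 2)
  beq <- band_model(2850, 12, 0, 1, 1)
  expect_equal(dichroic_ratio(beq), 1)
  b0 <- band_model(2850, 12, 0, 1, 0)
  expect_error(dichroic_ratio(b0), "zero s-polarised area")
  # a magic-angle band reproduces the isotropic ratio (Ex2+Ez2)/Ey2
  f <- interface_field_intensities(cfg_si_d2o)
  g <- gen_polarized_spectra(
    data.frame(center = 2850, width = 12, shape_mix = 0,
               strength = 0.02, theta_dip = acos(sqrt(1 / 3)) * 180 / pi),
    cfg_si_d2o, noise_sd = 0, seed = 1)
  expect_equal(g$truth$dichroic_ratio, (f$ex2 + f$ez2) / f$ey2,
               tolerance = 1e-10)
  expect_equal(g$truth$dichroic_ratio, 1.87806, tolerance = 1e-4)
})

test_that("order parameter from ratio hits its analytic anchor points", {
  f <- interface_field_intensities(cfg_si_d2o)
  r_iso <- (f$ex2 + f$ez2) / f$ey2
  expect_equal(order_parameter_from_ratio(r_iso, f), 0, tolerance = 1e-12)
  expect_equal(order_parameter_from_ratio(f$ex2 / f$ey2, f), -0.5,
               tolerance = 1e-12)
  s1 <- order_parameter_from_ratio(1, f)
  expect_equal(s1, -0.38096, tolerance = 1e-4)
  expect_equal(dipole_angle(s1), 73.638, tolerance = 1e-3)
  # below R = Ex2/Ey2 the implied S drops under -0.5: optics-inconsistent
  expect_error(order_parameter_from_ratio(0.1, f), "inconsistent")
})

test_that("S_dip grows (and theta_dip falls) monotonically in R", {
  # a band absorbing relatively more p light is more normal-aligned
  f <- interface_field_intensities(cfg_si_d2o)
  rs <- seq(0.9, 2.2, by = 0.1)
  ss <- vapply(rs, order_parameter_from_ratio, numeric(1L), f = f)
  expect_true(all(diff(ss) > 0))
  ths <- vapply(ss, dipole_angle, numeric(1L))
  expect_true(all(diff(ths) < 0))
})

test_that("dipole angle inverts the order parameter exactly", {
  expect_equal(dipole_angle(1), 0)
  expect_equal(dipole_angle(0), 54.7356, tolerance = 1e-4)
  expect_equal(dipole_angle(-0.5), 90)
  expect_error(dipole_angle(1.2), "\\[-0.5, 1\\]")
  for (th in seq(0, 90, by = 7.5)) {
    s <- (3 * cos(th * pi / 180)^2 - 1) / 2
    expect_equal(dipole_angle(s), th, tolerance = 1e-9)
  }
})

test_that("chain tilt from orthogonal TDM angles matches geometry", {
  expect_equal(chain_tilt_from_tdm_angles(67, 62)$theta_tilt, 37.647,
               tolerance = 1e-3)
  expect_equal(chain_tilt_from_tdm_angles(67, 67)$theta_tilt, 33.544,
               tolerance = 1e-3)
  expect_equal(chain_tilt_from_tdm_angles(90, 90)$theta_tilt, 0)
  # symmetric in its two arguments
  set.seed(12)
  for (i in 1:8) {
    a <- runif(1, 45, 90); b <- runif(1, 45, 90)
    if (cos(a * pi / 180)^2 + cos(b * pi / 180)^2 > 1) next
    expect_equal(chain_tilt_from_tdm_angles(a, b)$theta_tilt,
                 chain_tilt_from_tdm_angles(b, a)$theta_tilt)
  }
  expect_error(chain_tilt_from_tdm_angles(10, 10), "non-orthogonal")
})

test_that("forward-generated spectra round-trip to the prescribed dipole angles", {
  for (s in c(1, 17)) {
    bands <- data.frame(center = c(2850, 2921), width = c(14, 18),
                        shape_mix = 0.3, strength = c(0.02, 0.03),
                        theta_dip = c(62, 67))
    g <- gen_polarized_spectra(bands, cfg_si_d2o, noise_sd = 1e-4, seed = s)
    fit <- deconvolve_bands(g$spectrum,
                            band_model(c(2848, 2923), c(12, 16), 0.2,
                                       0.01, 0.01),
                            c(2800, 3000))
    rr <- dichroic_ratio(fit)
    th <- vapply(rr, function(r)
      dipole_angle(order_parameter_from_ratio(r, g$fields)), numeric(1L))
    expect_true(all(abs(th[order(fit$center)] - bands$theta_dip) < 2))
  }
})

test_that("spectrum files round-trip through the text reader", {
  g <- gen_polarized_spectra(
    data.frame(center = 2850, width = 12, shape_mix = 0, strength = 0.02,
               theta_dip = 60), cfg_si_d2o, seed = 2)
  f <- tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm1,abs_p,abs_s",
               paste(rev(g$spectrum$wavenumber), rev(g$spectrum$absorbance_p),
                     rev(g$spectrum$absorbance_s), sep = ",")), f)
  sp <- read_polarized_spectrum(f)  # descending grid accepted, stored ascending
  expect_equal(sp$wavenumber, g$spectrum$wavenumber)
  expect_equal(sp$absorbance_p, g$spectrum$absorbance_p)
})
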