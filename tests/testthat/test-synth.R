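# synthetic-spectrum generator: Gaussian closed forms, determinism, cohort

test_that("gaussian_profile matches the closed-form height and FWHM definition", {
  g <- seq(1150, 1330, 0.5)
  y <- gaussian_profile(1240, 13.1, 1, g)
  sigma <- 13.1 / (2 * sqrt(2 * log(2)))
  expect_equal(y[g == 1240], 1 / (sigma * sqrt(2 * pi)), tolerance = 1e-12)
  # half height at center +/- fwhm/2, by definition of FWHM
  yh <- gaussian_profile(1240, 13.1, 1, c(1240 - 13.1 / 2, 1240 + 13.1 / 2))
  expect_equal(yh, rep(y[g == 1240] / 2, 2), tolerance = 1e-9)
})

test_that("gaussian_profile integrates to its area parameter", {
  # grid extends > 5 sigma beyond the center on both sides
  g <- seq(1240 - 60, 1240 + 60, 0.25)
  for (prm in list(c(13.1, 1), c(7, 0.25), c(18, 42))) {
    y <- gaussian_profile(1240, prm[1], prm[2], g)
    expect_equal(trapz(g, y), prm[2], tolerance = 1e-6)
  }
  expect_equal(gaussian_profile(1240, 10, 0, g), rep(0, length(g)))
})

test_that("gaussian_profile rejects invalid parameters", {
  expect_error(gaussian_profile(1240, 0, 1, 1:5), "fwhm")
  expect_error(gaussian_profile(1240, -2, 1, 1:5), "fwhm")
  expect_error(gaussian_profile(1240, 10, -1, 1:5), "area")
  expect_error(gaussian_profile(1240, 10, 1, numeric(0)), "grid")
})

test_that("noiseless synthesis equals the pure 12-Gaussian sum", {
  ref <- reference_parameters("FYHHH")
  cfg <- synthetic_config(ref, baseline_coeffs = 0, noise_sd = 0,
                          portion_scale_sd = 0, seed = 1)
  s <- synthesize_spectrum(cfg, 1)
  pure <- Reduce(`+`, lapply(seq_len(12), function(k)
    gaussian_profile(ref$center[k], ref$fwhm[k], ref$area[k], cfg$grid)))
  expect_equal(s$absorbance, pure, tolerance = 1e-12)
})

test_that("synthesis is bit-identical under the same seed and portion", {
  ref <- reference_parameters("FOCHH")
  cfg <- synthetic_config(ref, seed = 99)
  s1 <- synthesize_spectrum(cfg, 3)
  s2 <- synthesize_spectrum(cfg, 3)
  expect_identical(s1$absorbance, s2$absorbance)
  # different portions draw different noise
  s3 <- synthesize_spectrum(cfg, 4)
  expect_gt(max(abs(s1$absorbance - s3$absorbance)), 0)
  # noise of distinct portions is essentially uncorrelated
  cfg0 <- synthetic_config(ref, baseline_coeffs = 0, portion_scale_sd = 0,
                           seed = 99)
  pure <- synthesize_spectrum(synthetic_config(ref, baseline_coeffs = 0,
                                               noise_sd = 0,
                                               portion_scale_sd = 0,
                                               seed = 99), 1)$absorbance
  n1 <- synthesize_spectrum(cfg0, 1)$absorbance - pure
  n2 <- synthesize_spectrum(cfg0, 2)$absorbance - pure
  expect_lt(abs(cor(n1, n2)), 0.2)
})

test_that("the mean of many noisy portions converges to the noiseless sum", {
  ref <- reference_parameters("FOMLG")
  noiseless <- synthesize_spectrum(
    synthetic_config(ref, baseline_coeffs = 0, noise_sd = 0,
                     portion_scale_sd = 0, seed = 5), 1)$absorbance
  cfg <- synthetic_config(ref, baseline_coeffs = 0, portion_scale_sd = 0,
                          seed = 5)
  n <- 200
  avg <- rowMeans(vapply(seq_len(n), function(p)
    synthesize_spectrum(cfg, p)$absorbance, numeric(length(cfg$grid))))
  # max deviation of the mean of n iid draws: ~ noise_sd/sqrt(n) per point
  expect_lt(max(abs(avg - noiseless)), 5 * cfg$noise_sd / sqrt(n))
})

test_that("reference spectra reproduce the published parameter table", {
  s <- spectrum_from_table("FOMLG")
  ref <- reference_parameters("FOMLG")
  expect_equal(ref$center[ref$index == "V"], 1238.5)
  expect_equal(ref$fwhm[ref$index == "V"], 13.4)
  expect_equal(ref$area[ref$index == "V"], 30.2)
  # component V contributes its Gaussian exactly
  rest <- ref[ref$index != "V", ]
  vonly <- s$absorbance - Reduce(`+`, lapply(seq_len(nrow(rest)), function(k)
    gaussian_profile(rest$center[k], rest$fwhm[k], rest$area[k], s$wavenumber)))
  expect_equal(vonly, gaussian_profile(1238.5, 13.4, 30.2, s$wavenumber),
               tolerance = 1e-10)
  expect_error(spectrum_from_table("XXXXX"), "unknown")
})

test_that("each reference band integrates to ~100 and samples differ", {
  for (sid in REF_SAMPLES) {
    s <- spectrum_from_table(sid)
    printed_total <- sum(reference_parameters(sid)$area)
    expect_equal(trapz(s$wavenumber, s$absorbance), printed_total,
                 tolerance = 0.5 / 100)  # edge-tail truncation only
    expect_lt(abs(printed_total - 100), 0.5)
  }
  d <- max(abs(spectrum_from_table("FYHHH")$absorbance -
               spectrum_from_table("FOMLG")$absorbance))
  expect_gt(d, 0)
})

test_that("cohort generation has the study geometry and is deterministic", {
  roster <- cohort_roster()
  expect_equal(nrow(roster), 17L)
  coh <- generate_cohort(roster, n_portions = 10, seed = 11)
  expect_length(coh$spectra, 170L)
  coh2 <- generate_cohort(roster, n_portions = 10, seed = 11)
  expect_identical(lapply(coh$spectra, `[[`, "absorbance"),
                   lapply(coh2$spectra, `[[`, "absorbance"))
  # all drawn centers lie inside the library windows
  lib <- amide3_library()
  for (p in coh$params) {
    expect_true(all(p$center >= lib$window_low & p$center <= lib$window_high))
    expect_true(all(p$fwhm > 0) && all(p$area >= 0))
  }
})

test_that("zero portion variability makes portions identical", {
  roster <- cohort_roster()[1:2, ]
  coh <- generate_cohort(roster, n_portions = 3, seed = 2,
                         portion_scale_sd = 0, noise_sd = 0)
  a <- lapply(coh$spectra[1:3], `[[`, "absorbance")
  expect_identical(a[[1]], a[[2]])
  expect_identical(a[[1]], a[[3]])
})

test_that("synthetic_config validates its invariants", {
  ref <- reference_parameters("FYHHH")
  expect_error(synthetic_config(ref[1:11, ]), "12 components")
  expect_error(synthetic_config(ref, grid_step = 0), "grid_step")
  expect_error(synthetic_config(ref, n_portions = 0), "n_portions")
  expect_error(synthetic_config(ref, grid_min = 1250, grid_max = 1300),
               "cover")
})
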