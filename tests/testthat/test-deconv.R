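# peak initialization, box-constrained Gaussian fitting, fit criteria

test_that("second derivative locates isolated and resolved band centers", {
  g <- amide3_grid()
  # analytic: the 2nd derivative of a Gaussian is minimal at its center
  s1 <- spectrum(g, gaussian_profile(1240, 13, 10, g), "one")
  d2 <- savitzky_golay(s1, window = 25, order = 4, deriv = 2)$absorbance
  expect_lt(abs(g[which.min(d2)] - 1240), 0.5 + 1e-9)  # within 1 grid step
  # two resolved Gaussians 20 cm^-1 apart, FWHM 10
  s2 <- spectrum(g, gaussian_profile(1240, 10, 5, g) +
                   gaussian_profile(1260, 10, 5, g), "two")
  d2 <- savitzky_golay(s2, window = 25, order = 4, deriv = 2)$absorbance
  n <- length(d2)
  mins <- which(d2[2:(n - 1)] < d2[1:(n - 2)] & d2[2:(n - 1)] <= d2[3:n]) + 1L
  mins <- mins[d2[mins] < 0.5 * min(d2)]
  expect_length(mins, 2L)
  expect_lt(max(abs(sort(g[mins]) - c(1240, 1260))), 1)
})

test_that("initialization assigns in-window candidates and falls back to midpoints", {
  g <- amide3_grid()
  lib <- amide3_library()
  s <- spectrum(g, gaussian_profile(1240, 13, 10, g), "one")
  init <- initialize_peaks(s)
  expect_equal(nrow(init), 12L)
  k <- which(init$index == "V")
  expect_equal(init$source[k], "derivative")
  expect_lt(abs(init$center[k] - 1240), 1)
  # a flat trace initializes every component at its window midpoint
  init0 <- initialize_peaks(spectrum(g, rep(0, length(g)), "flat"))
  expect_true(all(init0$source == "midpoint"))
  expect_equal(init0$center, lib$midpoint)
  expect_true(all(init0$area == 0))
})

test_that("a single off-library band is absorbed by one component", {
  g <- amide3_grid()
  s <- spectrum(g, gaussian_profile(1248, 10, 5, g), "lone")
  fit <- suppressWarnings(deconvolve(s))
  expect_gt(max(fit$components$relative_pct), 90)
  expect_lt(fit$chi2, 1e-8 * max(s$absorbance)^2)
})

test_that("fit matches an exhaustive lattice search on a 3-Gaussian toy", {
  g <- seq(1185, 1330, 1)   # coarse grid
  true <- data.frame(center = c(1240, 1271.5, 1298.5),
                     fwhm = c(10, 12, 11), area = c(5, 3, 2))
  y <- Reduce(`+`, lapply(1:3, function(i)
    gaussian_profile(true$center[i], true$fwhm[i], true$area[i], g)))
  fit <- suppressWarnings(deconvolve(spectrum(g, y, "toy")))
  # brute-force oracle: full search over a (center, fwhm, area) lattice
  lat <- lapply(1:3, function(i)
    expand.grid(center = true$center[i] + (-1:1),
                fwhm = true$fwhm[i] + (-1:1),
                area = true$area[i] + c(-0.5, 0, 0.5)))
  prof <- lapply(lat, function(L) vapply(seq_len(nrow(L)), function(r)
    gaussian_profile(L$center[r], L$fwhm[r], L$area[r], g),
    numeric(length(g))))
  best <- NULL
  for (i in seq_len(nrow(lat[[1]]))) {
    for (j in seq_len(nrow(lat[[2]]))) {
      part <- prof[[1]][, i] + prof[[2]][, j] - y
      rss <- colSums((prof[[3]] + part)^2)
      k <- which.min(rss)
      if (is.null(best) || rss[k] < best$rss)
        best <- list(rss = rss[k],
                     par = rbind(lat[[1]][i, ], lat[[2]][j, ], lat[[3]][k, ]))
    }
  }
  # the three dominant fitted components agree with the lattice optimum to
  # within one lattice step
  top <- fit$components[order(-fit$components$area), ][1:3, ]
  top <- top[order(top$center), ]
  expect_lt(max(abs(top$center - best$par$center)), 1 + 1e-6)
  expect_lt(max(abs(top$fwhm - best$par$fwhm)), 1 + 1e-6)
  expect_lt(max(abs(top$area - best$par$area)), 0.5 + 1e-6)
})

test_that("reduced chi-square follows its closed forms", {
  y <- rnorm(100)
  expect_equal(chi2(y, y), 0)
  expect_equal(chi2(y, y + 0.3), 0.3^2 * 100 / (100 - 36), tolerance = 1e-12)
  expect_error(chi2(y[1:30], y[1:30]), "degrees of freedom|N <= n_par")
  expect_error(chi2(y, y[1:50]), "length")
})

test_that("relative content is a scale-invariant percentage", {
  a <- c(2, 0, 1, 5, 0.5, 1, 1, 0.5, 0.3, 0.2, 0.3, 0.2)
  pct <- relative_content(a)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  expect_equal(relative_content(2 * a), pct, tolerance = 1e-12)
  single <- c(rep(0, 11), 3)
  expect_equal(unname(relative_content(single)[12]), 100)
  expect_error(relative_content(rep(0, 12)), "undefined")
})

test_that("fitted parameters respect the constraint boxes", {
  ref <- reference_parameters("FOCHH")
  cfg <- synthetic_config(ref, baseline_coeffs = 0, seed = 3)
  s <- savitzky_golay(synthesize_spectrum(cfg, 1))
  init <- initialize_peaks(s)
  fit <- suppressWarnings(fit_gaussians(s, init, max_restarts = 0L))
  cons <- fit_constraints()
  expect_true(all(abs(fit$components$center - init$center) <=
                    cons$center_box + 1e-8))
  expect_true(all(fit$components$fwhm >= cons$fwhm_box[1] - 1e-8))
  expect_true(all(fit$components$fwhm <= cons$fwhm_box[2] + 1e-8))
  expect_true(all(fit$components$area >= 0))
  expect_equal(sum(fit$components$relative_pct), 100, tolerance = 1e-9)
  expect_equal(nrow(fit$components), 12L)
})

test_that("fitted profiles plus residual reconstruct the input exactly", {
  s <- spectrum_from_table("FOCMC")
  fit <- suppressWarnings(deconvolve(s))
  expect_equal(fit$fitted + fit$residual, s$absorbance, tolerance = 1e-12)
  profs <- predict(fit, component = fit$components$index)
  expect_equal(rowSums(profs), fit$fitted, tolerance = 1e-9)
})

test_that("the fit is invariant to uniform intensity rescaling", {
  s <- spectrum_from_table("FYHHH")
  f1 <- suppressWarnings(deconvolve(s))
  s2 <- s; s2$absorbance <- 2.5 * s$absorbance
  f2 <- suppressWarnings(deconvolve(s2))
  expect_equal(f2$components$relative_pct, f1$components$relative_pct,
               tolerance = 1e-3)
  expect_equal(f2$components$area, 2.5 * f1$components$area,
               tolerance = 1e-3)
})

test_that("noiseless reference synthesis is recovered through the full path", {
  s <- spectrum_from_table("FOMLG")
  fit <- deconvolve(s)
  ref <- reference_parameters("FOMLG")
  expect_true(fit$converged)
  expect_lt(fit$chi2, 1e-8 * max(s$absorbance)^2)
  expect_lt(max(abs(fit$components$center - ref$center)), 0.5)
  expect_lt(max(abs(fit$components$relative_pct -
                      100 * ref$area / sum(ref$area))), 1.0)
})

test_that("portioned deconvolution anchors portions in one solution", {
  ref <- reference_parameters("FYHHH")
  cfg <- synthetic_config(ref, baseline_coeffs = 0, seed = 21, n_portions = 4)
  ss <- lapply(1:4, function(p) savitzky_golay(synthesize_spectrum(cfg, p)))
  dp <- deconvolve_portions(ss)
  expect_length(dp$fits, 4L)
  expect_s3_class(dp$anchor_fit, "amide3_fit")
  expect_equal(dim(dp$mean), c(12L, 6L))
  # anchored portion centers stay within the box of the anchor fit
  for (f in dp$fits)
    expect_true(all(abs(f$components$center -
                          dp$anchor_fit$components$center) <= 2 + 1e-8))
  # across-portion spread of relative content is small at 0.5% noise
  expect_lt(max(dp$sd$relative_pct), 1)
  dp2 <- deconvolve_portions(ss)
  expect_equal(dp$mean, dp2$mean, tolerance = 1e-12)
})

test_that("strict FWHM preset and input validation work", {
  expect_equal(fit_constraints(strict_fwhm = TRUE)$fwhm_box, c(7, 10))
  expect_error(fit_constraints(center_box = 0), "center_box")
  expect_error(fit_constraints(fwhm_box = c(5, 4)), "fwhm_box")
  s <- spectrum_from_table("FYHHH")
  expect_error(fit_gaussians(s, initialize_peaks(s)[1:10, ]), "12 components")
  short <- spectrum(seq(1240, 1250, 0.5), rnorm(21), "short")
  expect_error(fit_gaussians(short, initialize_peaks(spectrum_from_table("FYHHH"))),
               "36")
})
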