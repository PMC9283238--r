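test_that("baseline correction subtracts a band-free polynomial to ~0", {
  x <- grid_800_1800
  u <- (x - 1300) / 500
  base <- 50 + 10 * u + 5 * u^3 + 2 * u^11     # an 11th-order polynomial
  s <- raman_spectrum(x, base)
  out <- correct_baseline(s, order = 11)
  expect_lt(max(abs(out$intensity)), 1e-6 * diff(range(base)))
})

test_that("a constant spectrum is fully absorbed by the baseline", {
  s <- raman_spectrum(grid_800_1800, rep(7, 1001))
  out <- correct_baseline(s)
  expect_lt(max(abs(out$intensity)), 1e-8)
})

test_that("band areas survive removal of a cubic background within 2%", {
  s <- generate_spectrum(mmr = 3, carbonate = 0.15, fwhm = 18,
                         noise = 0, baseline = 0.6)
  b <- correct_baseline(s)
  b$state <- "smoothed"                     # isolate the baseline stage
  bands <- default_bands()
  amide <- 100                              # generator intensity scale
  expect_equal(band_area(b, bands$amide_I), amide, tolerance = 0.02)
  expect_equal(band_area(b, bands$nu1_phosphate), 3 * amide,
               tolerance = 0.02)
  expect_equal(band_area(b, bands$nu1_carbonate), 0.15 * 3 * amide,
               tolerance = 0.02)
})

test_that("an isolated spike is removed and nothing else is touched", {
  clean <- gauss_profile(grid_800_1800, 959, 8, 500) + 1
  spiked <- clean
  i <- 300L
  spiked[i] <- spiked[i] + 4 * max(clean)
  out <- remove_cosmic_rays(spectrum_in_state(spiked, "baselined"))
  expect_identical(attr(out, "spikes"), i)
  expect_identical(out$intensity[-i], clean[-i])
  expect_equal(out$intensity[i], clean[i], tolerance = 0.05)
})

test_that("despiking is a no-op on spike-free spectra and is idempotent", {
  clean <- gauss_profile(grid_800_1800, 959, 8, 500) +
    gauss_profile(grid_800_1800, 1660, 10, 300)
  s <- spectrum_in_state(clean, "baselined")
  out <- remove_cosmic_rays(s)
  expect_identical(out$intensity, clean)

  spiked <- clean
  spiked[400] <- spiked[400] + 1000
  once <- remove_cosmic_rays(spectrum_in_state(spiked, "baselined"))
  twice <- remove_cosmic_rays(spectrum_in_state(once$intensity, "baselined"))
  expect_identical(twice$intensity, once$intensity)
})

test_that("a genuine band of FWHM 15 is not mistaken for a spike", {
  fw <- 15
  sig <- fw / (2 * sqrt(2 * log(2)))
  clean <- gauss_profile(grid_800_1800, 959, sig, 500)
  s <- spectrum_in_state(clean, "baselined")
  out <- remove_cosmic_rays(s)
  a0 <- pracma::trapz(grid_800_1800, clean)
  a1 <- pracma::trapz(grid_800_1800, out$intensity)
  expect_lt(abs(a1 / a0 - 1), 0.001)
})

test_that("Savitzky-Golay reproduces low-degree polynomials exactly", {
  x <- grid_800_1800
  u <- (x - 1300) / 500
  y <- 3 + 2 * u - u^2 + 0.5 * u^3 + 0.2 * u^4
  out <- smooth_spectrum(spectrum_in_state(y, "despiked"),
                         window = 11, polyorder = 4)
  expect_equal(out$intensity, y, tolerance = 1e-10)
})

test_that("noise variance drops by the theoretical filter factor", {
  set.seed(77)
  factor_theory <- sg_variance_factor(11, 4)
  ratios <- replicate(500, {
    y <- rnorm(256)
    out <- smooth_spectrum(spectrum_in_state(y, "despiked",
                                             wavenumber = seq_len(256)))
    var(out$intensity[20:237])          # interior, away from edge transients
  })
  expect_equal(mean(ratios), factor_theory, tolerance = 0.10)
})

test_that("smoothing does not move a band maximum", {
  sig <- 20 / (2 * sqrt(2 * log(2)))
  y <- gauss_profile(grid_800_1800, 959.4, sig, 500)
  out <- smooth_spectrum(spectrum_in_state(y, "despiked"))
  expect_lte(abs(which.max(out$intensity) - which.max(y)), 1)
})

test_that("smoothing rejects invalid filter parameters", {
  s <- spectrum_in_state(rep(1, 1001), "despiked")
  expect_error(smooth_spectrum(s, window = 10), "odd")
  expect_error(smooth_spectrum(s, window = 11, polyorder = 11), "polyorder")
  expect_error(smooth_spectrum(s, window = 1003), "shorter")
})

test_that("band_area matches the closed-form Gaussian integral", {
  y <- gauss_profile(grid_800_1800, 955, 10, 10 * sqrt(2 * pi))
  s <- spectrum_in_state(y, "smoothed")
  a <- band_area(s, band_definition("nu1_phosphate", 900, 1010))
  expect_equal(a, 10 * sqrt(2 * pi), tolerance = 0.005)

  zero <- spectrum_in_state(rep(0, 1001), "smoothed")
  expect_identical(band_area(zero, default_bands()$nu1_phosphate), 0)
})

test_that("band_area isolates the band inside its window", {
  y <- gauss_profile(grid_800_1800, 959, 7, 200) +
    gauss_profile(grid_800_1800, 1660, 10, 400)
  s <- spectrum_in_state(y, "smoothed")
  expect_equal(band_area(s, default_bands()$nu1_phosphate), 200,
               tolerance = 0.01)
  expect_equal(band_area(s, default_bands()$amide_I), 400,
               tolerance = 0.01)
  expect_error(band_area(s, band_definition("amide_I", 1700, 1900)),
               "outside")
})

test_that("Gaussian fit recovers its own model and flags misfit", {
  sig <- 8.5
  band <- default_bands()$nu1_phosphate
  y <- gauss_profile(grid_800_1800, 959, sig, 300)
  g <- fit_phosphate_gaussian(spectrum_in_state(y, "smoothed"), band)
  expect_equal(g$fwhm, 2 * sqrt(2 * log(2)) * 8.5, tolerance = 1e-3)
  expect_equal(g$center, 959, tolerance = 1e-3)

  set.seed(31)
  fw_err <- replicate(100, {
    yn <- y * (1 + 0.01 * rnorm(length(y)))
    gn <- fit_phosphate_gaussian(spectrum_in_state(yn, "smoothed"), band)
    gn$fwhm / g$fwhm - 1
  })
  expect_lt(max(abs(fw_err)), 0.02)

  # Lorentzian input: converges, but fits worse than the Gaussian case
  lor <- 300 / (pi * sig) / (1 + ((grid_800_1800 - 959) / sig)^2)
  gl <- fit_phosphate_gaussian(spectrum_in_state(lor, "smoothed"), band)
  expect_gt(gl$rss, g$rss)
})

test_that("parameters hit configured area ratios and are scale invariant", {
  s <- generate_spectrum(mmr = 2.5, carbonate = 0.1, fwhm = 18, noise = 0)
  p <- process_spectrum(s)
  expect_equal(p$mmr, 2.5, tolerance = 0.02)
  expect_equal(p$carbonate_substitution, 0.1, tolerance = 0.02)
  expect_identical(p$crystallinity * p$fwhm_phosphate, 1)

  s2 <- s; s2$intensity <- s$intensity * 37.5
  p2 <- process_spectrum(s2)
  expect_equal(p2$mmr, p$mmr, tolerance = 1e-3)
  expect_equal(p2$carbonate_substitution, p$carbonate_substitution,
               tolerance = 1e-3)
  expect_equal(p2$crystallinity, p$crystallinity, tolerance = 1e-3)
})

test_that("full chain recovers ground truth across the parameter grid", {
  set.seed(202)
  for (mmr in c(1.5, 5)) {
    for (fw in c(12, 18)) {
      errs <- replicate(20, {
        s <- generate_spectrum(mmr, 0.15, fw, noise = 0.01, baseline = 0.5)
        p <- process_spectrum(s)
        c(p$mmr / mmr - 1, p$carbonate_substitution / 0.15 - 1,
          p$fwhm_phosphate / fw - 1)
      })
      expect_lt(max(abs(rowMeans(errs))), 0.03)          # bias
      expect_lt(max(sqrt(rowMeans(errs^2))), 0.05)       # RMSE
    }
  }
})
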