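test_that("spectrum generation is deterministic and encodes its truth", {
  a <- generate_spectrum(3, 0.15, 18, noise = 0.02, n_spikes = 2, seed = 42)
  b <- generate_spectrum(3, 0.15, 18, noise = 0.02, n_spikes = 2, seed = 42)
  expect_identical(a$intensity, b$intensity)
  expect_identical(attr(a, "truth"), list(mmr = 3, carbonate = 0.15,
                                          fwhm = 18))
  expect_error(generate_spectrum(-1, 0.1, 18), "mmr > 0")
})

test_that("doubling mmr doubles both mineral band areas", {
  x <- grid_800_1800
  win <- function(y, lo, hi) {
    i <- x >= lo & x <= hi
    pracma::trapz(x[i], y[i])
  }
  s1 <- generate_spectrum(2, 0.1, 16, noise = 0, baseline = 0)
  s2 <- generate_spectrum(4, 0.1, 16, noise = 0, baseline = 0)
  expect_equal(win(s2$intensity, 930, 980) / win(s1$intensity, 930, 980), 2,
               tolerance = 1e-6)
  expect_equal(win(s2$intensity, 1050, 1100) / win(s1$intensity, 1050, 1100),
               2, tolerance = 1e-6)
  expect_equal(win(s2$intensity, 1620, 1700), win(s1$intensity, 1620, 1700),
               tolerance = 1e-6)
})

test_that("synthetic loading branch follows the 3/2 power law", {
  cv <- generate_indent_curve(20, 0.6)
  le <- segment_curve(cv)$segments[1]
  idx <- which(cv$load[seq_len(le)] > 0.05 * max(cv$load))
  slope <- coef(lm(log(cv$load[idx]) ~ log(cv$displacement[idx])))[2]
  expect_equal(unname(slope), 1.5, tolerance = 0.01)

  a <- generate_indent_curve(20, 0.6, noise = 0.005, seed = 5)
  b <- generate_indent_curve(20, 0.6, noise = 0.005, seed = 5)
  expect_identical(a$displacement, b$displacement)
})

test_that("impossible property pairs are refused", {
  # H so small that the required area exceeds the hemisphere cross-section
  expect_error(generate_indent_curve(20, 0.2), "probe radius")
})

test_that("bse image generation is deterministic and flags degeneracy", {
  a <- generate_bse_image(22, 2, shape = c(100, 100), seed = 6)
  b <- generate_bse_image(22, 2, shape = c(100, 100), seed = 6)
  expect_identical(a$pixels, b$pixels)

  flat <- generate_bse_image(22, 0, shape = c(100, 100))
  expect_true(compute_bmdd(flat)$degenerate)

  expect_error(generate_bse_image(43, 2, shape = c(100, 100), seed = 1),
               "clips")
})

test_that("default study reproduces the sampling design counts", {
  st <- generate_study(study_config(seed = 3), level = "parameters")
  tab <- table(st$perilacunar$group, st$perilacunar$distance_um)
  expect_true(all(tab == 144))                  # 6 lacunae x 4 dir x 6 animals
  expect_identical(dim(tab), c(3L, 4L))
  expect_true(all(table(st$periosteal$group) == 96))   # 12 animals x 8 points
  expect_identical(nrow(st$images), 18L)               # 6 per group
})

test_that("study generation is reproducible from the master seed", {
  a <- generate_study(study_config(seed = 11), level = "parameters")
  b <- generate_study(study_config(seed = 11), level = "parameters")
  expect_identical(a$perilacunar, b$perilacunar)
  expect_identical(a$periosteal, b$periosteal)
})

test_that("configured group effects surface in the drawn parameters", {
  cfg <- study_config(seed = 19)
  st <- generate_study(cfg, level = "parameters")
  mean_by <- function(d, g, p) mean(d[[p]][d$group == g])
  # disease group: reduced modulus lowered by 1 SD = 2.5 GPa
  expect_equal(mean_by(st$perilacunar, "CTRL", "Er") -
                 mean_by(st$perilacunar, "CKD", "Er"), 2.5,
               tolerance = 0.2)
  # treated group: carbonate lowered by 1 SD = 0.02
  expect_equal(mean_by(st$perilacunar, "CTRL", "carbonate") -
                 mean_by(st$perilacunar, "CKD_KP", "carbonate"), 0.02,
               tolerance = 0.2)
})

test_that("zero-effect truth removes every group difference", {
  tr <- default_truth(zero_effects = TRUE)
  expect_true(all(tapply(tr$mean, tr$parameter,
                         function(v) length(unique(v)) == 1)))
})
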