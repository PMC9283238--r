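test_that("normality gate routes normal and skewed data correctly", {
  set.seed(61)
  par_rate <- mean(replicate(100, {
    g <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12))
    normality_gate(g)$route == "parametric"
  }))
  # expected rate is 0.95^3 ~ 0.857 with a 0.05-level test in each group
  expect_gte(par_rate, 0.75)

  nonpar_rate <- mean(replicate(100, {
    g <- list(a = rnorm(12), b = rnorm(12), c = rlnorm(12, sdlog = 1.5))
    normality_gate(g)$route == "nonparametric"
  }))
  expect_gte(nonpar_rate, 0.80)

  const <- normality_gate(list(a = rep(1, 5), b = rnorm(5), c = rnorm(5)))
  expect_identical(const$route, "nonparametric")
  expect_true(const$degenerate)
  expect_error(normality_gate(list(a = 1:2, b = 1:5)), "at least 3")
})

test_that("ANOVA omnibus behaves at the null and under separation", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  om <- omnibus_and_posthoc(g)
  expect_equal(om$F, 0, tolerance = 1e-12)
  expect_equal(om$p, 1, tolerance = 1e-12)
  expect_true(all(is.na(om$pairs$p_adj)))    # pairs untested without omnibus

  set.seed(71)
  power <- mean(replicate(200, {
    g <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12, 2))
    omnibus_and_posthoc(g)$p < 0.05
  }))
  expect_gte(power, 0.95)

  expect_error(omnibus_and_posthoc(list(a = rep(1, 4), b = rep(1, 4))),
               "variance")
})

test_that("ANOVA type-I error is near nominal", {
  set.seed(81)
  level <- mean(replicate(2000, {
    g <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12))
    omnibus_and_posthoc(g)$p < 0.05
  }))
  expect_equal(level, 0.05, tolerance = 0.02 / 0.05)
})

test_that("Tukey pairs isolate the shifted group", {
  set.seed(91)
  g <- list(CTRL = rnorm(12), CKD = rnorm(12), CKD_KP = rnorm(12, 3))
  om <- omnibus_and_posthoc(g)
  p <- setNames(om$pairs$p_adj, om$pairs$pair)
  expect_lt(p[["CKD_KP-CTRL"]], 0.001)
  expect_lt(p[["CKD_KP-CKD"]], 0.001)
  expect_gt(p[["CKD-CTRL"]], 0.05)
})

test_that("KS distance matches the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(1:20, 1:20)$statistic, 0)
  expect_equal(ks_two_sample(1:20 / 100, 21:40)$statistic, 1)
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(144); y <- rnorm(144, 0.2)
    expect_equal(ks_two_sample(x, y)$statistic, brute_force_ks(x, y),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(rnorm(5), rnorm(20)), "at least 8")
})

test_that("AD statistic is minimal for identical samples", {
  x <- sort(rnorm(50, 10))
  r <- ad_two_sample(x, x)
  expect_gt(r$p, 0.5)
  set.seed(17)
  y <- rnorm(50, 10)
  expect_gt(ad_two_sample(x, y)$statistic, 0)
  expect_error(ad_two_sample(rep(1, 20), rep(1, 20)), "tied")
})

test_that("permutation and asymptotic AD p-values agree", {
  set.seed(7)
  x <- rnorm(144); y <- rnorm(144, 0.3)
  pa <- ad_two_sample(x, y)$p
  pp <- ad_two_sample(x, y, method = "permutation", n_perm = 5000,
                      seed = 11)$p
  expect_lt(abs(pa - pp), 0.02)
})

test_that("shift calls use the Bonferroni level and report direction", {
  set.seed(3)
  x <- rnorm(144)
  sc <- shift_call(x, x + 1, labels = c("CTRL", "CKD"))
  expect_identical(sc$adjusted_alpha * 3, 0.05)
  expect_true(sc$significant)
  expect_identical(sc$direction, "right_shifted_B")

  null_sc <- shift_call(x, x, labels = c("CTRL", "CKD"))
  expect_false(null_sc$significant)
  expect_identical(null_sc$direction, "none")
})

test_that("shift decisions are invariant to monotone transforms", {
  set.seed(13)
  for (shift in c(0, 0.5)) {
    x <- rnorm(144); y <- rnorm(144, shift)
    a <- shift_call(x, y)
    b <- shift_call(exp(x), exp(y))
    expect_identical(a$significant, b$significant)
    expect_identical(a$direction, b$direction)
    expect_equal(a$ks_statistic, b$ks_statistic, tolerance = 1e-12)
    expect_equal(a$ad_statistic, b$ad_statistic, tolerance = 1e-12)
  }
})

test_that("conjunction rule is at least as strict as either test", {
  set.seed(29)
  x <- rnorm(144); y <- rnorm(144, 0.25)
  both <- shift_call(x, y, rule = "both")
  either <- shift_call(x, y, rule = "either")
  expect_true(!both$significant || either$significant)
})
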