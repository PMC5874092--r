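test_that("weight normalization preserves proportions and rejects bad input", {
  expect_equal(normalize_weights(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize_weights(c(1, 0)), c(1, 0))
  expect_equal(normalize_weights(c(0.3, 0.9)), c(0.25, 0.75))
  expect_error(normalize_weights(c(0, 0)), "positive")
  expect_error(normalize_weights(c(-1, 2)), "nonnegative")
})

test_that("FWHM/sigma conversions are the Gaussian closed form and round-trip", {
  expect_equal(fwhm_to_sigma(2.354820045), 1.0, tolerance = 1e-9)
  expect_equal(fwhm_to_sigma(0.10), 0.0424661, tolerance = 1e-6)
  expect_error(fwhm_to_sigma(0), "positive")
  expect_error(sigma_to_fwhm(-1), "positive")
  x <- 10^seq(-4, 1, length.out = 23)
  expect_equal(sigma_to_fwhm(fwhm_to_sigma(x)), x, tolerance = 1e-12)
  expect_equal(fwhm_to_sigma(sigma_to_fwhm(x)), x, tolerance = 1e-12)
})

test_that("mixture density is normalized at the origin and matches closed forms", {
  src <- gauss_source(weights = c(3, 1), sigma = c(0.5, 0.1))
  expect_equal(mixture_pdf(src, 0), 1.0)
  one <- gauss_source(weights = 1, sigma = 1)
  expect_equal(mixture_pdf(one, 1), exp(-0.5), tolerance = 1e-12)
  # the default double-Gaussian weights are fitted so that f(FWHM/2) = 1/2
  dg <- gauss_source(weights = c(0.667, 0.333), sigma = c(0.0334, 0.0077))
  expect_equal(mixture_pdf(dg, 0.0255), 0.5, tolerance = 1e-3)
  expect_error(mixture_pdf(src, -0.1), "nonnegative")
})

test_that("component areas follow the r dr Jacobian and cross-check by integration", {
  sym <- gauss_source(weights = c(0.5, 0.5), sigma = c(1, 1))
  expect_equal(mixture_probabilities(sym)$probabilities, c(0.5, 0.5))
  single <- gauss_source(weights = c(1, 0), sigma = c(1, 2))
  expect_equal(mixture_probabilities(single)$probabilities, c(1, 0))

  dg <- gauss_source(weights = c(0.667, 0.333), sigma = c(0.0334, 0.0077))
  pr <- mixture_probabilities(dg)
  expect_equal(pr$probabilities, c(0.9742, 0.0258), tolerance = 1e-3)
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-12)
  # independent oracle: numerically integrate a_i exp(-r^2/2s_i^2) r dr
  areas <- vapply(1:2, function(i) {
    a <- dg$components$weight[i]; s <- dg$components$sigma[i]
    integrate(function(r) a * exp(-r^2 / (2 * s^2)) * r, 0, 20 * s,
              rel.tol = 1e-12)$value
  }, numeric(1))
  expect_equal(pr$probabilities, areas / sum(areas), tolerance = 1e-9)
})

test_that("component selection is cumulative and boundary inclusive", {
  p <- c(0.5, 0.5)
  expect_identical(select_component(p, 0.3), 1L)
  expect_identical(select_component(p, 0.5), 1L)  # R1 = P1 selects component 1
  expect_identical(select_component(c(0.9742, 0.0258), 0.99), 2L)
  p3 <- c(0.2, 0.3, 0.5)
  expect_identical(select_component(p3, c(0.2, 0.21, 0.5, 0.51)),
                   c(1L, 2L, 2L, 3L))
  expect_error(select_component(p, 0), "\\(0, 1\\)")
  expect_error(select_component(p, 1), "\\(0, 1\\)")
})

test_that("radius sampling inverts the 2-D Gaussian radial CDF", {
  expect_equal(sample_radius(1, exp(-0.5)), 1.0, tolerance = 1e-12)
  expect_equal(sample_radius(0.3, 1), 0)
  expect_equal(sample_radius(0.0077, exp(-2)), 2 * 0.0077, tolerance = 1e-12)
  expect_error(sample_radius(1, 0), "\\(0, 1\\]")
  expect_error(sample_radius(-1, 0.5), "positive")
})

test_that("position sampling has correct marginals, CDF, and degenerate limits", {
  pt <- gauss_source(weights = c(0.5, 0.5), sigma = c(1e-9, 1e-9))
  pos <- sample_position(pt, 1000, seed = 1)
  expect_lt(max(abs(c(pos$x, pos$y))), 1e-7)

  one <- gauss_source(weights = 1, sigma = 1)
  pos <- sample_position(one, 1e5, seed = 42)
  se_var <- sqrt(2 / (1e5 - 1))       # SE of the sample variance of a Gaussian
  expect_lt(abs(var(pos$x) - 1), 3 * se_var)
  expect_lt(abs(var(pos$y) - 1), 3 * se_var)

  dg <- primus_source("double")
  pos <- sample_position(dg, 1e5, seed = 7)
  r <- sqrt(pos$x^2 + pos$y^2)
  expect_lt(ks_stat(r, radial_cdf(dg)), ks_critical(1e5, 0.01))
})

test_that("a zero-weight component reproduces the single-Gaussian stream exactly", {
  mix <- gauss_source(weights = c(1, 0), sigma = c(0.4, 0.1))
  single <- gauss_source(weights = 1, sigma = 0.4)
  expect_identical(sample_position(mix, 1e4, seed = 11),
                   sample_position(single, 1e4, seed = 11))
})

test_that("independent-XY mode uses 1-D areas and samples per-axis mixtures", {
  src <- gauss_source(axis_mode = "xy",
                      x = list(weights = c(0.667, 0.333),
                               sigma = c(0.0334, 0.0077)),
                      y = list(weights = 1, sigma = 0.02))
  prx <- mixture_probabilities(src, "x")
  a <- c(0.667, 0.333); s <- c(0.0334, 0.0077)
  expect_equal(prx$probabilities, a * s / sum(a * s), tolerance = 1e-12)
  pos <- sample_position(src, 2e5, seed = 3)
  # x marginal variance: sum Q_i s_i^2; y is a pure Gaussian
  q <- prx$probabilities
  expect_equal(var(pos$x), sum(q * s^2), tolerance = 0.02)
  expect_equal(var(pos$y), 0.02^2, tolerance = 0.02)
})

test_that("energy sampling matches the Gaussian spectrum and is reproducible", {
  spec <- energy_spectrum(6, 0)
  expect_equal(sample_energy(spec, 10, seed = 1), rep(6, 10))
  spec14 <- energy_spectrum(6, 0.14)
  e <- sample_energy(spec14, 1e6, seed = 5)
  sE <- 0.84 / (2 * sqrt(2 * log(2)))   # 0.35672 MeV
  expect_lt(abs(mean(e) - 6), 3 * sE / sqrt(1e6))
  expect_lt(abs(sd(e) - sE), 3 * sE / sqrt(2 * 1e6))
  expect_true(all(e > 0))
  expect_identical(sample_energy(spec14, 1, seed = 9),
                   sample_energy(spec14, 1, seed = 9))
  expect_error(energy_spectrum(-1), "positive")
  expect_error(energy_spectrum(6, 2), "\\[0, 2\\)")
})

test_that("analytic FWHM matches closed forms and a brute-force grid scan", {
  expect_equal(analytic_fwhm(gauss_source(weights = 1, sigma = 1)),
               2 * sqrt(2 * log(2)), tolerance = 1e-9)
  # printed-sigma mixture: 0.51 mm
  dg <- gauss_source(weights = c(0.667, 0.333), sigma = c(0.0334, 0.0077))
  expect_equal(analytic_fwhm(dg), 0.051, tolerance = 2e-4 / 0.051)
  # equal sigmas collapse to a single Gaussian
  eq <- gauss_source(weights = c(0.3, 0.7), sigma = c(0.2, 0.2))
  expect_equal(analytic_fwhm(eq), sigma_to_fwhm(0.2), tolerance = 1e-9)
  # brute-force oracle: fine grid scan of f(r) at 1e-7 cm resolution
  set.seed(101)
  for (k in 1:4) {
    sg <- sort(runif(2, 0.005, 0.05), decreasing = TRUE)
    a <- normalize_weights(runif(2, 0.1, 1))
    src <- gauss_source(weights = a, sigma = sg)
    grid <- seq(0, 2.4 * sg[1], by = 1e-7)
    f <- a[1] * exp(-grid^2 / (2 * sg[1]^2)) + a[2] * exp(-grid^2 / (2 * sg[2]^2))
    brute <- 2 * grid[which.max(f < 0.5)]
    expect_equal(analytic_fwhm(src), brute, tolerance = 1e-6 / brute)
  }
})

test_that("weight fitting hits the target FWHM and honours its domain", {
  a <- fit_weights_to_fwhm(0.0334, 0.0077, 0.051)
  expect_equal(unname(a[1]), 0.667, tolerance = 1e-3)
  # parameter-recovery loop across the admissible interval
  set.seed(77)
  for (k in 1:5) {
    s1 <- runif(1, 0.02, 0.06); s2 <- runif(1, 0.004, 0.015)
    lo <- sigma_to_fwhm(s2); hi <- sigma_to_fwhm(s1)
    target <- runif(1, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
    w <- fit_weights_to_fwhm(s1, s2, target)
    src <- gauss_source(weights = w, sigma = c(s1, s2))
    expect_lt(abs(analytic_fwhm(src) - target), 1e-9)
  }
  # limits of the admissible interval
  eps <- 1e-6
  w <- fit_weights_to_fwhm(0.0334, 0.0077, sigma_to_fwhm(0.0334) - eps)
  expect_gt(w[1], 0.999)
  expect_error(fit_weights_to_fwhm(0.0334, 0.0077, sigma_to_fwhm(0.0077)),
               "open interval")
  expect_error(fit_weights_to_fwhm(0.0077, 0.0334, 0.05), "sigma1 > sigma2")
})

test_that("preset sources reflect the commissioned parameterizations", {
  dg <- primus_source("double")
  expect_equal(dg$components$sigma, c(0.0334, 0.0077))
  expect_equal(analytic_fwhm(dg), 0.051, tolerance = 1e-9)
  sg <- primus_source("single")
  expect_equal(analytic_fwhm(sg), 0.10, tolerance = 1e-9)
  expect_output(print(dg), "component 1")
  sm <- summary(dg)
  expect_equal(sm$fwhm, 0.051, tolerance = 1e-9)
  expect_equal(unname(coef(sg)[, "sigma"]), fwhm_to_sigma(0.10))
})
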