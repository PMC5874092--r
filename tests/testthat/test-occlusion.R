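test_that("ray tracing through apertures follows similar triangles", {
  geom <- beam_geometry(list(aperture_circle(59, 0.05)), ssd = 100, depth = 1.5)
  # axial ray through any centered aperture
  expect_true(trace(0, 0, 0, 0, 1, geom))
  # ray from (0.2, 0) toward the axis point at z = 101.5 crosses z = 59 at
  # 0.2 * (1 - 59/101.5) = 0.0838 cm > 0.05 -> absorbed
  Z <- 101.5
  nrm <- sqrt(0.2^2 + Z^2)
  expect_false(trace(0.2, 0, -0.2 / nrm, 0, Z / nrm, geom))
  expect_equal(0.2 * (1 - 59 / 101.5), 0.0838, tolerance = 1e-3)
  # boundary-inclusive transmission at a rectangle edge
  rectg <- beam_geometry(list(aperture_rect(50, 0.5, 0.5)))
  expect_true(trace(0.5, 0, 0, 0, 1, rectg))
  expect_false(trace(0.5 + 1e-12, 0, 0, 0, 1, rectg))
  expect_error(trace(0, 0, 0, 0, -1, rectg), "w > 0")
})

test_that("geometry constructors validate ordering and dimensions", {
  expect_error(aperture_rect(10, -1, 1), "positive")
  expect_error(aperture_circle(0, 1), "positive")
  expect_error(beam_geometry(list(aperture_rect(30, 1, 1),
                                  aperture_rect(20, 1, 1))), "ordered")
  expect_error(beam_geometry(list(aperture_rect(120, 1, 1))), "upstream")
  g <- square_field_geometry(10)
  expect_equal(g$scoring_z, 101.5)
  expect_equal(g$apertures[[1]]$half_y, 5 * 22 / 100)
  expect_equal(g$apertures[[2]]$half_x, 5 * 31 / 100)
  expect_equal(cone_geometry(2)$apertures[[1]]$radius, 0.1)
})

test_that("central-axis MC agrees with the closed-form visible fraction", {
  # the worked closed-form case: R = 0.05 cm at 59 cm, scoring at 101.5 cm
  sg <- gauss_source(weights = 1, sigma = 0.0424661)
  geom <- beam_geometry(list(aperture_circle(59, 0.05)))
  cf <- visible_fraction(sg, 0.05, 59, 101.5)
  expect_equal(cf, 0.9808, tolerance = 1e-4)
  mc <- central_axis_value(sg, energy_spectrum(6, 0.14), geom, n = 2e5,
                           seed = 31, tally_halfwidth = 0.001)
  expect_lt(abs(mc$value - cf), 3 * mc$sigma)
  # unbiasedness across a grid of (R, d, sigma) cases
  cases <- expand.grid(R = c(0.01, 0.02, 0.05),
                       d = c(22, 41, 59), KEEP.OUT.ATTRS = FALSE)
  cases$sigma <- rep(c(0.02, 0.0334, 0.0424661), 3)
  for (k in seq_len(nrow(cases))) {
    src <- gauss_source(weights = 1, sigma = cases$sigma[k])
    geom <- beam_geometry(list(aperture_circle(cases$d[k], cases$R[k])))
    cf <- visible_fraction(src, cases$R[k], cases$d[k], 101.5)
    mc <- central_axis_value(src, energy_spectrum(6, 0), geom, n = 1e5,
                             seed = 100 + k, tally_halfwidth = 0.001)
    expect_lt(abs(mc$value - cf), 3 * mc$sigma + 1e-4)
  }
  # no occlusion when the aperture is much wider than the source
  wide <- beam_geometry(list(aperture_circle(59, 5)))
  mc <- central_axis_value(sg, energy_spectrum(6, 0), wide, n = 1e4, seed = 9)
  expect_equal(mc$value, 1)
})

test_that("a point source casts a sharp magnified shadow", {
  pt <- gauss_source(weights = 1, sigma = 1e-9)
  geom <- beam_geometry(list(aperture_rect(50, 0.1, 1e3)))
  edges <- seq(-0.4, 0.4, by = 0.01)
  prof <- simulate_profile(pt, energy_spectrum(6, 0), geom, edges,
                           n = 2e5, seed = 41)
  # 50% width equals the geometrically magnified aperture, 0.2 * 101.5/50,
  # to within one bin
  expect_equal(field_size_50(prof), 0.2 * 101.5 / 50, tolerance = 0.01 / 0.4)
  # profile is flat inside and empty outside the shadow
  ctr <- bin_centers(prof)
  expect_true(all(prof$values[abs(ctr) > 0.21] == 0))
  expect_true(all(prof$values[abs(ctr) < 0.19] > 0))
})

test_that("penumbra grows with source width and matches the edge-spread form", {
  spec <- energy_spectrum(6, 0)
  geom <- beam_geometry(list(aperture_rect(31, 0.0775, 1e3)))
  edges <- seq(-0.5, 0.5, by = 0.005)
  pens <- vapply(c(0.02, 0.0334, 0.05), function(s) {
    prof <- simulate_profile(gauss_source(weights = 1, sigma = s), spec,
                             geom, edges, n = 5e5, seed = 55)
    penumbra_20_80(prof)$mean
  }, numeric(1))
  expect_true(all(diff(pens) > 0))   # blur monotonicity in source width
  # closed-form Gaussian edge spread: 1.6832 * sigma * (D - d)/d
  k2080 <- qnorm(0.8) - qnorm(0.2)
  expect_equal(pens[2], k2080 * 0.0334 * (101.5 - 31) / 31, tolerance = 0.05)
})

test_that("penumbra grows with (D - d)/d at fixed source", {
  spec <- energy_spectrum(6, 0)
  src <- primus_source("single")
  pens <- vapply(c(59, 31, 22), function(d) {
    half <- 0.25 * d / 100
    geom <- beam_geometry(list(aperture_rect(d, half, 1e3)))
    edges <- seq(-0.5, 0.5, by = 0.005)
    prof <- simulate_profile(src, spec, geom, edges, n = 5e5, seed = 60)
    penumbra_20_80(prof)$mean
  }, numeric(1))
  expect_true(all(diff(pens) > 0))
})

test_that("identical seeds give bitwise-identical profiles", {
  src <- primus_source("double")
  spec <- energy_spectrum(6, 0.14)
  geom <- square_field_geometry(1)
  edges <- seq(-1, 1, by = 0.02)
  p1 <- simulate_profile(src, spec, geom, edges, n = 1e5, seed = 77)
  p2 <- simulate_profile(src, spec, geom, edges, n = 1e5, seed = 77)
  expect_identical(p1$values, p2$values)
  expect_identical(p1$sigma, p2$sigma)
  # and an empty field errors explicitly
  blocked <- beam_geometry(list(aperture_circle(50, 1e-6)))
  expect_error(simulate_profile(gauss_source(weights = 1, sigma = 0.5),
                                spec, blocked, seq(2, 3, 0.1), n = 100,
                                seed = 1),
               "empty field")
})

test_that("output factors normalize to the reference and grow with field size", {
  src <- primus_source("double")
  spec <- energy_spectrum(6, 0)
  sides <- c(0.5, 1, 2, 5, 10)
  geoms <- lapply(sides, square_field_geometry)
  names(geoms) <- paste0("s", sides)
  tab <- output_factors(src, spec, geoms, reference = "s10", n = 5e4, seed = 81)
  expect_identical(tab$of[tab$field == "s10"], 1)
  expect_true(all(diff(tab$of) >= 0))   # occlusion only: monotone in side
})

test_that("detector blur is mass-preserving, identity at zero, and widens penumbra", {
  edges <- seq(-3.005, 3.005, by = 0.01)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  step <- profile1d(edges, 100 * (abs(ctr) <= 2))
  expect_identical(detector_blur(step, 0), step)
  for (sk in c(0.05, 0.1)) {
    raw <- detector_blur(step, sk, renormalize = FALSE)
    expect_equal(sum(raw$values), sum(step$values), tolerance = 1e-9)
    pen <- penumbra_20_80(detector_blur(step, sk))
    # edge-spread closed form 1.6832 * sigma_k
    expect_equal(pen$mean, (qnorm(0.8) - qnorm(0.2)) * sk, tolerance = 0.01)
  }
  pens <- vapply(c(0.02, 0.05, 0.1), function(sk)
    penumbra_20_80(detector_blur(step, sk))$mean, numeric(1))
  expect_true(all(diff(pens) > 0))
})
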