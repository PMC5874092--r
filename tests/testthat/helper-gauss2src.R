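# Shared oracles and pipeline shorthands for the test suite.

# analytic radial CDF of a radial mixture: F(r) = sum_i P_i (1 - exp(-r^2/2s_i^2))
radial_cdf <- function(source) {
  pr <- mixture_probabilities(source)$probabilities
  sg <- source$components$sigma
  function(r) {
    vapply(r, function(ri) sum(pr * (1 - exp(-ri^2 / (2 * sg^2)))), numeric(1))
  }
}

# two-sided Kolmogorov-Smirnov statistic against a continuous CDF
ks_stat <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}

# asymptotic critical value of the two-sided KS statistic
ks_critical <- function(n, alpha = 0.01) sqrt(-log(alpha / 2) / 2) / sqrt(n)

# source-plane reconstruction pipeline: sample -> score at 100 cm ->
# back-project to z = 0 -> central-strip energy-fluence density profile
reconstruct_source_profile <- function(source, n, seed, bin_width = 0.01,
                                       strip = 0.005, range = 0.3) {
  spec <- energy_spectrum(6, 0.14)
  ps <- generate_source_phase_space(source, spec, n = n, seed = seed,
                                    plane_z = 100,
                                    emission_model = "parallel")
  bp <- backproject(ps, target_z = 0)
  k <- ceiling(range / bin_width)
  edges <- seq(-(k + 0.5) * bin_width, (k + 0.5) * bin_width, by = bin_width)
  energy_fluence_profile(bp[, c("x", "y")], bp$energy, bp$weight, edges,
                         axis = "x", strip_halfwidth = strip, density = TRUE)
}

# analytic Gaussian profile with known FWHM, normalized to 100 at center
analytic_gauss_profile <- function(fwhm, bin_width = 0.01, range = 0.3) {
  sg <- fwhm_to_sigma(fwhm)
  k <- ceiling(range / bin_width)
  edges <- seq(-(k + 0.5) * bin_width, (k + 0.5) * bin_width, by = bin_width)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  profile1d(edges, 100 * exp(-ctr^2 / (2 * sg^2)))
}
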