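# Synthetic fixtures: closed-form profiles, tiny hand-checkable phase
# spaces, and noisy variants. The whole test surface is generated in code.

#' Generate synthetic test fixtures
#'
#' Writes small plain-text fixtures of a given kind into `dir`:
#' \describe{
#'   \item{`"analytic-profiles"`}{Closed-form profiles with known metrics:
#'     a Gaussian with FWHM 0.10 cm, a perfect step of width 4 cm, a
#'     trapezoid whose edges ramp 0 to 100% over 1 cm (20-80% penumbra
#'     exactly 0.6 cm), and a step edge blurred with a sigma = 0.1 cm
#'     Gaussian (penumbra 1.6832 * 0.1 cm).}
#'   \item{`"toy-phsp"`}{A three-record text phase space at z = 100 cm with
#'     hand-checkable back-projections: an axial ray, a ray with slope
#'     u/w = 0.01 arriving at x = 1 (back-projects to x = 0), and a
#'     diverging electron.}
#'   \item{`"noisy-profiles"`}{The analytic Gaussian with seeded Gaussian
#'     noise of stated per-bin sigma, and a sigma = 0 variant identical to
#'     the analytic curve.}
#' }
#'
#' @param kind Fixture family (see above).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the noisy variants.
#' @return Named character vector of file paths.
#' @export
make_fixtures <- function(kind = c("analytic-profiles", "toy-phsp",
                                   "noisy-profiles"),
                          dir = tempfile("fixtures"), seed = 1) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, p) {
    path <- file.path(dir, name)
    write_profile(p, path)
    path
  }
  if (kind == "analytic-profiles") {
    edges <- seq(-0.3005, 0.3005, by = 0.01)
    ctr <- (edges[-1] + edges[-length(edges)]) / 2
    sg <- fwhm_to_sigma(0.10)
    paths["gaussian_fwhm0p10"] <-
      put("gaussian_fwhm0p10.csv",
          profile1d(edges, 100 * exp(-ctr^2 / (2 * sg^2))))
    edges4 <- seq(-3.005, 3.005, by = 0.01)
    ctr4 <- (edges4[-1] + edges4[-length(edges4)]) / 2
    paths["step_width4"] <-
      put("step_width4.csv", profile1d(edges4, 100 * (abs(ctr4) <= 2)))
    trap <- pmin(100, pmax(0, (2.5 - abs(ctr4)) * 100))
    paths["trapezoid_ramp1cm"] <-
      put("trapezoid_ramp1cm.csv", profile1d(edges4, trap))
    paths["blurred_step_sigma0p1"] <-
      put("blurred_step_sigma0p1.csv",
          profile1d(edges4, 100 * (pnorm((ctr4 + 2) / 0.1) -
                                   pnorm((ctr4 - 2) / 0.1))))
  } else if (kind == "toy-phsp") {
    w2 <- 1 / sqrt(1 + 0.01^2)
    rec <- data.frame(
      kind = c("photon", "photon", "electron"),
      energy = c(6, 2, 0.5),
      x = c(0, 1, -2), y = c(0, 0, 1),
      u = c(0, 0.01 * w2, 0), v = c(0, 0, 0),
      w = c(1, w2, 1), weight = c(1, 1, 2))
    ps <- phase_space(rec, plane_z = 100, metadata = list(fixture = "toy"))
    paths["toy_phsp"] <- file.path(dir, "toy.phsp.txt")
    write_phsp(ps, paths["toy_phsp"], format = "text")
  } else {
    set.seed(seed)
    edges <- seq(-0.3005, 0.3005, by = 0.01)
    ctr <- (edges[-1] + edges[-length(edges)]) / 2
    sg <- fwhm_to_sigma(0.10)
    clean <- 100 * exp(-ctr^2 / (2 * sg^2))
    noise_sigma <- 1.5
    paths["noisy_gaussian"] <-
      put("noisy_gaussian.csv",
          profile1d(edges, clean + stats::rnorm(length(clean), 0, noise_sigma),
                    sigma = noise_sigma))
    paths["noiseless_gaussian"] <-
      put("noiseless_gaussian.csv", profile1d(edges, clean, sigma = 0))
  }
  paths
}
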