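# Simplified geometric transport: photons from the extended source are
# ray-traced through perfectly absorbing, zero-thickness apertures to a
# scoring plane. The dose proxy is in-air energy fluence: no phantom
# transport, no aperture scatter or leakage. This isolates the
# source-occlusion mechanism that governs small-field output and penumbra.

#' Collimating aperture
#'
#' A zero-thickness, perfectly absorbing plane with a rectangular or
#' circular opening centered on the beam axis. Transmission at the exact
#' opening boundary is inclusive (fixed for determinism).
#'
#' @param plane_z Distance from the source plane, cm (0 < plane_z < scoring z).
#' @param half_x,half_y Rectangle half-apertures, cm.
#' @param radius Circle radius, cm.
#' @return An object of class `"aperture"`.
#' @name aperture
NULL

#' @rdname aperture
#' @export
aperture_rect <- function(plane_z, half_x, half_y) {
  if (plane_z <= 0 || half_x <= 0 || half_y <= 0)
    stop("aperture dimensions and plane_z must be positive", call. = FALSE)
  structure(list(shape = "rectangle", plane_z = plane_z,
                 half_x = half_x, half_y = half_y), class = "aperture")
}

#' @rdname aperture
#' @export
aperture_circle <- function(plane_z, radius) {
  if (plane_z <= 0 || radius <= 0)
    stop("aperture radius and plane_z must be positive", call. = FALSE)
  structure(list(shape = "circle", plane_z = plane_z, radius = radius),
            class = "aperture")
}

#' Beam geometry
#'
#' The ordered set of absorbing apertures between the source plane (z = 0)
#' and the scoring plane at `z = ssd + depth` (source-to-surface distance
#' plus scoring depth; the default 100 + 1.5 cm matches standard output
#' factor and profile scoring conditions).
#'
#' @param apertures List of [aperture_rect()] / [aperture_circle()] objects,
#'   strictly ordered by increasing `plane_z`.
#' @param ssd Source-to-surface distance, cm.
#' @param depth Scoring depth below the surface, cm.
#' @return An object of class `"beam_geometry"` with element `scoring_z`.
#' @export
beam_geometry <- function(apertures, ssd = 100, depth = 1.5) {
  if (inherits(apertures, "aperture")) apertures <- list(apertures)
  if (!length(apertures) || !all(vapply(apertures, inherits, logical(1), "aperture")))
    stop("'apertures' must be a list of aperture objects", call. = FALSE)
  if (ssd <= 0 || depth <= 0) stop("'ssd' and 'depth' must be positive", call. = FALSE)
  z <- vapply(apertures, `[[`, numeric(1), "plane_z")
  if (any(diff(z) <= 0))
    stop("apertures must be strictly ordered by plane_z", call. = FALSE)
  scoring_z <- ssd + depth
  if (any(z >= scoring_z))
    stop("all apertures must lie upstream of the scoring plane", call. = FALSE)
  structure(list(apertures = apertures[order(z)], ssd = ssd, depth = depth,
                 scoring_z = scoring_z), class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("Beam geometry: SSD %g cm, depth %g cm (scoring at z = %g cm)\n",
              x$ssd, x$depth, x$scoring_z))
  for (a in x$apertures) {
    if (a$shape == "rectangle")
      cat(sprintf("  rectangle at z = %g cm: half_x %g, half_y %g cm\n",
                  a$plane_z, a$half_x, a$half_y))
    else
      cat(sprintf("  circle at z = %g cm: radius %g cm\n", a$plane_z, a$radius))
  }
  invisible(x)
}

#' Trace rays through the aperture stack
#'
#' Follows straight lines from origins on the source plane along their
#' direction cosines and reports whether each ray passes inside every
#' aperture opening (boundary inclusive). Vectorized over rays.
#'
#' @param x0,y0 Ray origins at z = 0, cm.
#' @param u,v,w Direction cosines (w > 0).
#' @param geometry A [beam_geometry()] object.
#' @return Logical vector: `TRUE` for transmitted rays.
#' @export
trace <- function(x0, y0, u, v, w, geometry) {
  stopifnot(inherits(geometry, "beam_geometry"))
  if (any(w <= 0)) stop("all rays must travel toward the scoring plane (w > 0)",
                        call. = FALSE)
  ok <- rep(TRUE, length(x0))
  for (a in geometry$apertures) {
    t <- a$plane_z
    px <- x0 + u / w * t
    py <- y0 + v / w * t
    ok <- ok & if (a$shape == "rectangle")
      abs(px) <= a$half_x & abs(py) <= a$half_y
    else
      px^2 + py^2 <= a$radius^2
  }
  ok
}

#' Closed-form visible-source fraction (single circular aperture)
#'
#' For a radial mixture source viewed through one circular aperture of
#' radius R at distance d, with the tally point on the axis at distance D,
#' the source points able to reach the axis point lie within the
#' back-projected radius \eqn{\rho_{max} = R D / (D - d)}; the transmitted
#' fraction is \eqn{\sum_i P_i (1 - e^{-\rho_{max}^2 / 2\sigma_i^2})}.
#' Serves as the analytic oracle for [central_axis_value()].
#'
#' @param source A radial [gauss_source()] object.
#' @param radius Aperture radius, cm.
#' @param d Aperture distance from the source, cm.
#' @param D Tally-point distance from the source, cm (D > d).
#' @return Visible (transmitted) fraction in (0, 1].
#' @export
visible_fraction <- function(source, radius, d, D) {
  stopifnot(inherits(source, "gauss_source"), source$axis_mode == "radial",
            D > d, d > 0, radius > 0)
  rho_max <- radius * D / (D - d)
  pr <- mixture_probabilities(source)
  cmp <- source$components
  sum(pr$probabilities * (1 - exp(-rho_max^2 / (2 * cmp$sigma^2))))
}

## shared Monte Carlo engine: sample source particles aimed at uniform
## target points in a rectangle on the scoring plane, trace, accumulate.
## Targets are drawn uniformly over the collection rectangle; over the tiny
## solid angles involved the emission density is flat, so every history
## carries the same importance weight and relative fluence is unbiased.
occlusion_mc <- function(source, spectrum, geometry, n, seed,
                         x_range, y_range, accumulate, chunk = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  Z <- geometry$scoring_z
  remaining <- n
  while (remaining > 0) {
    m <- min(chunk, remaining)
    pos <- sample_position(source, m)
    energy <- sample_energy(spectrum, m)
    xt <- runif(m, x_range[1], x_range[2])
    yt <- runif(m, y_range[1], y_range[2])
    dx <- xt - pos$x; dy <- yt - pos$y
    nrm <- sqrt(dx^2 + dy^2 + Z^2)
    ok <- trace(pos$x, pos$y, dx / nrm, dy / nrm, Z / nrm, geometry)
    accumulate(xt, yt, energy, ok)
    remaining <- remaining - m
  }
  invisible(NULL)
}

#' Monte Carlo transmitted-fluence profile
#'
#' Estimates the relative transmitted energy-fluence profile along one scan
#' axis at the scoring plane. Histories are importance-sampled: each source
#' particle is aimed at a point drawn uniformly over the scan range x a
#' thin orthogonal strip (half-width `strip_halfwidth`, emulating one row
#' of scoring voxels), so every history lands on the scored region and
#' carries identical weight. Transmitted energy fluence is accumulated per
#' bin and normalized to the central-axis value (100%); per-bin
#' uncertainties are scaled identically.
#'
#' @param source A [gauss_source()] object.
#' @param spectrum An [energy_spectrum()] object.
#' @param geometry A [beam_geometry()] object.
#' @param bin_edges Scan bin edges, cm, at the scoring plane. The scan range
#'   must cover the beam axis (0) when `normalize = TRUE`.
#' @param scan_axis `"x"` or `"y"`.
#' @param n Number of histories.
#' @param seed Optional integer seed.
#' @param strip_halfwidth Orthogonal half-width of the scored strip, cm
#'   (default 0.005, i.e. one 0.1 mm voxel row).
#' @param normalize Normalize to the central value (100%)?
#' @return A [profile1d()]; values in percent of the central-axis value when
#'   normalized, else raw transmitted energy fluence per bin.
#' @export
simulate_profile <- function(source, spectrum, geometry, bin_edges,
                             scan_axis = c("x", "y"), n, seed = NULL,
                             strip_halfwidth = 0.005, normalize = TRUE) {
  scan_axis <- match.arg(scan_axis)
  stopifnot(n >= 1)
  if (any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  nb <- length(bin_edges) - 1L
  vals <- numeric(nb); sig2 <- numeric(nb)
  scan_range <- range(bin_edges)
  strip <- c(-strip_halfwidth, strip_halfwidth)
  acc <- function(xt, yt, energy, ok) {
    coord <- if (scan_axis == "x") xt else yt
    idx <- findInterval(coord[ok], bin_edges, rightmost.closed = TRUE)
    fidx <- factor(idx, levels = seq_len(nb))
    vals <<- vals + as.numeric(tapply(energy[ok], fidx, sum, default = 0))
    sig2 <<- sig2 + as.numeric(tapply(energy[ok]^2, fidx, sum, default = 0))
  }
  if (scan_axis == "x")
    occlusion_mc(source, spectrum, geometry, n, seed, scan_range, strip, acc)
  else
    occlusion_mc(source, spectrum, geometry, n, seed, strip, scan_range, acc)
  if (all(vals == 0))
    stop("empty field: no particle was transmitted through the apertures",
         call. = FALSE)
  sig <- sqrt(sig2)
  p <- profile1d(bin_edges, vals, sig, axis = scan_axis,
                 metadata = list(n_histories = n,
                                 strip_halfwidth = strip_halfwidth,
                                 scoring_z = geometry$scoring_z))
  if (normalize) p <- normalize_profile(p, "central") # nolint: defined in profile_analysis.R
  p
}

#' Monte Carlo central-axis transmitted fraction
#'
#' Estimates the transmitted energy fluence into a small square tally
#' centered on the beam axis at the scoring plane, per unit incident energy
#' fluence aimed at the tally (a dimensionless transmission factor in
#' (0, 1]). For a single circular aperture this converges to the
#' closed-form [visible_fraction()].
#'
#' @inheritParams simulate_profile
#' @param tally_halfwidth Tally half-side, cm (default 0.005 cm, a
#'   0.01 x 0.01 cm^2 tally).
#' @return List with elements `value`, `sigma` (standard error) and `n`.
#' @export
central_axis_value <- function(source, spectrum, geometry, n, seed = NULL,
                               tally_halfwidth = 0.005) {
  stopifnot(n >= 1)
  num <- 0; den <- 0; num2 <- 0; cross <- 0; den2 <- 0
  tal <- c(-tally_halfwidth, tally_halfwidth)
  acc <- function(xt, yt, energy, ok) {
    t <- energy * ok
    num <<- num + sum(t);     den <<- den + sum(energy)
    num2 <<- num2 + sum(t^2); cross <<- cross + sum(t * energy)
    den2 <<- den2 + sum(energy^2)
  }
  occlusion_mc(source, spectrum, geometry, n, seed, tal, tal, acc)
  value <- num / den
  ## delta-method standard error of the ratio estimator
  var_r <- (num2 - 2 * value * cross + value^2 * den2) / den^2
  list(value = value, sigma = sqrt(max(var_r, 0)), n = n)
}

#' Output factors over a set of field geometries
#'
#' Computes the central-axis transmitted fluence for every geometry and
#' normalizes to the reference geometry:
#' OF(field) = central(field) / central(reference), so OF(reference) = 1
#' exactly. In this pure occlusion model the output factor captures only
#' the visible-source fraction; head scatter and the collimator exchange
#' effect are outside the model.
#'
#' @param source A [gauss_source()] object.
#' @param spectrum An [energy_spectrum()] object.
#' @param geometries Named list of [beam_geometry()] objects.
#' @param reference Name (or index) of the reference geometry in
#'   `geometries`.
#' @param n Histories per geometry.
#' @param seed Optional integer base seed; geometry k uses `seed + k - 1`.
#' @param tally_halfwidth Tally half-side, cm.
#' @return Data.frame with columns `field`, `value`, `sigma`, `of`,
#'   `of_sigma`.
#' @export
output_factors <- function(source, spectrum, geometries, reference, n,
                           seed = NULL, tally_halfwidth = 0.005) {
  if (is.null(names(geometries)) || any(!nzchar(names(geometries))))
    stop("'geometries' must be a named list", call. = FALSE)
  if (is.numeric(reference)) reference <- names(geometries)[reference]
  if (!reference %in% names(geometries))
    stop("the reference geometry must be included in 'geometries'",
         call. = FALSE)
  res <- lapply(seq_along(geometries), function(k) {
    central_axis_value(source, spectrum, geometries[[k]], n = n,
                       seed = if (is.null(seed)) NULL else seed + k - 1,
                       tally_halfwidth = tally_halfwidth)
  })
  value <- vapply(res, `[[`, numeric(1), "value")
  sig <- vapply(res, `[[`, numeric(1), "sigma")
  ref <- which(names(geometries) == reference)
  of <- value / value[ref]
  rel2 <- (sig / value)^2
  of_sigma <- of * sqrt(rel2 + rel2[ref])
  of_sigma[ref] <- 0
  data.frame(field = names(geometries), value = value, sigma = sig,
             of = of, of_sigma = of_sigma, row.names = NULL)
}

#' Gaussian detector blur
#'
#' Convolves a profile with a discrete Gaussian kernel of width
#' `kernel_sigma`, emulating the partial-volume averaging of a finite
#' detector. The kernel is normalized per source bin over the available
#' output bins, so the total integral is preserved exactly before the
#' optional renormalization to the central value. Per-bin uncertainties are
#' propagated through the squared kernel. `kernel_sigma = 0` returns the
#' profile unchanged.
#'
#' @param profile A [profile1d()] object (uniform bins).
#' @param kernel_sigma Blur width, cm; nonnegative.
#' @param renormalize Rescale so the central value is 100 afterwards?
#' @return A blurred [profile1d()].
#' @export
detector_blur <- function(profile, kernel_sigma, renormalize = TRUE) {
  stopifnot(inherits(profile, "profile1d"), kernel_sigma >= 0)
  if (kernel_sigma == 0) return(profile)
  ctr <- bin_centers(profile)
  nb <- length(ctr)
  K <- outer(ctr, ctr, function(a, b) stats::dnorm(a - b, sd = kernel_sigma))
  K <- sweep(K, 2, colSums(K), "/")   # mass-preserving per input bin
  vals <- as.numeric(K %*% profile$values)
  sig <- sqrt(as.numeric((K^2) %*% profile$sigma^2))
  out <- profile1d(profile$bin_edges, vals, sig, axis = profile$axis,
                   metadata = c(profile$metadata,
                                list(kernel_sigma = kernel_sigma)))
  if (renormalize) out <- normalize_profile(out, "central")
  out
}

#' Square-field jaw/MLC geometry
#'
#' Builds the two-aperture geometry of a square field: one jaw pair
#' limiting y at `jaw_z` and one MLC-defined pair limiting x at `mlc_z`
#' (the MLC sits farther from the source than the jaws on this machine).
#' The side length is defined at `define_at` (default the SSD plane,
#' 100 cm), and each aperture is scaled to its own plane by similar
#' triangles.
#'
#' @param side Field side length at `define_at`, cm.
#' @param jaw_z,mlc_z Aperture plane distances from the source, cm.
#' @param ssd,depth Scoring geometry, cm.
#' @param define_at Plane at which `side` is defined, cm.
#' @return A [beam_geometry()] object.
#' @export
square_field_geometry <- function(side, jaw_z = 22, mlc_z = 31,
                                  ssd = 100, depth = 1.5, define_at = 100) {
  stopifnot(side > 0)
  half <- side / 2
  beam_geometry(list(
    aperture_rect(jaw_z, half_x = 1e3, half_y = half * jaw_z / define_at),
    aperture_rect(mlc_z, half_x = half * mlc_z / define_at, half_y = 1e3)
  ), ssd = ssd, depth = depth)
}

#' Stereotactic-cone geometry
#'
#' A single circular collimator of the given physical aperture diameter
#' mounted at `cone_z` (default 59 cm) from the source.
#'
#' @param diameter_mm Aperture diameter, mm.
#' @param cone_z Collimator distance from the source, cm.
#' @param ssd,depth Scoring geometry, cm.
#' @return A [beam_geometry()] object.
#' @export
cone_geometry <- function(diameter_mm, cone_z = 59, ssd = 100, depth = 1.5) {
  stopifnot(diameter_mm > 0)
  beam_geometry(list(aperture_circle(cone_z, radius = diameter_mm / 20)),
                ssd = ssd, depth = depth)
}
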