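# Metrics on 1-D profiles: normalization, FWHM, 20-80% penumbra, 50% field
# size and profile-difference statistics. Linear interpolation between bin
# centers everywhere; percent levels are relative to the central-axis value.

central_value <- function(p) {
  ctr <- bin_centers(p)
  if (min(p$bin_edges) > 0 || max(p$bin_edges) < 0)
    stop("profile does not cover the beam axis (position 0)", call. = FALSE)
  k <- which.min(abs(ctr))
  list(value = p$values[k], sigma = p$sigma[k], index = k)
}

#' Normalize a profile
#'
#' Rescales profile values (and uncertainties identically) so the reference
#' value equals 100%: either the central-axis value (the bin nearest
#' position 0; mode `"central"`, the convention used for relative dose
#' profiles) or the profile maximum (mode `"max"`).
#'
#' @param p A [profile1d()] object.
#' @param mode `"central"` or `"max"`.
#' @return A normalized [profile1d()].
#' @export
normalize_profile <- function(p, mode = c("central", "max")) {
  stopifnot(inherits(p, "profile1d"))
  mode <- match.arg(mode)
  ref <- if (mode == "central") central_value(p)$value else max(p$values)
  if (!is.finite(ref) || ref == 0)
    stop("cannot normalize: reference value is zero", call. = FALSE)
  profile1d(p$bin_edges, p$values / ref * 100, p$sigma / ref * 100,
            axis = p$axis, metadata = c(p$metadata, list(normalized = mode)))
}

## linear interpolation of the position where the segment (x1,v1)-(x2,v2)
## crosses 'level', with first-order uncertainty from (s1, s2, slevel)
interp_crossing <- function(x1, x2, v1, v2, s1, s2, level, slevel = 0) {
  dx <- x2 - x1
  dv <- v2 - v1
  xc <- x1 + (level - v1) / dv * dx
  d1 <- dx * (level - v2) / dv^2
  d2 <- -dx * (level - v1) / dv^2
  dl <- dx / dv
  list(x = xc, sigma = sqrt(d1^2 * s1^2 + d2^2 * s2^2 + dl^2 * slevel^2))
}

## first crossing of 'level' approached from the outside on one side of the
## profile; side = -1 for left (rising edge), +1 for right (falling edge)
edge_crossing <- function(p, level, side, slevel = 0) {
  ctr <- bin_centers(p)
  v <- p$values
  mask <- if (side < 0) ctr <= 0 else ctr >= 0
  at <- which(v >= level & mask)
  if (!length(at))
    stop(sprintf("level %.4g is not reached on the %s side", level,
                 if (side < 0) "left" else "right"), call. = FALSE)
  i <- if (side < 0) min(at) else max(at)
  j <- i + side   # outer neighbour
  if (j < 1 || j > length(v) || v[j] >= level)
    stop(sprintf("level %.4g is not crossed on the %s side", level,
                 if (side < 0) "left" else "right"), call. = FALSE)
  interp_crossing(ctr[j], ctr[i], v[j], v[i], p$sigma[j], p$sigma[i],
                  level, slevel)
}

#' Estimate the FWHM of a binned profile
#'
#' Finds half of the profile maximum and locates the half-maximum crossing
#' on each side by linear interpolation between the two bin centers
#' bracketing it. The profile must be unimodal at half maximum: exactly one
#' contiguous run of bins at or above the level (otherwise an ambiguity
#' error lists the crossing positions). The uncertainty combines, to first
#' order, the statistical uncertainty of the bracketing bins and of the
#' peak bin defining the level.
#'
#' @param p A [profile1d()] object.
#' @return List with elements `fwhm` and `sigma` (both cm).
#' @export
estimate_fwhm <- function(p) {
  stopifnot(inherits(p, "profile1d"))
  ctr <- bin_centers(p)
  v <- p$values
  imax <- which.max(v)
  level <- v[imax] / 2
  slevel <- p$sigma[imax] / 2
  above <- which(v >= level)
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  if (length(runs) != 1)
    stop("ambiguous FWHM: multiple regions at half maximum, near positions ",
         paste(sprintf("%.4g", ctr[vapply(runs, min, integer(1))]),
               collapse = ", "), call. = FALSE)
  iL <- min(above); iR <- max(above)
  if (iL == 1 || iR == length(v))
    stop("half maximum is not crossed inside the profile range", call. = FALSE)
  left <- interp_crossing(ctr[iL - 1], ctr[iL], v[iL - 1], v[iL],
                          p$sigma[iL - 1], p$sigma[iL], level, slevel)
  right <- interp_crossing(ctr[iR], ctr[iR + 1], v[iR], v[iR + 1],
                           p$sigma[iR], p$sigma[iR + 1], level, slevel)
  list(fwhm = right$x - left$x, sigma = sqrt(left$sigma^2 + right$sigma^2))
}

#' 20-80% penumbra of a profile
#'
#' The lateral distance between the 20% and 80% levels of the central-axis
#' value (100% at the beam axis) on each field edge, located by linear
#' interpolation between bin centers. Reported per side and as the
#' two-side mean.
#'
#' @param p A [profile1d()] object covering the beam axis; typically
#'   normalized to the central value.
#' @param side `"both"`, `"left"` or `"right"`.
#' @return An object of class `"penumbra_result"`: list with `left`,
#'   `right`, `mean` (cm; `NA` for the side not requested) and their
#'   uncertainties `left_sigma`, `right_sigma`.
#' @export
penumbra_20_80 <- function(p, side = c("both", "left", "right")) {
  side <- match.arg(side)
  cv <- central_value(p)
  lev20 <- 0.2 * cv$value; lev80 <- 0.8 * cv$value
  one <- function(s) {
    c20 <- edge_crossing(p, lev20, s, slevel = 0.2 * cv$sigma)
    c80 <- edge_crossing(p, lev80, s, slevel = 0.8 * cv$sigma)
    list(width = abs(c80$x - c20$x),
         sigma = sqrt(c20$sigma^2 + c80$sigma^2))
  }
  left <- if (side != "right") one(-1) else list(width = NA_real_, sigma = NA_real_)
  right <- if (side != "left") one(1) else list(width = NA_real_, sigma = NA_real_)
  structure(list(left = left$width, right = right$width,
                 mean = mean(c(left$width, right$width), na.rm = TRUE),
                 left_sigma = left$sigma, right_sigma = right$sigma),
            class = "penumbra_result")
}

#' @export
print.penumbra_result <- function(x, ...) {
  cat("20-80% penumbra [cm]:\n")
  if (!is.na(x$left))
    cat(sprintf("  left : %.5g +/- %.2g\n", x$left, x$left_sigma))
  if (!is.na(x$right))
    cat(sprintf("  right: %.5g +/- %.2g\n", x$right, x$right_sigma))
  cat(sprintf("  mean : %.5g\n", x$mean))
  invisible(x)
}

#' 50% field size of a profile
#'
#' Distance between the left and right crossings of 50% of the central-axis
#' value, by linear interpolation between bin centers.
#'
#' @param p A [profile1d()] object covering the beam axis.
#' @return Field size, cm.
#' @export
field_size_50 <- function(p) {
  cv <- central_value(p)
  lev <- 0.5 * cv$value
  left <- edge_crossing(p, lev, -1, slevel = 0.5 * cv$sigma)
  right <- edge_crossing(p, lev, 1, slevel = 0.5 * cv$sigma)
  right$x - left$x
}

#' Maximum absolute difference between two profiles
#'
#' Compares two profiles bin by bin and reports the maximum absolute
#' difference in percent of the first profile's central-axis value,
#' together with the full per-position difference series. If the binnings
#' differ, the second profile is resampled onto the first profile's bin
#' centers by linear interpolation; positions outside the overlap are
#' dropped (an error is raised if the supports do not overlap).
#'
#' @param a,b [profile1d()] objects (typically both normalized to their
#'   central value).
#' @return An object of class `"comparison_result"`: list with
#'   `max_abs_diff` (percent of a's central value), `position` of the
#'   maximum, and `difference` (data.frame of position and a - b).
#' @export
max_abs_difference <- function(a, b) {
  stopifnot(inherits(a, "profile1d"), inherits(b, "profile1d"))
  ctr_a <- bin_centers(a)
  if (identical(a$bin_edges, b$bin_edges)) {
    bv <- b$values
    keep <- rep(TRUE, length(ctr_a))
  } else {
    ctr_b <- bin_centers(b)
    if (max(ctr_b) < min(ctr_a) || min(ctr_b) > max(ctr_a))
      stop("profile supports do not overlap", call. = FALSE)
    bv <- stats::approx(ctr_b, b$values, xout = ctr_a, rule = 1)$y
    keep <- !is.na(bv)
  }
  dser <- a$values[keep] - bv[keep]
  cv <- central_value(a)$value
  dpct <- dser / cv * 100
  imax <- which.max(abs(dpct))
  structure(list(max_abs_diff = abs(dpct[imax]),
                 position = ctr_a[keep][imax],
                 difference = data.frame(position = ctr_a[keep],
                                         diff = dpct)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("max |difference| = %.4g%% of central value, at %.4g cm\n",
              x$max_abs_diff, x$position))
  invisible(x)
}

#' Read a 1-D profile from delimited text
#'
#' Reads two or three whitespace/comma-delimited columns (position cm,
#' value, optional per-bin sigma); lines starting with `#` are comments.
#' Positions are taken as bin centers of a uniform binning.
#'
#' @param path File path.
#' @param axis Axis label for the profile.
#' @return A [profile1d()] object.
#' @export
read_profile <- function(path, axis = "x") {
  tab <- utils::read.table(path, comment.char = "#", header = FALSE,
                           sep = "", blank.lines.skip = TRUE)
  if (ncol(tab) == 1)  # try comma separation
    tab <- utils::read.table(path, comment.char = "#", header = FALSE,
                             sep = ",", blank.lines.skip = TRUE)
  if (!ncol(tab) %in% c(2L, 3L))
    stop("profile file must have 2 or 3 columns (position, value[, sigma])",
         call. = FALSE)
  pos <- tab[[1]]
  if (is.unsorted(pos, strictly = TRUE))
    stop("profile positions must be strictly increasing", call. = FALSE)
  w <- if (length(pos) > 1) stats::median(diff(pos)) else 1
  edges <- c(pos - w / 2, pos[length(pos)] + w / 2)
  profile1d(edges, tab[[2]], if (ncol(tab) == 3) tab[[3]] else 0, axis = axis)
}

#' Write a 1-D profile as delimited text
#'
#' Writes bin centers, values and sigma as three tab-separated columns with
#' a `#` comment header; readable by [read_profile()].
#'
#' @param p A [profile1d()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "profile1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gauss2src profile",
               paste0("# axis ", p$axis),
               "# position_cm\tvalue\tsigma"), con)
  df <- as.data.frame(p)
  writeLines(paste(format(df$position, digits = 17),
                   format(df$value, digits = 17),
                   format(df$sigma, digits = 17), sep = "\t"), con)
  invisible(path)
}
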