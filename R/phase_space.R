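# Particle records at a plane: a self-contained columnar phase-space format,
# source phase-space generation, plane projection and fluence reconstruction.

PHSP_MAGIC <- "G2SPHSP1"
KIND_LEVELS <- c("photon", "electron")

#' Phase-space container
#'
#' A set of particle records scored on a plane perpendicular to the beam
#' axis. `records` is a data.frame with columns `kind` ("photon" or
#' "electron"), `energy` (MeV), `x`, `y` (cm at the plane), `u`, `v`, `w`
#' (direction cosines, unit norm) and `weight` (statistical weight).
#'
#' @param records Data.frame of particle records (may have zero rows).
#' @param plane_z Plane position along the beam axis, cm (source plane = 0).
#' @param metadata Named list carried through file round trips (e.g. seed,
#'   n_histories, source configuration hash).
#' @return An object of class `"phase_space"`.
#' @export
phase_space <- function(records, plane_z, metadata = list()) {
  need <- c("kind", "energy", "x", "y", "u", "v", "w", "weight")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!is.finite(plane_z)) stop("'plane_z' must be finite", call. = FALSE)
  records <- records[, need]
  if (nrow(records)) {
    if (any(records$energy <= 0)) stop("energies must be positive", call. = FALSE)
    if (any(records$weight <= 0)) stop("weights must be positive", call. = FALSE)
    nrm <- records$u^2 + records$v^2 + records$w^2
    if (any(abs(nrm - 1) > 1e-9))
      stop("direction cosines must have unit norm (tolerance 1e-9)", call. = FALSE)
    if (!all(records$kind %in% KIND_LEVELS))
      stop("'kind' must be 'photon' or 'electron'", call. = FALSE)
  }
  structure(list(plane_z = plane_z, records = records, metadata = metadata),
            class = "phase_space")
}

#' @export
print.phase_space <- function(x, ...) {
  cat(sprintf("Phase space at z = %g cm: %d records\n",
              x$plane_z, nrow(x$records)))
  if (nrow(x$records)) {
    tab <- table(x$records$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  total weight %.6g, mean energy %.4g MeV\n",
                sum(x$records$weight),
                sum(x$records$weight * x$records$energy) / sum(x$records$weight)))
  }
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a source phase space
#'
#' Samples `n` particles from the mixture source at the source plane
#' (z = 0), assigns energies from the spectrum, gives each an emission
#' direction and propagates it in vacuum to `plane_z`. Emission models:
#' `"parallel"` (u = v = 0, w = 1, transverse coordinates unchanged by
#' propagation) or `"cone"` (directions uniform over the spherical cap of
#' half-angle `theta_max`; `theta_max = 0` reduces to parallel).
#'
#' @param source A [gauss_source()] object.
#' @param spectrum An [energy_spectrum()] object.
#' @param n Number of particles.
#' @param seed Optional integer seed.
#' @param plane_z Scoring plane, cm (default 100, the nominal scoring
#'   distance from the source plane).
#' @param emission_model `"parallel"` or `"cone"`.
#' @param theta_max Cone half-angle, radians (cone model only).
#' @param kind Particle kind label for the records.
#' @return A [phase_space()] object.
#' @export
generate_source_phase_space <- function(source, spectrum, n, seed = NULL,
                                        plane_z = 100,
                                        emission_model = c("parallel", "cone"),
                                        theta_max = 0, kind = "photon") {
  emission_model <- match.arg(emission_model)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pos <- sample_position(source, n)
  energy <- sample_energy(spectrum, n)
  if (emission_model == "parallel" || theta_max == 0) {
    u <- v <- rep(0, n); w <- rep(1, n)
  } else {
    if (theta_max <= 0 || theta_max >= pi / 2)
      stop("'theta_max' must lie in (0, pi/2)", call. = FALSE)
    w <- runif(n, cos(theta_max), 1)
    phi <- runif(n) * 2 * pi
    st <- sqrt(pmax(0, 1 - w^2))
    u <- st * cos(phi); v <- st * sin(phi)
  }
  x <- pos$x + u / w * plane_z
  y <- pos$y + v / w * plane_z
  phase_space(
    data.frame(kind = kind, energy = energy, x = x, y = y,
               u = u, v = v, w = w, weight = 1),
    plane_z = plane_z,
    metadata = list(n_histories = as.integer(n),
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                    emission_model = emission_model))
}

#' Write a phase space to file
#'
#' Two dialects share a text header (magic line, `format`, `plane_z`,
#' `count`, one `meta` line of JSON, then `END_HEADER`). The binary dialect
#' stores per record: kind as one unsigned byte (0 photon, 1 electron)
#' followed by seven little-endian doubles (energy, x, y, u, v, w, weight;
#' 57 bytes per record). The text dialect stores the same columns as
#' tab-separated values, full double precision, one record per line.
#'
#' @param ps A [phase_space()] object.
#' @param path Output file path.
#' @param format `"binary"` (default) or `"text"`.
#' @return `path`, invisibly.
#' @seealso [read_phsp()]
#' @export
write_phsp <- function(ps, path, format = c("binary", "text")) {
  stopifnot(inherits(ps, "phase_space"))
  format <- match.arg(format)
  rec <- ps$records
  meta <- jsonlite::toJSON(ps$metadata, auto_unbox = TRUE, digits = NA)
  header <- c(PHSP_MAGIC,
              paste("format", format),
              paste("plane_z", format(ps$plane_z, digits = 17)),
              paste("count", nrow(rec)),
              paste("meta", meta),
              "END_HEADER")
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    if (nrow(rec)) {
      num <- vapply(rec[, -1], function(col) format(col, digits = 17),
                    character(nrow(rec)))
      num <- matrix(num, nrow = nrow(rec))
      writeLines(paste(rec$kind, apply(num, 1, paste, collapse = "\t"),
                       sep = "\t"), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    if (nrow(rec)) {
      kind_raw <- as.raw(match(rec$kind, KIND_LEVELS) - 1L)
      vals <- t(as.matrix(rec[, c("energy", "x", "y", "u", "v", "w", "weight")]))
      for (i in seq_len(nrow(rec))) {
        writeBin(kind_raw[i], con)
        writeBin(vals[, i], con, size = 8, endian = "little")
      }
    }
  }
  invisible(path)
}

#' Read a phase space from file
#'
#' Reads either dialect written by [write_phsp()], validating the header and
#' the record count; truncated or malformed files raise a format error that
#' names the offending byte offset or line.
#'
#' @param path File path.
#' @return A [phase_space()] object.
#' @export
read_phsp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line))
      stop("phase-space format error: header not terminated by END_HEADER (offset ",
           seek(con, NA), ")", call. = FALSE)
    if (identical(line, "END_HEADER")) break
    header <- c(header, line)
    if (length(header) > 64)
      stop("phase-space format error: runaway header", call. = FALSE)
  }
  if (!length(header) || header[1] != PHSP_MAGIC)
    stop("phase-space format error: bad magic line (byte offset 0)", call. = FALSE)
  getval <- function(key) {
    hit <- grep(paste0("^", key, " "), header, value = TRUE)
    if (length(hit) != 1)
      stop("phase-space format error: missing header key '", key, "'",
           call. = FALSE)
    sub(paste0("^", key, " "), "", hit)
  }
  fmt <- getval("format")
  plane_z <- as.numeric(getval("plane_z"))
  count <- as.integer(getval("count"))
  metadata <- jsonlite::fromJSON(getval("meta"))
  body_off <- seek(con, NA)
  cols <- c("energy", "x", "y", "u", "v", "w", "weight")
  if (fmt == "text") {
    lines <- readLines(con)
    lines <- lines[nzchar(lines)]
    if (length(lines) != count)
      stop("phase-space format error: header count ", count,
           " != body count ", length(lines), call. = FALSE)
    if (count == 0) {
      warning("phase space is empty")
      rec <- data.frame(kind = character(), energy = numeric(), x = numeric(),
                        y = numeric(), u = numeric(), v = numeric(),
                        w = numeric(), weight = numeric())
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(parts) != 8))
        stop("phase-space format error: record at line ",
             which(lengths(parts) != 8)[1], " has wrong field count",
             call. = FALSE)
      m <- do.call(rbind, parts)
      rec <- data.frame(kind = m[, 1])
      for (j in seq_along(cols)) rec[[cols[j]]] <- as.numeric(m[, j + 1])
    }
  } else if (fmt == "binary") {
    rec_bytes <- 57L
    raw_body <- readBin(con, "raw", n = count * rec_bytes + 1L)
    if (length(raw_body) != count * rec_bytes)
      stop("phase-space format error: expected ", count * rec_bytes,
           " body bytes, found ", length(raw_body),
           " (body starts at byte offset ", body_off, ")", call. = FALSE)
    if (count == 0) {
      warning("phase space is empty")
      rec <- data.frame(kind = character(), energy = numeric(), x = numeric(),
                        y = numeric(), u = numeric(), v = numeric(),
                        w = numeric(), weight = numeric())
    } else {
      m <- matrix(raw_body, nrow = rec_bytes)
      kind_idx <- as.integer(m[1, ]) + 1L
      if (any(kind_idx > length(KIND_LEVELS)))
        stop("phase-space format error: unknown particle kind byte", call. = FALSE)
      vals <- matrix(readBin(as.vector(m[-1, ]), "double",
                             n = 7L * count, size = 8, endian = "little"),
                     nrow = 7L)
      rec <- data.frame(kind = KIND_LEVELS[kind_idx])
      for (j in seq_along(cols)) rec[[cols[j]]] <- vals[j, ]
    }
  } else {
    stop("phase-space format error: unknown format '", fmt, "'", call. = FALSE)
  }
  phase_space(rec, plane_z = plane_z, metadata = as.list(metadata))
}

#' Back-project particle records to a plane
#'
#' Extrapolates every record along its straight-line trajectory to
#' `target_z`: \eqn{x' = x + (u/w)(z_t - z_p)} and analogously for y. This
#' is the operation that reconstructs the source image from a downstream
#' phase space (and is its own inverse: projecting back to the original
#' plane restores the original positions). Records with `w = 0` cannot be
#' projected; they are excluded with a warning, and the number excluded is
#' attached as attribute `"n_excluded"`.
#'
#' @param ps A [phase_space()] object.
#' @param target_z Target plane, cm.
#' @return Data.frame with columns `x`, `y`, plus the surviving `energy` and
#'   `weight` columns (convenient for fluence reconstruction); attribute
#'   `n_excluded` counts dropped records.
#' @export
backproject <- function(ps, target_z) {
  stopifnot(inherits(ps, "phase_space"), is.finite(target_z))
  rec <- ps$records
  bad <- rec$w == 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with w = 0 excluded from projection")
    rec <- rec[!bad, ]
  }
  dz <- target_z - ps$plane_z
  out <- data.frame(x = rec$x + rec$u / rec$w * dz,
                    y = rec$y + rec$v / rec$w * dz,
                    energy = rec$energy, weight = rec$weight)
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' 1-D binned profile
#'
#' A binned 1-D profile (fluence, energy fluence, or relative dose proxy)
#' with per-bin statistical uncertainties.
#'
#' @param bin_edges Strictly increasing bin edges, cm.
#' @param values Per-bin values; length `length(bin_edges) - 1`.
#' @param sigma Per-bin statistical uncertainties (same units as `values`);
#'   scalar 0 is recycled.
#' @param axis `"x"`, `"y"` or `"radial"`.
#' @param metadata Optional named list.
#' @return An object of class `"profile1d"`.
#' @export
profile1d <- function(bin_edges, values, sigma = 0, axis = "x",
                      metadata = list()) {
  if (any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  if (length(values) != length(bin_edges) - 1L)
    stop("length(values) must equal length(bin_edges) - 1", call. = FALSE)
  if (length(sigma) == 1L) sigma <- rep(sigma, length(values))
  if (length(sigma) != length(values) || any(sigma < 0))
    stop("'sigma' must be nonnegative, one per bin", call. = FALSE)
  if (!axis %in% c("x", "y", "radial"))
    stop("'axis' must be one of x, y, radial", call. = FALSE)
  structure(list(axis = axis, bin_edges = bin_edges, values = values,
                 sigma = sigma, metadata = metadata),
            class = "profile1d")
}

#' Bin centers of a profile
#' @param p A [profile1d()] object.
#' @return Numeric vector of bin centers, cm.
#' @export
bin_centers <- function(p) {
  stopifnot(inherits(p, "profile1d"))
  (p$bin_edges[-1] + p$bin_edges[-length(p$bin_edges)]) / 2
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("1-D profile along %s: %d bins on [%g, %g] cm\n", x$axis,
              length(x$values), min(x$bin_edges), max(x$bin_edges)))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  ov <- x$metadata$overflow
  if (!is.null(ov) && ov > 0) cat(sprintf("  overflow (outside edges): %g\n", ov))
  invisible(x)
}

#' @export
plot.profile1d <- function(x, ...) {
  graphics::plot(bin_centers(x), x$values, type = "s",
                 xlab = paste(x$axis, "[cm]"), ylab = "value", ...)
  invisible(x)
}

#' @export
as.data.frame.profile1d <- function(x, ...) {
  data.frame(position = bin_centers(x), value = x$values, sigma = x$sigma)
}

#' Energy-fluence profile from particle positions
#'
#' Bins particles along one axis and accumulates energy fluence
#' \eqn{\sum w E} per bin, with the uncorrelated-history uncertainty
#' estimate \eqn{\sqrt{\sum (wE)^2}}. For `axis = "x"` or `"y"` only
#' particles inside a central strip on the orthogonal axis
#' (|orthogonal| <= `strip_halfwidth`) contribute, which turns the 2-D
#' position distribution into a profile through the beam axis; for
#' `axis = "radial"` particles are binned by radius. Particles outside the
#' edges (or the strip) are counted as overflow and reported in the profile
#' metadata. With `density = TRUE`, values and sigma are divided by the bin
#' collection area (bin width x strip width, or the annulus area), giving
#' energy fluence per unit area.
#'
#' @param positions Two-column matrix or data.frame of (x, y), cm.
#' @param energies Particle energies, MeV.
#' @param weights Statistical weights.
#' @param bin_edges Strictly increasing bin edges, cm (for `"radial"`,
#'   nonnegative).
#' @param axis `"x"`, `"y"` or `"radial"`.
#' @param strip_halfwidth Central-strip half-width on the orthogonal axis,
#'   cm (ignored for `"radial"`).
#' @param density Divide by the bin collection area?
#' @return A [profile1d()] with metadata fields `overflow` (energy fluence
#'   outside the edges/strip) and `n_overflow`.
#' @export
energy_fluence_profile <- function(positions, energies, weights, bin_edges,
                                   axis = c("x", "y", "radial"),
                                   strip_halfwidth = 0.5, density = FALSE) {
  axis <- match.arg(axis)
  positions <- as.data.frame(positions)
  n <- nrow(positions)
  if (length(energies) != n || length(weights) != n)
    stop("'positions', 'energies' and 'weights' must have equal length",
         call. = FALSE)
  if (any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  we <- weights * energies
  if (axis == "radial") {
    coord <- sqrt(positions[[1]]^2 + positions[[2]]^2)
    in_strip <- rep(TRUE, n)
    area <- pi * diff(bin_edges^2)
  } else {
    coord <- if (axis == "x") positions[[1]] else positions[[2]]
    ortho <- if (axis == "x") positions[[2]] else positions[[1]]
    in_strip <- abs(ortho) <= strip_halfwidth
    area <- diff(bin_edges) * 2 * strip_halfwidth
  }
  idx <- findInterval(coord, bin_edges, rightmost.closed = TRUE)
  inside <- in_strip & idx >= 1L & idx <= length(bin_edges) - 1L
  nb <- length(bin_edges) - 1L
  vals <- as.numeric(tapply(we[inside], factor(idx[inside], levels = seq_len(nb)),
                            sum, default = 0))
  sig2 <- as.numeric(tapply(we[inside]^2, factor(idx[inside], levels = seq_len(nb)),
                            sum, default = 0))
  sig <- sqrt(sig2)
  if (density) { vals <- vals / area; sig <- sig / area }
  profile1d(bin_edges, vals, sig, axis = axis,
            metadata = list(overflow = sum(we[!inside]),
                            n_overflow = sum(!inside),
                            density = density,
                            strip_halfwidth = if (axis == "radial") NA
                                              else strip_halfwidth))
}
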