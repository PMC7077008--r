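# Axial orientation from the principal axis of the second central moments
# of a pixel coordinate set. Returns degrees in [0, 180); near-isotropic
# shapes (eigenvalues within 1%) are flagged degenerate with angle 0.
mask_orientation <- function(coords) {
  x <- coords[, 1] - mean(coords[, 1])
  y <- coords[, 2] - mean(coords[, 2])
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  tr <- mu20 + mu02
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0 || (l1 - l2) < 0.01 * l1)
    return(list(angle = 0, degenerate = TRUE, lambda = c(l1, l2)))
  ang <- atan2(2 * mu11, mu20 - mu02) / 2 * 180 / pi
  list(angle = ang %% 180, degenerate = FALSE, lambda = c(l1, l2))
}

#' Axial orientation of a gland
#'
#' Angle of the principal axis of the mask's second central moments, in
#' degrees on the axial circle `[0, 180)`. Shapes whose two moment
#' eigenvalues differ by less than 1% are flagged degenerate and assigned
#' angle 0 by convention.
#'
#' @param g a [gland()] with mask area >= 5 px.
#' @return list with `angle_deg` and `degenerate`.
#' @export
orientation <- function(g) {
  stopifnot(inherits(g, "gland"))
  if (sum(g$mask) < 5) stop_domain("gland %d: mask below 5 px minimum", g$id)
  o <- mask_orientation(mask_coords(g$mask, g$offset))
  list(angle_deg = o$angle, degenerate = o$degenerate)
}

#' Per-gland shape and size descriptors
#'
#' Area is measured on the rasterized mask, perimeter on the boundary
#' polygon; circularity is \eqn{4\pi A/P^2} (1 for a disc). Eccentricity and
#' the minor/major axis ratio come from the mask's moment eigenvalues,
#' solidity from the convex hull of the boundary, and the boundary fractal
#' dimension from box counting. `fourier_energy` holds the magnitudes of the
#' first 10 harmonics of the complex boundary (x + iy) DFT, normalized by
#' the first harmonic, which makes them invariant to the starting vertex
#' and to scale.
#'
#' @param g a [gland()].
#' @return list of class `shape_descriptors`: `area`, `perimeter`,
#'   `circularity`, `eccentricity`, `solidity`, `axis_ratio`,
#'   `equivalent_diameter`, `fractal_dimension`, `fourier_energy` (length 10).
#' @export
shape_descriptors <- function(g) {
  stopifnot(inherits(g, "gland"))
  if (nrow(g$boundary) < 3 || !is_simple_polygon(g$boundary))
    stop_domain("gland %d: degenerate boundary polygon", g$id)
  area <- sum(g$mask)
  perim <- polygon_perimeter(g$boundary)
  circ <- 4 * pi * area / perim^2
  co <- mask_coords(g$mask, g$offset)
  mo <- mask_orientation(co)
  l1 <- mo$lambda[1]; l2 <- max(mo$lambda[2], 0)
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  axr <- if (l1 > 0) sqrt(l2 / l1) else 1
  hull <- g$boundary[rev(grDevices::chull(g$boundary)), , drop = FALSE]
  hull_area <- polygon_area(hull)
  solidity <- min(1, polygon_area(g$boundary) / max(hull_area, 1e-9))
  structure(list(
    area = area,
    perimeter = perim,
    circularity = circ,
    eccentricity = ecc,
    solidity = solidity,
    axis_ratio = axr,
    equivalent_diameter = sqrt(4 * area / pi),
    fractal_dimension = fractal_dimension(g$boundary),
    fourier_energy = boundary_fourier_energy(g$boundary)
  ), class = "shape_descriptors")
}

# |DFT| of the complex boundary, harmonics 1..10 normalized by harmonic 1;
# exactly invariant under cyclic shift of the vertex sequence
boundary_fourier_energy <- function(poly, n_harmonics = 10L) {
  z <- complex(real = poly[, 1], imaginary = poly[, 2])
  co <- fft(z) / length(z)
  mags <- Mod(co)
  denom <- max(mags[2], 1e-12)  # harmonic 1 (index 2; index 1 is the centroid)
  out <- numeric(n_harmonics)
  avail <- min(n_harmonics, length(mags) - 1L)
  if (avail > 0) out[seq_len(avail)] <- mags[1L + seq_len(avail)] / denom
  out
}

#' Box-counting fractal dimension of a boundary
#'
#' The boundary is resampled at ~0.5 px arc-length steps, covered with
#' square boxes of side s in {2, 4, 8, 16, 32, 64} anchored at the
#' bounding-box corner, and the dimension is the least-squares slope of
#' log N(s) against log(1/s). Smooth curves give values near 1; convoluted
#' gland boundaries approach 2.
#'
#' @param boundary `n x 2` matrix of (x, y) points along the curve.
#' @param closed close the curve back to its first point (TRUE for gland
#'   boundaries; FALSE for open polylines).
#' @return Estimated dimension (dimensionless).
#' @export
fractal_dimension <- function(boundary, closed = TRUE) {
  boundary <- as.matrix(boundary)
  pts <- resample_curve(boundary, step = 0.25, closed = closed)
  if (nrow(pts) < 16) stop_domain("boundary too short: < 16 resampled points")
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  sizes <- c(2, 4, 8, 16, 32, 64)
  if (span < sizes[1]) stop_domain("boundary extent below the smallest box scale")
  # box scales comparable to the input's own vertex spacing see mostly the
  # straight interpolation segments between vertices and bias the slope
  # toward 1; fit only in the scaling regime (scales >= 1.5x the vertex
  # spacing), always keeping the 3 largest scales so the fit is well posed
  seg_len <- sqrt(rowSums(diff(boundary)^2))
  res <- median(seg_len)
  keep <- sizes >= 1.5 * res
  if (sum(keep) < 3) keep <- sizes %in% utils::tail(sizes, 3)
  # boxes comparable to the whole object saturate (N -> 1) and inflate the
  # slope; cap the coarsest scale at a quarter of the span
  keep_span <- sizes <= span / 4
  if (sum(keep & keep_span) >= 3) keep <- keep & keep_span
  sizes <- sizes[keep]
  x0 <- min(pts[, 1]); y0 <- min(pts[, 2])
  counts <- vapply(sizes, function(s) {
    ix <- floor((pts[, 1] - x0) / s)
    iy <- floor((pts[, 2] - y0) / s)
    length(unique(ix * 1e6 + iy))
  }, numeric(1))
  keep <- counts > 0
  fit <- stats::lm.fit(cbind(1, log(1 / sizes[keep])), log(counts[keep]))
  unname(fit$coefficients[2])
}

# resample a polyline/polygon at fixed arc-length steps
resample_curve <- function(pts, step = 0.5, closed = TRUE) {
  if (closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(pts[1, , drop = FALSE])
  s <- seq(0, total, by = step)
  xi <- stats::approx(cum, pts[, 1], xout = s, ties = "ordered")$y
  yi <- stats::approx(cum, pts[, 2], xout = s, ties = "ordered")$y
  cbind(xi, yi)
}

#' Neighborhood statistics of a per-gland value
#'
#' For each gland, computes a statistic of `values` restricted to that
#' gland's neighborhood (typically itself plus its graph neighbors) — the
#' local-disorder building block behind features such as the mean
#' neighborhood entropy of circularity. Entropy is in bits with
#' `0 log 0 = 0`; energy is the sum of squared bin proportions. Bins for
#' entropy/energy are laid on the observed min-max range of the whole
#' image's values, so a constant image yields entropy 0.
#'
#' @param values numeric vector, one value per gland.
#' @param neighborhoods list of integer index vectors, one per gland,
#'   each non-empty.
#' @param stat one of "mean", "sd", "entropy", "energy".
#' @param nbins number of bins for entropy/energy (>= 2).
#' @return numeric vector, one statistic per gland.
#' @export
local_statistic <- function(values, neighborhoods,
                            stat = c("mean", "sd", "entropy", "energy"),
                            nbins = 10L) {
  stat <- match.arg(stat)
  if (any(lengths(neighborhoods) == 0)) stop_domain("empty neighborhood")
  if (stat %in% c("entropy", "energy")) {
    if (nbins < 2) stop_domain("nbins must be >= 2 for entropy/energy")
    rng <- range(values)
    if (diff(rng) <= max(1e-12, 1e-9 * max(abs(rng)))) {
      # constant values: single occupied bin => entropy 0, energy 1
      return(vapply(neighborhoods, function(nb)
        if (stat == "entropy") 0 else 1, numeric(1)))
    }
    bin <- pmin(nbins, 1L + floor((values - rng[1]) / diff(rng) * nbins))
  }
  vapply(neighborhoods, function(nb) {
    v <- values[nb]
    switch(stat,
      mean = mean(v),
      sd = if (length(v) > 1) sd(v) else 0,
      entropy = {
        p <- tabulate(bin[nb], nbins) / length(nb)
        p <- p[p > 0]
        -sum(p * log2(p))
      },
      energy = {
        p <- tabulate(bin[nb], nbins) / length(nb)
        sum(p^2)
      })
  }, numeric(1))
}
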