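#' @include AllClasses.R
NULL

# --- Ellipsoid shape primitives -------------------------------------------
#
# Cell bodies are axis-aligned ellipsoids (lateral semi-axes a, b; vertical
# semi-axis c along the apical-basal direction). Two approximations of the
# cell-cell contact area coexist:
#
#   * "fast": each cell is replaced by a sphere whose radius equals its radial
#     extent along the centre-centre line, and the area of the sphere-sphere
#     intersection circle is returned. For strongly oblate cells this
#     overestimates contact at narrow (lateral) edges and underestimates it at
#     broad, flat (apico-basal) edges -- a bias the corneocyte adhesion rule
#     exploits to obtain lateral-dominant adhesion and interdigitation.
#
#   * "accurate": the cross-section of the ellipsoid-ellipsoid overlap region
#     on the separating plane normal to the contact axis, placed at the
#     mid-point of the overlap segment. The section of each ellipsoid by that
#     plane is an ellipse; the area of the intersection of the two convex
#     sections is integrated in polar form around a point interior to both
#     (exact per-ray root finding, trapezoidal rule in the angle). Used
#     wherever the physical interface area matters, e.g. for transport.

#' Radial extent of an ellipsoid
#'
#' Distance from the centre to the surface of an axis-aligned ellipsoid along
#' a direction, from the closed form of the quadratic surface:
#' \eqn{r(u) = (u_x^2/a^2 + u_y^2/b^2 + u_z^2/c^2)^{-1/2}} for unit `u`.
#'
#' @param semiAxes numeric length-3 `(a, b, c)`, strictly positive (um).
#' @param direction numeric length-3 direction; normalized internally, but a
#'   zero-norm direction is an error.
#' @return Distance centre-to-surface (um).
#' @examples
#' radialExtent(c(5, 5, 5), c(0, 1, 0)) # sphere: 5
#' radialExtent(c(15, 15, 0.5), c(0, 0, 1)) # vertical semi-axis
#' @export
radialExtent <- function(semiAxes, direction) {
  stopifnot(length(semiAxes) == 3L, length(direction) == 3L)
  if (any(semiAxes <= 0)) stop("semi-axes must be strictly positive")
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("direction must have non-zero norm")
  u <- direction / nrm
  1 / sqrt(sum((u / semiAxes)^2))
}

# Vectorized radial extents: semi (n x 3), u (n x 3, unit rows).
radialExtentRows <- function(semi, u) {
  1 / sqrt((u[, 1] / semi[, 1])^2 + (u[, 2] / semi[, 2])^2 + (u[, 3] / semi[, 3])^2)
}

#' Overlap depth between two ellipsoid cells
#'
#' \eqn{\delta = \max(0, r_A + r_B - d)} where \eqn{r_A, r_B} are the radial
#' extents of the two bodies along the centre-centre line and \eqn{d} the
#' centre distance. \eqn{\delta > 0} is the contact criterion defining "direct
#' neighbours". For coincident centres the direction is undefined; the vertical
#' axis is used conventionally, and the result carries
#' `attr(, "degenerate") = TRUE`.
#'
#' @param centreA,centreB length-3 centre positions (um).
#' @param semiA,semiB length-3 semi-axes (um).
#' @return Overlap depth (um), possibly with a `degenerate` attribute.
#' @export
overlapDepth <- function(centreA, semiA, centreB, semiB) {
  dvec <- centreB - centreA
  d <- sqrt(sum(dvec^2))
  if (d < 1e-12) {
    res <- radialExtent(semiA, c(0, 0, 1)) + radialExtent(semiB, c(0, 0, 1))
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  u <- dvec / d
  max(0, radialExtent(semiA, u) + radialExtent(semiB, u) - d)
}

# Sphere-sphere intersection-circle area for radii rA, rB at centre distance d.
# Vectorized. Returns 0 when disjoint; the full small-circle area when one
# sphere is engulfed.
sphereLensArea <- function(rA, rB, d) {
  area <- numeric(length(d))
  engulf <- d <= abs(rA - rB)
  area[engulf] <- pi * pmin(rA, rB)[engulf]^2
  ov <- !engulf & d < rA + rB
  if (any(ov)) {
    x <- (d[ov]^2 - rB[ov]^2 + rA[ov]^2) / (2 * d[ov])
    h2 <- pmax(0, rA[ov]^2 - x^2)
    area[ov] <- pi * h2
  }
  area
}

#' Fast (sphere-based) contact area
#'
#' Each cell is treated as a sphere of radius equal to its radial extent along
#' the centre line; the area of the sphere-sphere intersection circle is
#' returned (0 if disjoint). By construction this overestimates contact at
#' narrow edges and underestimates it at broad flat edges of strongly oblate
#' cells.
#'
#' @inheritParams overlapDepth
#' @return Contact area (um^2).
#' @examples
#' # equal spheres r = 5 at distance 8: lens circle radius^2 = 25 - 16
#' contactAreaFast(c(0, 0, 0), c(5, 5, 5), c(8, 0, 0), c(5, 5, 5)) # 9 * pi
#' @export
contactAreaFast <- function(centreA, semiA, centreB, semiB) {
  dvec <- centreB - centreA
  d <- sqrt(sum(dvec^2))
  if (d < 1e-12) stop("coincident centres: contact axis undefined")
  u <- dvec / d
  rA <- radialExtent(semiA, u)
  rB <- radialExtent(semiB, u)
  sphereLensArea(rA, rB, d)
}

# Accurate contact areas for a batch of cell pairs, all expressed in the frame
# where A sits at the origin and B at distance d along the unit axis u.
#   semiA, semiB: n x 3; u: n x 3 (unit rows); d, rA, rB: length n.
# nAngles controls the polar quadrature; the integrand is smooth and periodic,
# so the trapezoidal rule converges spectrally.
accurateAreaRows <- function(semiA, semiB, u, d, rA, rB, nAngles = 48L) {
  n <- length(d)
  area <- numeric(n)
  ov <- which(rA + rB - d > 0)
  if (!length(ov)) return(area)

  uo <- u[ov, , drop = FALSE]
  tStar <- (d[ov] - rB[ov] + rA[ov]) / 2 # mid-overlap point along the axis

  # Orthonormal basis (e1, e2) of the separating plane.
  useZ <- abs(uo[, 3]) < 0.9
  kx <- ifelse(useZ, 0, 1)
  kz <- ifelse(useZ, 1, 0)
  e1x <- uo[, 2] * kz
  e1y <- uo[, 3] * kx - uo[, 1] * kz
  e1z <- -uo[, 2] * kx
  n1 <- sqrt(e1x^2 + e1y^2 + e1z^2)
  e1x <- e1x / n1; e1y <- e1y / n1; e1z <- e1z / n1
  e2x <- uo[, 2] * e1z - uo[, 3] * e1y
  e2y <- uo[, 3] * e1x - uo[, 1] * e1z
  e2z <- uo[, 1] * e1y - uo[, 2] * e1x

  theta <- (seq_len(nAngles) - 1) * (2 * pi / nAngles)
  ct <- cos(theta); st <- sin(theta)

  # Ray directions v (m x nAngles per coordinate), m = length(ov).
  vx <- outer(e1x, ct) + outer(e2x, st)
  vy <- outer(e1y, ct) + outer(e2y, st)
  vz <- outer(e1z, ct) + outer(e2z, st)

  rho2 <- NULL
  for (side in 1:2) {
    semi <- if (side == 1) semiA[ov, , drop = FALSE] else semiB[ov, , drop = FALSE]
    # Plane point relative to this ellipsoid's centre: tStar * u (side A) or
    # (tStar - d) * u (side B).
    tRel <- if (side == 1) tStar else tStar - d[ov]
    px <- tRel * uo[, 1]; py <- tRel * uo[, 2]; pz <- tRel * uo[, 3]
    ia2 <- 1 / semi[, 1]^2; ib2 <- 1 / semi[, 2]^2; ic2 <- 1 / semi[, 3]^2
    Aq <- vx^2 * ia2 + vy^2 * ib2 + vz^2 * ic2
    Bq <- 2 * (vx * (px * ia2) + vy * (py * ib2) + vz * (pz * ic2))
    Cq <- px^2 * ia2 + py^2 * ib2 + pz^2 * ic2
    disc <- pmax(0, Bq^2 - 4 * Aq * (Cq - 1))
    rho <- (-Bq + sqrt(disc)) / (2 * Aq)
    rho[Cq >= 1] <- 0 # plane point outside this body: empty along the ray
    rho <- pmax(rho, 0)
    rho2 <- if (is.null(rho2)) rho else pmin(rho2, rho)
  }
  area[ov] <- (2 * pi / nAngles) * 0.5 * rowSums(rho2^2)
  area
}

#' Accurate (separating-plane cross-section) contact area
#'
#' Area of the cross-section of the ellipsoid-ellipsoid overlap region on the
#' plane normal to the contact axis at the mid-point of the overlap segment.
#' Each planar section is an ellipse; their convex intersection is integrated
#' exactly along polar rays with a trapezoidal angular quadrature whose
#' resolution is chosen from `tolerance`.
#'
#' @inheritParams overlapDepth
#' @param tolerance requested relative accuracy (> 0); controls the angular
#'   resolution.
#' @return Contact area (um^2); 0 for disjoint bodies.
#' @examples
#' # reduces to the sphere lens circle for spherical cells
#' contactAreaAccurate(c(0, 0, 0), c(5, 5, 5), c(8, 0, 0), c(5, 5, 5))
#' @export
contactAreaAccurate <- function(centreA, semiA, centreB, semiB, tolerance = 1e-3) {
  if (tolerance <= 0) stop("tolerance must be positive")
  # Canonical argument order makes the quadrature exactly symmetric in A, B.
  ord <- order(c(
    paste(signif(c(centreA, semiA), 12), collapse = ","),
    paste(signif(c(centreB, semiB), 12), collapse = ",")
  ))
  if (ord[1] == 2L) {
    tmp <- centreA; centreA <- centreB; centreB <- tmp
    tmp <- semiA; semiA <- semiB; semiB <- tmp
  }
  dvec <- centreB - centreA
  d <- sqrt(sum(dvec^2))
  if (d < 1e-12) stop("coincident centres: contact axis undefined")
  u <- dvec / d
  rA <- radialExtent(semiA, u)
  rB <- radialExtent(semiB, u)
  if (rA + rB - d <= 0) return(0)
  nAngles <- max(48L, min(1024L, as.integer(ceiling(2 * pi / sqrt(tolerance)))))
  accurateAreaRows(
    matrix(semiA, 1), matrix(semiB, 1), matrix(u, 1), d, rA, rB,
    nAngles = nAngles
  )[1]
}
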