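#' @include AllClasses.R geometry.R membrane.R
NULL

# Candidate cell pairs by uniform spatial binning. Bin size >= the maximum
# bounding diameter, so any contacting pair shares a bin or sits in adjacent
# bins; lateral bins wrap periodically. Returns a 2-column matrix of row
# indices (i < j after deduplication).
candidatePairs <- function(x, y, z, maxRadius, Lx, Ly) {
  n <- length(x)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  s <- 2 * maxRadius * 1.0001
  nbx <- max(1L, as.integer(floor(Lx / s)))
  nby <- max(1L, as.integer(floor(Ly / s)))
  sx <- Lx / nbx
  sy <- Ly / nby
  zmin <- min(z)
  nbz <- max(1L, as.integer(ceiling((max(z) - zmin + 1e-9) / s)))
  ix <- pmin(nbx - 1L, as.integer(floor(wrapCoord(x, Lx) / sx)))
  iy <- pmin(nby - 1L, as.integer(floor(wrapCoord(y, Ly) / sy)))
  iz <- pmin(nbz - 1L, as.integer(floor((z - zmin) / s)))
  key <- ix + nbx * (iy + nby * iz)
  byBin <- split(seq_len(n), key)
  binOf <- function(bx, by, bz) {
    (bx %% nbx) + nbx * ((by %% nby) + nby * bz)
  }
  # Half-space offsets: each unordered bin pair visited once.
  offs <- rbind(
    c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(-1L, 1L, 0L),
    cbind(rep(-1:1, 3L), rep(-1:1, each = 3L), 1L)
  )
  pairs <- vector("list", length(byBin) * nrow(offs))
  np <- 0L
  keys <- as.integer(names(byBin))
  for (bi in seq_along(byBin)) {
    k <- keys[bi]
    bx <- k %% nbx
    by <- (k %/% nbx) %% nby
    bz <- k %/% (nbx * nby)
    A <- byBin[[bi]]
    for (oi in seq_len(nrow(offs))) {
      o <- offs[oi, ]
      if (bz + o[3L] >= nbz) next
      if (all(o == 0L)) {
        if (length(A) > 1L) {
          np <- np + 1L
          pairs[[np]] <- t(utils::combn(A, 2L))
        }
      } else {
        B <- byBin[[as.character(binOf(bx + o[1L], by + o[2L], bz + o[3L]))]]
        if (!is.null(B)) {
          np <- np + 1L
          pairs[[np]] <- cbind(
            rep(A, times = length(B)),
            rep(B, each = length(A))
          )
        }
      }
    }
  }
  if (!np) return(matrix(integer(0), ncol = 2L))
  pm <- do.call(rbind, pairs[seq_len(np)])
  pm <- pm[pm[, 1L] != pm[, 2L], , drop = FALSE]
  pm <- cbind(pmin(pm[, 1L], pm[, 2L]), pmax(pm[, 1L], pm[, 2L]))
  pm[!duplicated(pm[, 1L] + (max(pm[, 2L]) + 1) * pm[, 2L] * 1.0), , drop = FALSE]
}

#' Build the cell-cell contact graph
#'
#' Detects all pairs of cells whose ellipsoid bodies overlap along the
#' centre-centre line (overlap depth > 0; the "direct neighbour" criterion for
#' all forces and transport), using uniform spatial binning with bin size at
#' least the maximum bounding diameter and minimum-image lateral displacements
#' on the periodic domain. Each edge is annotated with the contact axis, the
#' overlap depth and both contact-area approximations. Cells with no contact
#' pressing on their apical side and no other cell body overhead are marked
#' surface-exposed, with exposed area estimated as their lateral cross-section
#' \eqn{\pi a b}.
#'
#' Coincident centres (degenerate contact axis) are resolved by displacing the
#' higher-indexed cell by a tiny random lateral offset drawn from the current
#' RNG stream.
#'
#' @param tissue a [Tissue-class].
#' @param membrane a [MembraneGeometry-class] (provides the periodic domain).
#' @param nAngles angular resolution of the accurate contact-area quadrature.
#' @return A [ContactGraph-class].
#' @export
buildContactGraph <- function(tissue, membrane, nAngles = 48L) {
  cl <- tissue@cells
  n <- nrow(cl)
  emptyEdges <- data.frame(
    i = integer(0), j = integer(0), idA = integer(0), idB = integer(0),
    ux = numeric(0), uy = numeric(0), uz = numeric(0), d = numeric(0),
    rA = numeric(0), rB = numeric(0), depth = numeric(0),
    areaFast = numeric(0), areaAccurate = numeric(0)
  )
  if (n == 0L) {
    return(new("ContactGraph",
      ids = integer(0), edges = emptyEdges,
      exposed = logical(0), exposedArea = numeric(0)
    ))
  }
  maxR <- max(cl$a, cl$b, cl$c)
  pm <- candidatePairs(cl$x, cl$y, cl$z, maxR, membrane@Lx, membrane@Ly)
  if (nrow(pm)) {
    i <- pm[, 1L]; j <- pm[, 2L]
    dx <- wrapDelta(cl$x[j] - cl$x[i], membrane@Lx)
    dy <- wrapDelta(cl$y[j] - cl$y[i], membrane@Ly)
    dz <- cl$z[j] - cl$z[i]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    deg <- which(d < 1e-9)
    if (length(deg)) {
      # Deterministic-by-stream tiny displacement resolves coincident centres.
      ang <- runif(length(deg), 0, 2 * pi)
      cl$x[j[deg]] <- cl$x[j[deg]] + 1e-4 * cos(ang)
      cl$y[j[deg]] <- cl$y[j[deg]] + 1e-4 * sin(ang)
      dx <- wrapDelta(cl$x[j] - cl$x[i], membrane@Lx)
      dy <- wrapDelta(cl$y[j] - cl$y[i], membrane@Ly)
      d <- sqrt(dx^2 + dy^2 + dz^2)
    }
    ux <- dx / d; uy <- dy / d; uz <- dz / d
    semi <- cbind(cl$a, cl$b, cl$c)
    u <- cbind(ux, uy, uz)
    rA <- radialExtentRows(semi[i, , drop = FALSE], u)
    rB <- radialExtentRows(semi[j, , drop = FALSE], u)
    depth <- rA + rB - d
    keep <- depth > 0
    edges <- data.frame(
      i = i[keep], j = j[keep], idA = cl$id[i[keep]], idB = cl$id[j[keep]],
      ux = ux[keep], uy = uy[keep], uz = uz[keep], d = d[keep],
      rA = rA[keep], rB = rB[keep], depth = depth[keep]
    )
    if (nrow(edges)) {
      edges$areaFast <- sphereLensArea(edges$rA, edges$rB, edges$d)
      edges$areaAccurate <- accurateAreaRows(
        semi[edges$i, , drop = FALSE], semi[edges$j, , drop = FALSE],
        cbind(edges$ux, edges$uy, edges$uz),
        edges$d, edges$rA, edges$rB, nAngles = nAngles
      )
    } else {
      edges$areaFast <- numeric(0)
      edges$areaAccurate <- numeric(0)
    }
  } else {
    edges <- emptyEdges
  }

  exposed <- surfaceExposure(cl, edges, membrane)
  new("ContactGraph",
    ids = cl$id, edges = edges, exposed = exposed,
    exposedArea = ifelse(exposed, pi * cl$a * cl$b, 0)
  )
}

# Surface exposure: a cell is exposed when its apical surface reaches (within
# a small margin) the local tissue surface -- the topmost body surface among
# all cells whose lateral footprint covers it. Cells buried under overlying
# bodies have an obstructed line to the exterior and are not exposed; the
# margin admits the full rugged top layer rather than only the single highest
# cell.
surfaceExposure <- function(cl, edges, membrane, coverFactor = 0.9,
                            margin = 1.5) {
  n <- nrow(cl)
  if (n == 0L) return(logical(0))
  if (n == 1L) return(TRUE)
  dxm <- wrapDelta(outer(cl$x, cl$x, "-"), membrane@Lx)
  dym <- wrapDelta(outer(cl$y, cl$y, "-"), membrane@Ly)
  lat <- sqrt(dxm^2 + dym^2)
  covers <- sweep(lat, 2L, coverFactor * pmax(cl$a, cl$b), "<") # [i, j]: j over i
  top <- matrix(rep(cl$z + cl$c, each = n), n, n)
  top[!covers] <- -Inf
  localSurf <- pmax(apply(top, 1L, max), cl$z + cl$c)
  (localSurf - (cl$z + cl$c)) < margin
}
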