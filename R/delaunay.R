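#' @include AllClasses.R
NULL

# 2D Delaunay triangulation by incremental insertion (Bowyer-Watson).
# Implemented in-package because no Delaunay library is part of the package's
# dependency set; sized for the few hundred points of a tissue cross section.
# Returns a matrix of triangles (rows of vertex indices into `points`).
delaunayTriangles <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points")
  rng <- apply(pts, 2L, range)
  span <- max(rng[2L, ] - rng[1L, ], 1e-6)
  cx <- mean(rng[, 1L])
  cy <- mean(rng[, 2L])
  # Super-triangle comfortably containing all points.
  big <- 64 * span
  P <- rbind(
    pts,
    c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big)
  )
  super <- n + 1:3
  tris <- matrix(super, nrow = 1L)

  circum <- function(tri) {
    ax <- P[tri[1L], 1L]; ay <- P[tri[1L], 2L]
    bx <- P[tri[2L], 1L]; by <- P[tri[2L], 2L]
    cxx <- P[tri[3L], 1L]; cyy <- P[tri[3L], 2L]
    d <- 2 * (ax * (by - cyy) + bx * (cyy - ay) + cxx * (ay - by))
    if (abs(d) < 1e-12 * span^2) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cyy) + (bx^2 + by^2) * (cyy - ay) +
      (cxx^2 + cyy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cxx - bx) + (bx^2 + by^2) * (ax - cxx) +
      (cxx^2 + cyy^2) * (bx - ax)) / d
    c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
  }
  cc <- t(apply(tris, 1L, circum))

  for (p in seq_len(n)) {
    px <- P[p, 1L]; py <- P[p, 2L]
    bad <- which((px - cc[, 1L])^2 + (py - cc[, 2L])^2 <= cc[, 3L] * (1 + 1e-12))
    if (!length(bad)) {
      # Numerical fallback: attach to the nearest triangle's cavity.
      d2 <- (px - cc[, 1L])^2 + (py - cc[, 2L])^2 - cc[, 3L]
      bad <- which.min(d2)
    }
    badTris <- tris[bad, , drop = FALSE]
    edges <- rbind(
      badTris[, c(1L, 2L), drop = FALSE],
      badTris[, c(2L, 3L), drop = FALSE],
      badTris[, c(3L, 1L), drop = FALSE]
    )
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newTris <- cbind(boundary, p)
    tris <- rbind(tris, newTris)
    cc <- rbind(cc, t(apply(newTris, 1L, circum)))
  }
  keep <- rowSums(matrix(tris %in% super, nrow = nrow(tris))) == 0L
  tris[keep, , drop = FALSE]
}

# Adjacency degree of each point in the Delaunay triangulation.
delaunayDegrees <- function(points) {
  tris <- delaunayTriangles(points)
  edges <- rbind(
    tris[, c(1L, 2L), drop = FALSE],
    tris[, c(2L, 3L), drop = FALSE],
    tris[, c(3L, 1L), drop = FALSE]
  )
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges <- unique(edges)
  tabulate(c(edges[, 1L], edges[, 2L]), nbins = nrow(as.matrix(points)))
}
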