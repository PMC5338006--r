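# Independent oracles used to validate the geometric primitives. These are
# deliberately naive (ray marching, Monte-Carlo integration, all-pairs
# scans, exhaustive circumcircle checks) and share no code with the package
# implementations they check.

# Ray-march from the centre along `direction` until the implicit ellipsoid
# surface is crossed; bisect to tolerance.
rayMarchRadialExtent <- function(semi, direction, tol = 1e-8) {
  u <- direction / sqrt(sum(direction^2))
  inside <- function(t) sum(((t * u) / semi)^2) <= 1
  hi <- max(semi) * 2
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (inside(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Monte-Carlo area of the cross-section of the two-ellipsoid overlap on the
# mid-overlap separating plane: sample the plane uniformly on a bounding
# square and count points interior to both bodies.
monteCarloPlaneArea <- function(centreA, semiA, centreB, semiB, nSamples = 2e5,
                                seed = 99L) {
  set.seed(seed)
  dvec <- centreB - centreA
  d <- sqrt(sum(dvec^2))
  u <- dvec / d
  rA <- 1 / sqrt(sum((u / semiA)^2))
  rB <- 1 / sqrt(sum((u / semiB)^2))
  if (rA + rB <= d) return(0)
  p <- centreA + ((d - rB + rA) / 2) * u
  k <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(
    u[2] * k[3] - u[3] * k[2], u[3] * k[1] - u[1] * k[3],
    u[1] * k[2] - u[2] * k[1]
  )
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  half <- min(max(semiA), max(semiB))
  s1 <- runif(nSamples, -half, half)
  s2 <- runif(nSamples, -half, half)
  px <- p[1] + s1 * e1[1] + s2 * e2[1]
  py <- p[2] + s1 * e1[2] + s2 * e2[2]
  pz <- p[3] + s1 * e1[3] + s2 * e2[3]
  inA <- ((px - centreA[1]) / semiA[1])^2 + ((py - centreA[2]) / semiA[2])^2 +
    ((pz - centreA[3]) / semiA[3])^2 <= 1
  inB <- ((px - centreB[1]) / semiB[1])^2 + ((py - centreB[2]) / semiB[2])^2 +
    ((pz - centreB[3]) / semiB[3])^2 <= 1
  mean(inA & inB) * (2 * half)^2
}

# All-pairs contact detection with minimum-image lateral displacements.
bruteForceContacts <- function(cl, Lx, Ly) {
  n <- nrow(cl)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- cl$x[j] - cl$x[i]
      dx <- dx - Lx * round(dx / Lx)
      dy <- cl$y[j] - cl$y[i]
      dy <- dy - Ly * round(dy / Ly)
      dz <- cl$z[j] - cl$z[i]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      if (d < 1e-12) next
      u <- c(dx, dy, dz) / d
      rA <- 1 / sqrt(sum((u / c(cl$a[i], cl$b[i], cl$c[i]))^2))
      rB <- 1 / sqrt(sum((u / c(cl$a[j], cl$b[j], cl$c[j]))^2))
      if (rA + rB - d > 0) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, out)
}

# A triangle belongs to the Delaunay triangulation iff its circumcircle is
# empty of all other points; enumerate all triangles (small n only) and
# derive the neighbour degrees.
bruteForceDelaunayDegrees <- function(pts) {
  n <- nrow(pts)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        ax <- pts[i, 1]; ay <- pts[i, 2]
        bx <- pts[j, 1]; by <- pts[j, 2]
        cx <- pts[k, 1]; cy <- pts[k, 2]
        dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(dd) < 1e-12) next
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
          (cx^2 + cy^2) * (ay - by)) / dd
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
          (cx^2 + cy^2) * (bx - ax)) / dd
        r2 <- (ax - ux)^2 + (ay - uy)^2
        empty <- TRUE
        for (m in seq_len(n)) {
          if (m %in% c(i, j, k)) next
          if ((pts[m, 1] - ux)^2 + (pts[m, 2] - uy)^2 < r2 * (1 - 1e-12)) {
            empty <- FALSE
            break
          }
        }
        if (empty) {
          adj[i, j] <- adj[j, i] <- TRUE
          adj[j, k] <- adj[k, j] <- TRUE
          adj[i, k] <- adj[k, i] <- TRUE
        }
      }
    }
  }
  rowSums(adj)
}

# Random loose cell cluster used by mechanics/contact tests.
randomTestTissue <- function(n, Lx = 60, Ly = 60, zMax = 30, seed = 7L) {
  set.seed(seed)
  cl <- emptyCellTable(n)
  cl$id <- seq_len(n)
  cl$type <- sample(c("SS", "SG", "SC"), n, replace = TRUE)
  cl$x <- runif(n, 0, Lx)
  cl$y <- runif(n, 0, Ly)
  cl$z <- runif(n, 2, zMax)
  cl$a <- runif(n, 3, 8)
  cl$b <- runif(n, 3, 8)
  cl$c <- runif(n, 0.5, 5)
  cl$water <- runif(n, 20, 90)
  cl$caMobile <- runif(n, 0, 2)
  cl$adhesion <- runif(n, 0.2, 1)
  cl$cycleLen <- 10L
  new("Tissue", cells = cl, nextId = as.integer(n + 1L))
}
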