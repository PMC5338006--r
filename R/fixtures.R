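#' @include AllClasses.R membrane.R engine.R
NULL

# Programmatic miniature test tissues. Every fixture's ground truth (totals,
# layer boundaries, lattice topology) is fixed by construction, never computed
# by the operations under test.

#' Single vertical column of cells
#'
#' Stacks `n` identical ellipsoid cells on a flat membrane, each overlapping
#' the next vertically (spacing `overlapFraction * 2c`), with prescribed
#' per-cell water/calcium contents and types. The bottom cell rests on the
#' membrane (membrane contact); the top cell is surface-exposed. Used for
#' transport-gradient studies with a dermis below and evaporation above.
#'
#' @param n number of cells (>= 1).
#' @param semiAxes common semi-axes `(a, b, c)` (um).
#' @param water per-cell water contents (recycled to length `n`).
#' @param caMobile per-cell mobile calcium (recycled).
#' @param types per-cell types (recycled; default "SS").
#' @param tj,lipid per-cell barrier levels (recycled).
#' @param overlapFraction vertical overlap as a fraction of cell height.
#' @param domain lateral domain extent (um); defaults to just over one cell.
#' @return `list(tissue, membrane, groundTruth)`; the ground truth records the
#'   prescribed totals and heights.
#' @export
makeColumn <- function(n, semiAxes = c(6.5, 6.5, 3.5), water = 100,
                       caMobile = 0, types = "SS", tj = 0, lipid = 0,
                       overlapFraction = 0.9, domain = NULL) {
  stopifnot(n >= 1L)
  a <- semiAxes[1]; b <- semiAxes[2]; cc <- semiAxes[3]
  L <- if (is.null(domain)) 2.2 * max(a, b) else domain
  mem <- membraneGeometry(mode = "flat", meanHeight = 0, Lx = L, Ly = L)
  spacing <- overlapFraction * 2 * cc
  z <- cc + spacing * (seq_len(n) - 1L)
  cl <- emptyCellTable(n)
  cl$id <- seq_len(n)
  cl$type <- rep_len(types, n)
  cl$x <- L / 2
  cl$y <- L / 2
  cl$z <- z
  cl$a <- a; cl$b <- b; cl$c <- cc
  cl$water <- rep_len(water, n)
  cl$caMobile <- rep_len(caMobile, n)
  cl$tj <- rep_len(tj, n)
  cl$lipid <- rep_len(lipid, n)
  cl$adhesion <- 1
  cl$cycleLen <- 1L
  cl$membraneContact <- seq_len(n) == 1L
  cl$surface <- seq_len(n) == n
  list(
    tissue = new("Tissue", cells = cl, nextId = as.integer(n + 1L)),
    membrane = mem,
    groundTruth = list(
      totalWater = sum(cl$water), totalCaMobile = sum(cl$caMobile),
      heights = z, spacing = spacing
    )
  )
}

#' Laterally periodic slab of stacked cell layers
#'
#' Builds bands of close-packed identical cells on a flat membrane, one band
#' per `(type, thickness, cellHeight)` entry (bottom first). Within a band,
#' cells are laid out on a square lateral grid with rows of cells stacked to
#' fill the band's thickness; exact layer boundaries are recorded as ground
#' truth for thickness and cross-section tests.
#'
#' @param layers list of `list(type =, thickness =, cellSize = c(a, b, c))`.
#' @param Lx,Ly lateral domain (um).
#' @param lateralFill fraction of the lateral cell diameter used as grid
#'   spacing (< 1 packs with overlap).
#' @return `list(tissue, membrane, groundTruth)` with the layer boundaries
#'   (um) and per-layer cell counts.
#' @export
makeSlab <- function(layers, Lx = 60, Ly = 60, lateralFill = 0.95) {
  mem <- membraneGeometry(mode = "flat", meanHeight = 0, Lx = Lx, Ly = Ly)
  rows <- list()
  z0 <- 0
  bounds <- numeric(0)
  countPerLayer <- integer(0)
  nextId <- 1L
  for (ly in layers) {
    stopifnot(ly$thickness > 0)
    a <- ly$cellSize[1]; b <- ly$cellSize[2]; cc <- ly$cellSize[3]
    nz <- max(1L, as.integer(round(ly$thickness / (2 * cc))))
    dz <- ly$thickness / nz
    nx <- max(1L, as.integer(ceiling(Lx / (2 * a * lateralFill))))
    ny <- max(1L, as.integer(ceiling(Ly / (2 * b * lateralFill))))
    g <- expand.grid(
      x = (seq_len(nx) - 0.5) * Lx / nx,
      y = (seq_len(ny) - 0.5) * Ly / ny,
      k = seq_len(nz)
    )
    nCells <- nrow(g)
    cl <- emptyCellTable(nCells)
    cl$id <- nextId + seq_len(nCells) - 1L
    nextId <- nextId + nCells
    cl$type <- ly$type
    cl$x <- g$x
    cl$y <- g$y
    cl$z <- z0 + (g$k - 0.5) * dz
    cl$a <- a; cl$b <- b; cl$c <- cc
    cl$water <- 100
    cl$adhesion <- 1
    cl$cycleLen <- 1L
    cl$membraneContact <- z0 == 0 & g$k == 1L
    rows[[length(rows) + 1L]] <- cl
    bounds <- c(bounds, z0 + ly$thickness)
    countPerLayer <- c(countPerLayer, nCells)
    z0 <- z0 + ly$thickness
  }
  cells <- do.call(rbind, rows)
  list(
    tissue = new("Tissue", cells = cells, nextId = nextId),
    membrane = mem,
    groundTruth = list(
      layerBoundaries = bounds,
      types = vapply(layers, `[[`, "", "type"),
      cellsPerLayer = countPerLayer
    )
  )
}

#' Planar lattice point sets with known topology
#'
#' Generates a hexagonal (triangular) lattice, optionally jittered, for
#' Delaunay-topology tests: interior points of the unperturbed lattice have
#' exactly 6 Delaunay neighbours. Generation is deterministic given `seed`.
#'
#' @param kind `"hexagonal"` or `"perturbed"`.
#' @param nx,ny lattice extent (points per row / number of rows).
#' @param spacing lattice constant.
#' @param jitter jitter amplitude as a fraction of the spacing (perturbed
#'   kind; 0 reproduces the plain lattice).
#' @param seed RNG seed for the jitter.
#' @return Matrix of points with attribute `interior`: indices of points at
#'   least one lattice ring away from the hull.
#' @export
makeLatticePoints <- function(kind = c("hexagonal", "perturbed"), nx = 10L,
                              ny = 10L, spacing = 1, jitter = 0.15,
                              seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(nx * ny >= 3L)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  x <- (g$i - 1) * spacing + (g$j %% 2L) * spacing / 2
  y <- (g$j - 1) * spacing * sqrt(3) / 2
  pts <- cbind(x = x, y = y)
  if (kind == "perturbed" && jitter > 0) {
    set.seed(seed)
    pts <- pts + matrix(runif(2L * nrow(pts), -jitter, jitter) * spacing,
      ncol = 2L
    )
  }
  interior <- which(g$i > 1L & g$i < nx & g$j > 1L & g$j < ny)
  attr(pts, "interior") <- interior
  pts
}
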