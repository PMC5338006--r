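#' @include AllClasses.R membrane.R delaunay.R engine.R
NULL

# Thickness along vertical lines at precomputed sample points.
# For each point: cells whose ellipsoid intersects the vertical line
# contribute the interval [z - c*s, z + c*s], s = sqrt(1 - lateral term).
# VE = membrane to the basal surface of the lowest corneocyte on the line;
# SC = from there to the topmost corneocyte surface. Without corneocytes the
# viable thickness is measured to the topmost viable surface (scPresent
# FALSE); an empty line gives (0, 0) flagged empty.
thicknessAtPoints <- function(cl, membrane, pts) {
  out <- pts[, c("subvolume", "mode")]
  out$ve <- 0
  out$sc <- 0
  out$scPresent <- FALSE
  out$empty <- TRUE
  if (!nrow(cl)) return(out)
  for (r in seq_len(nrow(pts))) {
    dx <- wrapDelta(cl$x - pts$x[r], membrane@Lx)
    dy <- wrapDelta(cl$y - pts$y[r], membrane@Ly)
    t2 <- (dx / cl$a)^2 + (dy / cl$b)^2
    on <- t2 < 1
    if (!any(on)) next
    s <- sqrt(1 - t2[on])
    zlo <- cl$z[on] - cl$c[on] * s
    zhi <- cl$z[on] + cl$c[on] * s
    isSC <- cl$type[on] == "SC"
    h <- pts$h[r]
    out$empty[r] <- FALSE
    if (any(isSC)) {
      veTop <- min(zlo[isSC])
      out$scPresent[r] <- TRUE
      out$ve[r] <- max(0, veTop - h)
      out$sc[r] <- max(0, max(zhi[isSC]) - veTop)
    } else {
      out$ve[r] <- max(0, max(zhi) - h)
    }
  }
  out
}

#' Measure viable-epidermis and stratum-corneum thickness
#'
#' Partitions the lateral domain into subvolumes (default 6), casts a vertical
#' line at the deepest (rete-ridge trough) or shallowest (crest) membrane
#' point of each subvolume, and measures the viable-epidermis thickness (from
#' the membrane to the basal surface of the lowest corneocyte on the line) and
#' the stratum-corneum thickness (from there to the topmost corneocyte
#' surface).
#'
#' @param tissue a [Tissue-class].
#' @param membrane a [MembraneGeometry-class].
#' @param nSubvolumes number of lateral subvolumes (default 6).
#' @param mode `"deepest"`, `"shallowest"` or `"both"`.
#' @return `data.frame(subvolume, mode, ve, sc, scPresent, empty)` (um).
#' @export
measureThickness <- function(tissue, membrane, nSubvolumes = 6L,
                             mode = c("both", "deepest", "shallowest")) {
  mode <- match.arg(mode)
  pts <- subvolumeSamplePoints(membrane, nSubvolumes)
  if (mode != "both") pts <- pts[pts$mode == mode, , drop = FALSE]
  thicknessAtPoints(tissue@cells, membrane, pts)
}

#' Depth-binned water or calcium profile
#'
#' Depth is measured downward from the local tissue surface (the topmost cell
#' surface over each cell's lateral position; 0 um is the surface). Cells are
#' assigned to bins by centre depth; empty bins are flagged.
#'
#' @param tissue a [Tissue-class].
#' @param membrane a [MembraneGeometry-class].
#' @param quantity `"water"` or `"caMobile"`.
#' @param binHeight bin height (um), > 0.
#' @param types optional cell-type filter.
#' @return `data.frame(depthLo, depthMid, mean, sd, n)`; rows with `n = 0`
#'   only appear between occupied bins.
#' @export
depthProfile <- function(tissue, membrane, quantity = c("water", "caMobile"),
                         binHeight = 5, types = NULL) {
  quantity <- match.arg(quantity)
  stopifnot(binHeight > 0)
  cl <- tissue@cells
  if (!is.null(types)) {
    keepType <- cl$type %in% types
  } else {
    keepType <- rep(TRUE, nrow(cl))
  }
  depth <- cellDepths(cl, membrane)
  v <- cl[[quantity]]
  depth <- depth[keepType]
  v <- v[keepType]
  if (!length(v)) {
    return(data.frame(
      depthLo = numeric(0), depthMid = numeric(0), mean = numeric(0),
      sd = numeric(0), n = integer(0)
    ))
  }
  bin <- floor(depth / binHeight)
  bins <- seq(0L, max(bin))
  agg <- lapply(bins, function(b) {
    vb <- v[bin == b]
    data.frame(
      depthLo = b * binHeight, depthMid = (b + 0.5) * binHeight,
      mean = if (length(vb)) mean(vb) else NA_real_,
      sd = if (length(vb) > 1L) stats::sd(vb) else if (length(vb)) 0 else NA_real_,
      n = length(vb)
    )
  })
  do.call(rbind, agg)
}

#' Calcium histogram over time for one layer
#'
#' Builds the 2D histogram (recorded step x calcium bin) of the mobile-calcium
#' distribution over the cells of one layer, from the per-cell records of a
#' run. Each row is the distribution at a single recorded timepoint; row sums
#' equal the layer's cell count at that step.
#'
#' @param metrics a [TrajectoryMetrics-class] with per-cell records.
#' @param layer cell type ("SS", "SG" or "SC").
#' @param breaks calcium bin edges (cells outside the range are clamped into
#'   the end bins).
#' @return Integer matrix with recorded steps as rownames and bin mid-points
#'   as colnames.
#' @export
calciumHistogramOverTime <- function(metrics, layer = c("SS", "SG", "SC"),
                                     breaks = seq(0, 2, by = 0.1)) {
  layer <- match.arg(layer)
  rec <- metrics@cellRecords
  rec <- rec[rec$type == layer, , drop = FALSE]
  stepsU <- sort(unique(metrics@cellRecords$step))
  nb <- length(breaks) - 1L
  out <- matrix(0L, length(stepsU), nb, dimnames = list(
    stepsU, sprintf("%.3g", (head(breaks, -1L) + tail(breaks, -1L)) / 2)
  ))
  if (!nrow(rec)) return(out)
  ca <- pmin(pmax(rec$caMobile, breaks[1L]), breaks[length(breaks)])
  bin <- pmin(pmax(findInterval(ca, breaks, rightmost.closed = TRUE), 1L), nb)
  tb <- table(factor(rec$step, levels = stepsU), factor(bin, levels = seq_len(nb)))
  out[] <- as.integer(tb)
  out
}

#' Extract a planar cross section
#'
#' Returns the lateral centres of the cells whose ellipsoid body intersects
#' the horizontal plane at the given height (for axis-aligned bodies:
#' `|z - height| < c`) and whose type matches the filter. The entire
#' rectangular section is the region of interest.
#'
#' @param tissue a [Tissue-class].
#' @param height section height (um).
#' @param types optional cell-type filter (e.g. "SS" or "SG").
#' @return `data.frame(id, x, y, type)`.
#' @export
extractCrossSection <- function(tissue, height, types = NULL) {
  cl <- tissue@cells
  on <- abs(cl$z - height) < cl$c
  if (!is.null(types)) on <- on & cl$type %in% types
  data.frame(id = cl$id[on], x = cl$x[on], y = cl$y[on], type = cl$type[on])
}

#' Delaunay neighbour-count distribution of a planar point set
#'
#' Triangulates the 2D points (Delaunay; the dual of the Voronoi diagram used
#' to describe the spatial organization of cells in a cross section) and
#' returns each point's number of Delaunay neighbours together with the
#' empirical probability distribution of neighbour counts.
#'
#' @param points matrix or data frame with two columns (lateral coordinates).
#' @param excludeBoundary if `TRUE`, points on the convex hull are excluded
#'   from the distribution (their degree is reported as `NA`).
#' @param layer,plane informational labels stored in the result.
#' @return A [NeighbourTopology-class].
#' @export
delaunayNeighbourDistribution <- function(points, excludeBoundary = FALSE,
                                          layer = "", plane = NA_real_) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3L) stop("need at least 3 points")
  spread <- apply(pts, 2L, function(v) diff(range(v)))
  if (any(!is.finite(spread)) || all(spread < 1e-9)) stop("degenerate point set")
  # Collinear sets have no 2D triangulation.
  cent <- sweep(pts, 2L, colMeans(pts))
  if (min(svd(cent)$d) < 1e-9 * max(spread)) stop("points are collinear")
  deg <- delaunayDegrees(pts)
  counts <- as.integer(deg)
  use <- rep(TRUE, nrow(pts))
  if (excludeBoundary) {
    hull <- grDevices::chull(pts)
    use[hull] <- FALSE
    counts[hull] <- NA_integer_
  }
  tb <- table(counts[use])
  distribution <- stats::setNames(as.numeric(tb) / sum(tb), names(tb))
  new("NeighbourTopology",
    points = pts, counts = counts, distribution = distribution,
    layer = layer, plane = as.numeric(plane)
  )
}

#' Detect the onset of homeostasis in a thickness series
#'
#' Homeostasis is defined operationally as thickness stability: the earliest
#' step `s` such that over the window `[s, s + window - 1]` every value stays
#' within `tolerance` (relative, by default) of the window mean. Returns `NA`
#' if the series never stabilizes.
#'
#' @param series numeric thickness series (one value per step).
#' @param window window length in samples (>= 2).
#' @param tolerance allowed deviation from the window mean; relative if
#'   `relative = TRUE`.
#' @param relative interpret `tolerance` as a fraction of the window mean.
#' @return The 1-based index of the earliest homeostatic step, or `NA`.
#' @export
detectHomeostasis <- function(series, window = 150L, tolerance = 0.05,
                              relative = TRUE) {
  n <- length(series)
  if (window < 2L) stop("window must span at least 2 samples")
  if (n < window) stop("series shorter than the window")
  for (s in seq_len(n - window + 1L)) {
    w <- series[s:(s + window - 1L)]
    m <- mean(w)
    tol <- if (relative) tolerance * abs(m) else tolerance
    if (all(abs(w - m) <= tol)) return(s)
  }
  NA_integer_
}

#' Mean total-thickness series of a run
#'
#' Averages VE + SC thickness over the subvolume sample points of one mode at
#' every recorded step, as input for [detectHomeostasis()].
#'
#' @param metrics a [TrajectoryMetrics-class].
#' @param mode `"deepest"` or `"shallowest"`.
#' @param component `"total"`, `"ve"` or `"sc"`.
#' @return Numeric series, one value per recorded step.
#' @export
thicknessSeries <- function(metrics, mode = c("deepest", "shallowest"),
                            component = c("total", "ve", "sc")) {
  mode <- match.arg(mode)
  component <- match.arg(component)
  th <- metrics@thickness
  th <- th[th$mode == mode, , drop = FALSE]
  v <- switch(component, total = th$ve + th$sc, ve = th$ve, sc = th$sc)
  as.numeric(tapply(v, th$step, mean))
}
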