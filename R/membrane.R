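#' @include AllClasses.R
NULL

#' Create a basement-membrane geometry
#'
#' @param mode `"undulated"` (rete ridges, product-of-cosines height field) or
#'   `"flat"`.
#' @param meanHeight mean membrane height (um).
#' @param amplitude undulation amplitude (um).
#' @param period lateral period (um), identical in both lateral directions.
#' @param Lx,Ly lateral domain extents (um); the lateral boundaries are
#'   periodic.
#' @return A [MembraneGeometry-class].
#' @export
membraneGeometry <- function(mode = c("undulated", "flat"), meanHeight = 0,
                             amplitude = 10, period = 60, Lx = 60, Ly = 60) {
  mode <- match.arg(mode)
  new("MembraneGeometry",
    mode = mode, meanHeight = meanHeight, amplitude = amplitude,
    period = period, Lx = Lx, Ly = Ly
  )
}

#' Membrane height at lateral positions
#'
#' Flat mode returns the mean height everywhere. Undulated mode uses the
#' product-of-cosines surface
#' \eqn{h(x, y) = h_0 + A \cos(2\pi x / P)\cos(2\pi y / P)},
#' periodic with period \eqn{P} in both lateral directions; crests reach
#' \eqn{h_0 + A} and troughs (the deepest points of the rete ridges)
#' \eqn{h_0 - A}.
#'
#' @param x,y lateral coordinates (um), vectorized; wrapped periodically.
#' @param membrane a [MembraneGeometry-class].
#' @return Heights (um).
#' @export
membraneHeight <- function(x, y, membrane) {
  if (membrane@mode == "flat") {
    return(rep(membrane@meanHeight, length.out = max(length(x), length(y))))
  }
  w <- 2 * pi / membrane@period
  membrane@meanHeight + membrane@amplitude * cos(w * x) * cos(w * y)
}

# Deepest (trough) or shallowest (crest) membrane point within a lateral
# rectangle, by dense grid search (robust for any periodic height field).
membraneExtremum <- function(membrane, xlim, ylim, mode = c("deepest", "shallowest"),
                             nGrid = 41L) {
  mode <- match.arg(mode)
  xs <- seq(xlim[1], xlim[2], length.out = nGrid)
  ys <- seq(ylim[1], ylim[2], length.out = nGrid)
  g <- expand.grid(x = xs, y = ys)
  h <- membraneHeight(g$x, g$y, membrane)
  if (max(h) - min(h) < 1e-9) {
    # Constant height over the subvolume (flat membrane): sample its centre.
    ctr <- c(mean(xlim), mean(ylim))
    return(c(x = ctr[1], y = ctr[2], h = h[1]))
  }
  k <- if (mode == "deepest") which.min(h) else which.max(h)
  c(x = g$x[k], y = g$y[k], h = h[k])
}

# Minimum-image lateral displacement on the periodic domain.
wrapDelta <- function(delta, L) {
  delta - L * round(delta / L)
}

# Wrap absolute coordinates into [0, L).
wrapCoord <- function(x, L) {
  x - L * floor(x / L)
}
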