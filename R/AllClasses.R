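#' @include EpidermaSim-package.R
NULL

# Columns of the per-cell state table, in canonical order. Positions and
# semi-axes are in micrometres; water is in arbitrary units on [0, 100];
# calcium in arbitrary units (the dermis content defines the scale);
# tj/lipid are barrier-component levels on [0, 1]; adhesion is the corneocyte
# adhesion maturity (dimensionless, >= 0); ages/clocks are in simulation steps.
CELL_COLUMNS <- c(
  "id", "type", "x", "y", "z", "a", "b", "c",
  "water", "caMobile", "caBound", "tj", "lipid", "adhesion",
  "age", "ageInType", "taLeft", "cycleLen",
  "premature", "desiccated", "membraneContact", "surface", "lowWaterClock"
)

#' Construct an empty cell-state table
#'
#' @param n number of rows.
#' @return A `data.frame` with the canonical cell-state columns.
#' @keywords internal
emptyCellTable <- function(n = 0L) {
  data.frame(
    id = integer(n), type = character(n),
    x = numeric(n), y = numeric(n), z = numeric(n),
    a = numeric(n), b = numeric(n), c = numeric(n),
    water = numeric(n), caMobile = numeric(n), caBound = numeric(n),
    tj = numeric(n), lipid = numeric(n), adhesion = numeric(n),
    age = integer(n), ageInType = integer(n),
    taLeft = integer(n), cycleLen = integer(n),
    premature = logical(n), desiccated = logical(n),
    membraneContact = logical(n), surface = logical(n),
    lowWaterClock = integer(n),
    stringsAsFactors = FALSE
  )
}

#' Basement-membrane geometry
#'
#' A fixed, rigid substrate. In `"undulated"` mode the height function is a
#' product of cosines with the given amplitude and lateral period (the rete
#' ridges); in `"flat"` mode it is constant. The lateral domain is
#' `[0, Lx) x [0, Ly)` with periodic boundaries; the vertical axis points
#' apically (towards the skin surface) and the mean membrane height defines
#' z = `meanHeight`.
#'
#' @slot mode `"undulated"` or `"flat"`.
#' @slot meanHeight mean membrane height (um).
#' @slot amplitude undulation amplitude (um); ignored in flat mode.
#' @slot period lateral period of the undulation in both directions (um).
#' @slot Lx,Ly lateral domain extents (um).
#' @export
setClass("MembraneGeometry",
  representation(
    mode = "character", meanHeight = "numeric", amplitude = "numeric",
    period = "numeric", Lx = "numeric", Ly = "numeric"
  ),
  prototype(
    mode = "undulated", meanHeight = 0, amplitude = 10, period = 60,
    Lx = 60, Ly = 60
  )
)

setValidity("MembraneGeometry", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("undulated", "flat")) {
    msg <- c(msg, "mode must be 'undulated' or 'flat'")
  }
  if (object@Lx <= 0 || object@Ly <= 0) msg <- c(msg, "domain extents must be positive")
  if (object@mode == "undulated") {
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be non-negative")
    if (object@period <= 0) msg <- c(msg, "period must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' A multicellular tissue state
#'
#' Holds the full per-cell state as a data frame (one row per cell) plus the
#' next free cell identifier. All mechanics, behaviour and transport operate on
#' this table with vectorized column operations.
#'
#' @slot cells `data.frame` with the columns of [emptyCellTable()].
#' @slot nextId next unused integer cell id.
#' @export
setClass("Tissue",
  representation(cells = "data.frame", nextId = "integer"),
  prototype(cells = emptyCellTable(0L), nextId = 1L)
)

setValidity("Tissue", function(object) {
  msg <- character(0)
  if (!identical(names(object@cells), CELL_COLUMNS)) {
    msg <- c(msg, "cells must have the canonical cell-state columns")
  } else {
    cl <- object@cells
    if (nrow(cl)) {
      if (anyDuplicated(cl$id)) msg <- c(msg, "cell ids must be unique")
      if (!all(cl$type %in% CELL_TYPES)) msg <- c(msg, "unknown cell type")
      if (any(cl$a <= 0 | cl$b <= 0 | cl$c <= 0)) msg <- c(msg, "semi-axes must be strictly positive")
      if (any(cl$water < -1e-9 | cl$water > 100 + 1e-9)) msg <- c(msg, "water must lie in [0, 100]")
      if (any(cl$caMobile < -1e-9) || any(cl$caBound < -1e-9)) msg <- c(msg, "calcium must be non-negative")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cell-cell contact graph
#'
#' Symmetric adjacency of cells in physical contact (overlap depth along the
#' centre line > 0), annotated with the contact axis, overlap depth and both
#' contact-area approximations, plus the per-cell surface-exposure flag and
#' exposed-area estimate used by evaporation and desquamation.
#'
#' @slot ids integer cell ids, parallel to the tissue rows the graph was built
#'   from.
#' @slot edges `data.frame` with columns `i`, `j` (row indices into `ids`),
#'   `idA`, `idB`, `ux`, `uy`, `uz` (unit contact axis from A to B, minimum
#'   image), `d` (centre distance, um), `rA`, `rB` (radial extents along the
#'   axis, um), `depth` (overlap depth, um), `areaFast`, `areaAccurate` (um^2).
#' @slot exposed per-cell logical: surface-exposed.
#' @slot exposedArea per-cell exposed-area estimate (um^2, 0 if not exposed).
#' @export
setClass("ContactGraph",
  representation(
    ids = "integer", edges = "data.frame",
    exposed = "logical", exposedArea = "numeric"
  )
)

#' Simulation configuration
#'
#' All global parameters of a run: schedule, membrane, force, behaviour and
#' transport parameter groups, seeding and output cadence. Create with
#' [simulationConfig()] or [defaultConfig()]; read from YAML with
#' [readSimulationConfig()].
#'
#' @slot steps total simulation steps to run.
#' @slot dtMinutes simulated minutes per step (bookkeeping only; 30 by default).
#' @slot seed RNG seed fixed before any stochastic call.
#' @slot humidity `data.frame(fromStep, H)`: piecewise-constant ambient
#'   humidity schedule, `H` on [0, 100] (arbitrary scale).
#' @slot membrane a [MembraneGeometry-class].
#' @slot forces named list of force parameters (see [defaultForceParameters()]).
#' @slot behaviour named list of behaviour parameters
#'   (see [defaultBehaviourParameters()]).
#' @slot transport named list of transport parameters
#'   (see [defaultTransportParameters()]).
#' @slot nStem number of stem cells seeded initially.
#' @slot outputEvery cadence (steps) of depth-profile/cell records.
#' @slot mechSubsteps mechanics relaxation sub-iterations per behavioural step.
#' @slot scAdhesionArea `"fast"` (default; lateral overestimate drives
#'   corneocyte interdigitation) or `"accurate"` (column-stacking control).
#' @slot profile free-text profile label (`"reduced"` or `"paper"`).
#' @export
setClass("SimulationConfig",
  representation(
    steps = "integer", dtMinutes = "numeric", seed = "integer",
    humidity = "data.frame", membrane = "MembraneGeometry",
    forces = "list", behaviour = "list", transport = "list",
    nStem = "integer", outputEvery = "integer",
    mechSubsteps = "integer", scAdhesionArea = "character",
    profile = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@steps < 0L) msg <- c(msg, "steps must be >= 0")
  if (!all(c("fromStep", "H") %in% names(object@humidity))) {
    msg <- c(msg, "humidity schedule needs columns fromStep, H")
  } else if (any(object@humidity$H < 0 | object@humidity$H > 100)) {
    msg <- c(msg, "humidity must lie in [0, 100]")
  }
  if (object@nStem < 1L) msg <- c(msg, "nStem must be >= 1")
  if (!object@scAdhesionArea %in% c("fast", "accurate")) {
    msg <- c(msg, "scAdhesionArea must be 'fast' or 'accurate'")
  }
  if (object@mechSubsteps < 1L) msg <- c(msg, "mechSubsteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Simulation snapshot
#'
#' Complete serializable state of a run: tissue, step index, RNG state and the
#' configuration. `loadSnapshot(saveSnapshot(x))` reproduces the state exactly,
#' and resuming a run from a snapshot is step-for-step identical to the
#' uninterrupted run.
#'
#' @slot version snapshot format version.
#' @slot step step index at which the snapshot was taken.
#' @slot tissue a [Tissue-class].
#' @slot rngState the `.Random.seed` vector at snapshot time.
#' @slot config the [SimulationConfig-class] of the run.
#' @export
setClass("Snapshot",
  representation(
    version = "integer", step = "integer", tissue = "Tissue",
    rngState = "integer", config = "SimulationConfig"
  )
)

#' Per-step trajectory metrics
#'
#' @slot steps recorded step indices (every step).
#' @slot counts matrix (step x cell type) of cell counts.
#' @slot thickness `data.frame(step, subvolume, mode, ve, sc, scPresent,
#'   empty)`: viable-epidermis and stratum-corneum thickness (um) at the
#'   deepest (trough) and shallowest (crest) membrane sample point of each
#'   subvolume.
#' @slot events `data.frame(step, event, count)` of divisions, transitions,
#'   desquamations, desiccations.
#' @slot ledger per-step boundary-flux ledger: dermis inflows, TEWL outflow,
#'   calcium deposition, corneocyte binding, desquamation removal, and the
#'   post-step water/calcium totals (for conservation audits).
#' @slot cellRecords `data.frame(step, id, type, depth, water, caMobile)`
#'   recorded at the output cadence (for depth profiles and calcium
#'   histograms over time).
#' @export
setClass("TrajectoryMetrics",
  representation(
    steps = "integer", counts = "matrix", thickness = "data.frame",
    events = "data.frame", ledger = "data.frame", cellRecords = "data.frame"
  )
)

#' Result of a simulation run
#'
#' @slot config the configuration used.
#' @slot metrics a [TrajectoryMetrics-class].
#' @slot tissue the final [Tissue-class].
#' @slot snapshot the final [Snapshot-class].
#' @export
setClass("SimulationResult",
  representation(
    config = "SimulationConfig", metrics = "TrajectoryMetrics",
    tissue = "Tissue", snapshot = "Snapshot"
  )
)

#' Delaunay neighbour topology of a planar cross section
#'
#' @slot points n x 2 matrix of lateral cell-centre coordinates.
#' @slot counts integer Delaunay neighbour count per point (NA for points
#'   excluded as boundary when requested).
#' @slot distribution empirical probability distribution over neighbour
#'   counts (named numeric, sums to 1).
#' @slot layer layer label (e.g. "SS" or "SG"), informational.
#' @slot plane section height (um), informational.
#' @export
setClass("NeighbourTopology",
  representation(
    points = "matrix", counts = "integer", distribution = "numeric",
    layer = "character", plane = "numeric"
  )
)

setMethod("show", "MembraneGeometry", function(object) {
  cat(sprintf(
    "MembraneGeometry: %s, mean %.1f um, amplitude %.1f um, period %.1f um, domain %.0f x %.0f um\n",
    object@mode, object@meanHeight, object@amplitude, object@period, object@Lx, object@Ly
  ))
})

setMethod("show", "Tissue", function(object) {
  n <- nrow(object@cells)
  cat(sprintf("Tissue with %d cells\n", n))
  if (n) {
    tb <- table(factor(object@cells$type, levels = CELL_TYPES))
    cat("  ", paste(sprintf("%s: %d", names(tb), as.integer(tb)), collapse = "  "), "\n")
    cat(sprintf(
      "  z range [%.1f, %.1f] um; total water %.1f, mobile calcium %.2f\n",
      min(object@cells$z), max(object@cells$z),
      sum(object@cells$water), sum(object@cells$caMobile)
    ))
  }
})

setMethod("show", "ContactGraph", function(object) {
  cat(sprintf(
    "ContactGraph: %d cells, %d contacts, %d surface-exposed\n",
    length(object@ids), nrow(object@edges), sum(object@exposed)
  ))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig ('%s'): %d steps (%.0f min/step), seed %d, %d stem cells\n",
    object@profile, object@steps, object@dtMinutes, object@seed, object@nStem
  ))
  cat(sprintf(
    "  humidity: %s; SC adhesion area: %s\n",
    paste(sprintf("H=%g from step %d", object@humidity$H, object@humidity$fromStep),
      collapse = ", "
    ),
    object@scAdhesionArea
  ))
  show(object@membrane)
})

setMethod("show", "Snapshot", function(object) {
  cat(sprintf("Snapshot (v%d) at step %d\n", object@version, object@step))
  show(object@tissue)
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult after %d steps\n", object@snapshot@step))
  show(object@tissue)
})

setMethod("show", "NeighbourTopology", function(object) {
  cat(sprintf(
    "NeighbourTopology (%s, plane %.1f um): %d points, mode %s neighbours\n",
    object@layer, object@plane, nrow(object@points),
    names(object@distribution)[which.max(object@distribution)]
  ))
})
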