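#' @include config.R behaviour.R transport.R
NULL

SNAPSHOT_VERSION <- 1L

#' Seed the initial tissue
#'
#' Places `nStem` stem cells resting on the basement membrane. On an undulated
#' membrane the seeds are distributed equally among the rete-ridge troughs
#' (the minima of the height field), equidistantly on a small ring around each
#' minimum, so every seeded centre lies below the mean membrane height. On a
#' flat membrane seeds form a regular lateral grid. Cell-cycle lengths are
#' drawn from the current RNG stream ([runSimulation()] seeds the stream from
#' the configuration first).
#'
#' @param config a [SimulationConfig-class].
#' @return A [Tissue-class] of stem cells in membrane contact.
#' @export
seedInitialTissue <- function(config) {
  mem <- config@membrane
  n <- config@nStem
  if (mem@mode == "flat") {
    nx <- as.integer(ceiling(sqrt(n)))
    ny <- as.integer(ceiling(n / nx))
    gx <- (seq_len(nx) - 0.5) * mem@Lx / nx
    gy <- (seq_len(ny) - 0.5) * mem@Ly / ny
    g <- expand.grid(x = gx, y = gy)[seq_len(n), ]
    px <- g$x
    py <- g$y
  } else {
    P <- mem@period
    ix <- P * (0:floor((mem@Lx - 1e-9) / P))
    iy <- P * (0:floor((mem@Ly - 1e-9) / P))
    # Minima of the product-of-cosines field sit at half-period offsets in
    # exactly one lateral direction.
    t1 <- expand.grid(x = ix + P / 2, y = iy)
    t2 <- expand.grid(x = ix, y = iy + P / 2)
    troughX <- c(t1$x, t2$x)
    troughY <- c(t1$y, t2$y)
    nT <- length(troughX)
    ringR <- min(6, P / 8)
    maxSeats <- nT * max(1L, as.integer(floor(2 * pi * ringR / 3)))
    if (n > maxSeats) stop("nStem exceeds the packable trough positions")
    perT <- as.integer(ceiling(n / nT))
    px <- numeric(0)
    py <- numeric(0)
    for (t in seq_len(nT)) {
      kT <- min(perT, n - length(px))
      if (kT <= 0L) break
      angles <- 2 * pi * (seq_len(kT) - 1) / max(kT, 1L) + (t - 1) * pi / 4
      px <- c(px, troughX[t] + ringR * cos(angles))
      py <- c(py, troughY[t] + ringR * sin(angles))
    }
  }
  px <- wrapCoord(px, mem@Lx)
  py <- wrapCoord(py, mem@Ly)
  semi <- config@behaviour$shapeTargets$STEM
  cl <- emptyCellTable(n)
  cl$id <- seq_len(n)
  cl$type <- "STEM"
  cl$x <- px
  cl$y <- py
  cl$z <- membraneHeight(px, py, mem) + semi[3]
  cl$a <- semi[1]
  cl$b <- semi[2]
  cl$c <- semi[3]
  cl$water <- 100
  cl$caMobile <- config@transport$dermisCalcium
  cl$adhesion <- 1
  cl$cycleLen <- drawCycle(n, config@behaviour$stemCycle)
  cl$membraneContact <- TRUE
  cl$surface <- TRUE
  new("Tissue", cells = cl, nextId = n + 1L)
}

# Precompute the deepest/shallowest membrane sample point of each subvolume
# (3 x 2 lateral grid for the default 6 subvolumes).
subvolumeSamplePoints <- function(membrane, nSubvolumes = 6L) {
  nx <- if (nSubvolumes %in% c(6L, 3L)) 3L else as.integer(ceiling(sqrt(nSubvolumes)))
  ny <- as.integer(ceiling(nSubvolumes / nx))
  out <- list()
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      k <- k + 1L
      if (k > nSubvolumes) break
      xlim <- c(ix - 1, ix) * membrane@Lx / nx
      ylim <- c(iy - 1, iy) * membrane@Ly / ny
      for (mode in c("deepest", "shallowest")) {
        p <- membraneExtremum(membrane, xlim, ylim, mode)
        out[[length(out) + 1L]] <- data.frame(
          subvolume = k, mode = mode, x = p[["x"]], y = p[["y"]], h = p[["h"]]
        )
      }
    }
  }
  do.call(rbind, out)
}

# Depth of every cell below the local tissue surface (the topmost cell surface
# over each cell's lateral position).
cellDepths <- function(cl, membrane) {
  n <- nrow(cl)
  if (!n) return(numeric(0))
  dxm <- wrapDelta(outer(cl$x, cl$x, "-"), membrane@Lx)
  dym <- wrapDelta(outer(cl$y, cl$y, "-"), membrane@Ly)
  lat <- sqrt(dxm^2 + dym^2)
  covers <- sweep(lat, 2L, pmax(cl$a, cl$b), "<=") # [i, j]: j's footprint over i
  top <- matrix(rep(cl$z + cl$c, each = n), n, n)
  top[!covers] <- -Inf
  surf <- apply(top, 1L, max)
  pmax(0, surf - cl$z)
}

#' Run a simulation
#'
#' Executes the configured number of steps from an initial tissue or a
#' snapshot, in a fixed documented order per step: (1) cell behaviour (ageing,
#' divisions, differentiation, shape relaxation, barrier production,
#' corneocyte adhesion maturation), (2) contact-graph rebuild, (3) overdamped
#' mechanical relaxation, (4) transport (water diffusion, calcium
#' diffusion/advection, dermal and evaporative boundary exchange, corneocyte
#' calcium binding), (5) desquamation, (6) metrics. The run is deterministic
#' given (config, seed): a single RNG stream is seeded once at the start, and
#' its state is stored in the final snapshot so resumed runs are step-for-step
#' identical to uninterrupted ones.
#'
#' @param config a [SimulationConfig-class].
#' @param init `NULL` (seed a fresh tissue), a [Tissue-class] (start at step
#'   0 with the configured seed), or a [Snapshot-class] (resume; restores the
#'   RNG state and continues until `config@steps`).
#' @return A [SimulationResult-class].
#' @export
runSimulation <- function(config, init = NULL) {
  validObject(config)
  mem <- config@membrane
  if (is(init, "Snapshot")) {
    tissue <- init@tissue
    startStep <- init@step
    assign(".Random.seed", init@rngState, envir = globalenv())
  } else {
    set.seed(config@seed)
    tissue <- if (is(init, "Tissue")) init else seedInitialTissue(config)
    startStep <- 0L
  }
  pts <- subvolumeSamplePoints(mem)
  nSteps <- config@steps - startStep
  stepsV <- integer(max(nSteps, 0L))
  counts <- matrix(0L, max(nSteps, 0L), length(CELL_TYPES),
    dimnames = list(NULL, CELL_TYPES)
  )
  thickList <- vector("list", max(nSteps, 0L))
  eventList <- vector("list", max(nSteps, 0L))
  ledgerList <- vector("list", max(nSteps, 0L))
  recordList <- list()

  if (nSteps > 0L) {
    for (k in seq_len(nSteps)) {
      s <- startStep + k
      H <- humidityAt(config, s - 1L)

      # (1) behaviour
      cl <- tissue@cells
      cl$age <- cl$age + 1L
      cl$ageInType <- cl$ageInType + 1L
      tissue@cells <- cl
      div <- attemptDivisions(tissue, config@behaviour)
      tissue <- div$tissue
      dif <- updateDifferentiation(tissue, config@behaviour)
      tissue <- dif$tissue
      tissue <- updateShape(tissue, config@behaviour)
      tissue <- updateBarrierComponents(tissue, config@behaviour)
      tissue <- updateCorneocyteAdhesion(tissue, config@behaviour)

      # (2) contact graph, (3) mechanics
      graph <- buildContactGraph(tissue, mem)
      for (m in seq_len(config@mechSubsteps)) {
        tissue <- integrateStep(
          tissue, graph, config@forces, mem, config@scAdhesionArea
        )
      }
      tissue@cells$surface <- graph@exposed

      # (4) transport
      ws <- waterStep(tissue, graph, config@transport)
      tissue <- ws$tissue
      cs <- calciumStep(tissue, graph, ws$fluxes, config@transport)
      tissue <- cs$tissue
      be <- boundaryExchange(tissue, graph, mem, config@transport, H)
      tissue <- be$tissue
      bc <- bindCalcium(tissue, config@transport)
      tissue <- bc$tissue

      # (5) desquamation
      rm <- checkDesquamation(tissue, graph, config@forces, config@behaviour)
      desqWater <- sum(tissue@cells$water[rm])
      desqCaM <- sum(tissue@cells$caMobile[rm])
      desqCaB <- sum(tissue@cells$caBound[rm])
      nDesq <- sum(rm)
      if (nDesq) tissue@cells <- tissue@cells[!rm, , drop = FALSE]

      # (6) metrics
      cl <- tissue@cells
      stepsV[k] <- s
      counts[k, ] <- tabulate(factor(cl$type, levels = CELL_TYPES),
        nbins = length(CELL_TYPES)
      )
      th <- thicknessAtPoints(cl, mem, pts)
      th$step <- s
      thickList[[k]] <- th
      eventList[[k]] <- data.frame(
        step = s,
        event = c(
          "division", "taExhausted", names(dif$transitions), "desquamation"
        ),
        count = c(
          div$nDivisions, div$nExhausted, as.integer(dif$transitions), nDesq
        )
      )
      ledgerList[[k]] <- data.frame(
        step = s, H = H,
        dermisWaterIn = be$ledger[["dermisWaterIn"]],
        dermisCalciumIn = be$ledger[["dermisCalciumIn"]],
        tewlOut = be$ledger[["tewlOut"]],
        depositionOut = be$ledger[["depositionOut"]],
        bindingTransfer = bc$bindingTransfer,
        desqWaterOut = desqWater, desqCaMobileOut = desqCaM,
        desqCaBoundOut = desqCaB,
        totalWater = sum(cl$water), totalCaMobile = sum(cl$caMobile),
        totalCaBound = sum(cl$caBound), nCells = nrow(cl)
      )
      if (config@outputEvery > 0L && s %% config@outputEvery == 0L && nrow(cl)) {
        recordList[[length(recordList) + 1L]] <- data.frame(
          step = s, id = cl$id, type = cl$type,
          depth = cellDepths(cl, mem), water = cl$water,
          caMobile = cl$caMobile
        )
      }
      if (any(!is.finite(cl$water)) || any(!is.finite(cl$caMobile))) {
        stop("non-finite transport state at step ", s)
      }
    }
  }

  metrics <- new("TrajectoryMetrics",
    steps = stepsV,
    counts = counts,
    thickness = if (nSteps > 0L) do.call(rbind, thickList) else data.frame(),
    events = if (nSteps > 0L) do.call(rbind, eventList) else data.frame(),
    ledger = if (nSteps > 0L) do.call(rbind, ledgerList) else data.frame(),
    cellRecords = if (length(recordList)) {
      do.call(rbind, recordList)
    } else {
      data.frame(
        step = integer(0), id = integer(0), type = character(0),
        depth = numeric(0), water = numeric(0), caMobile = numeric(0)
      )
    }
  )
  snap <- new("Snapshot",
    version = SNAPSHOT_VERSION, step = config@steps, tissue = tissue,
    rngState = get(".Random.seed", envir = globalenv()), config = config
  )
  new("SimulationResult",
    config = config, metrics = metrics, tissue = tissue, snapshot = snap
  )
}

#' Save / load a snapshot
#'
#' Snapshots use R's native serialization as their container and restore the
#' complete state: `loadSnapshot(saveSnapshot(x, path))` reproduces the state
#' exactly, and a run continued from a snapshot is step-for-step identical to
#' the uninterrupted run.
#'
#' @param snapshot a [Snapshot-class].
#' @param path file path.
#' @return `saveSnapshot` returns `path` invisibly; `loadSnapshot` the
#'   [Snapshot-class].
#' @export
saveSnapshot <- function(snapshot, path) {
  stopifnot(is(snapshot, "Snapshot"))
  saveRDS(snapshot, path)
  invisible(path)
}

#' @rdname saveSnapshot
#' @export
loadSnapshot <- function(path) {
  snap <- readRDS(path)
  if (!is(snap, "Snapshot")) stop("file does not contain a Snapshot")
  if (snap@version > SNAPSHOT_VERSION) stop("snapshot version not supported")
  snap
}

#' Transport-only equilibration on a fixed geometry
#'
#' Runs only the transport operators (water diffusion, calcium
#' diffusion/advection, boundary exchange, corneocyte binding) on a frozen
#' tissue -- no mechanics, growth or differentiation. Used to study gradient
#' emergence on fixture tissues such as the stacked-cell column.
#'
#' @param tissue a [Tissue-class] (positions and barrier levels stay fixed).
#' @param membrane a [MembraneGeometry-class].
#' @param transport transport parameter list.
#' @param H ambient humidity.
#' @param steps number of transport steps.
#' @return `list(tissue, ledger)` with the per-step boundary-flux ledger.
#' @export
equilibrateTransport <- function(tissue, membrane,
                                 transport = defaultTransportParameters(),
                                 H = 100, steps = 100L) {
  graph <- buildContactGraph(tissue, membrane)
  rows <- vector("list", steps)
  for (s in seq_len(steps)) {
    ws <- waterStep(tissue, graph, transport)
    tissue <- ws$tissue
    cs <- calciumStep(tissue, graph, ws$fluxes, transport)
    tissue <- cs$tissue
    be <- boundaryExchange(tissue, graph, membrane, transport, H)
    tissue <- be$tissue
    bc <- bindCalcium(tissue, transport)
    tissue <- bc$tissue
    rows[[s]] <- data.frame(
      step = s, t(be$ledger), bindingTransfer = bc$bindingTransfer,
      totalWater = sum(tissue@cells$water),
      totalCaMobile = sum(tissue@cells$caMobile)
    )
  }
  list(tissue = tissue, ledger = do.call(rbind, rows))
}
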