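#' @include AllClasses.R
NULL

#' Accessors for simulation objects
#'
#' `cells()` returns the per-cell state table; `nCells()` the number of cells;
#' `contactEdges()` the annotated edge table of a contact graph;
#' `trajectoryMetrics()` the recorded metrics of a run; `neighbourCounts()` and
#' `neighbourDistribution()` the per-cell Delaunay degrees and their empirical
#' distribution.
#'
#' @param x a simulation object.
#' @param value replacement cell table.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname accessors
#' @export
setGeneric("cells<-", function(x, value) standardGeneric("cells<-"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("contactEdges", function(x) standardGeneric("contactEdges"))

#' @rdname accessors
#' @export
setGeneric("trajectoryMetrics", function(x) standardGeneric("trajectoryMetrics"))

#' @rdname accessors
#' @export
setGeneric("neighbourCounts", function(x) standardGeneric("neighbourCounts"))

#' @rdname accessors
#' @export
setGeneric("neighbourDistribution", function(x) standardGeneric("neighbourDistribution"))

#' @rdname accessors
#' @export
setMethod("cells", "Tissue", function(x) x@cells)

#' @rdname accessors
#' @export
setMethod("cells", "SimulationResult", function(x) x@tissue@cells)

#' @rdname accessors
#' @export
setMethod("cells", "Snapshot", function(x) x@tissue@cells)

#' @rdname accessors
#' @export
setReplaceMethod("cells", "Tissue", function(x, value) {
  x@cells <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("nCells", "Tissue", function(x) nrow(x@cells))

#' @rdname accessors
#' @export
setMethod("nCells", "SimulationResult", function(x) nrow(x@tissue@cells))

#' @rdname accessors
#' @export
setMethod("contactEdges", "ContactGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("trajectoryMetrics", "SimulationResult", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("neighbourCounts", "NeighbourTopology", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("neighbourDistribution", "NeighbourTopology", function(x) x@distribution)

#' Construct a tissue from a cell table
#'
#' @param cellTable a `data.frame` with the canonical cell-state columns;
#'   missing columns are filled with defaults.
#' @return A [Tissue-class].
#' @export
newTissue <- function(cellTable = emptyCellTable(0L)) {
  n <- nrow(cellTable)
  full <- emptyCellTable(n)
  if (n) {
    full$water <- rep(100, n)
    full$adhesion <- rep(1, n)
    full$cycleLen <- rep(1L, n)
    for (nm in intersect(names(cellTable), CELL_COLUMNS)) {
      full[[nm]] <- cellTable[[nm]]
    }
    if (!("id" %in% names(cellTable))) full$id <- seq_len(n)
  }
  new("Tissue", cells = full, nextId = if (n) max(full$id) + 1L else 1L)
}
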