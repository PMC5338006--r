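#' @include engine.R
NULL

#' Humidity-switch protocol
#'
#' From a snapshot of a homeostatic run, continues at the snapshot's humidity
#' for `preSteps` (demonstrating that reloading a stored state has no bearing
#' on homeostasis), then switches the global humidity to `HNew` and continues
#' for `postSteps`. The returned result's metrics carry the switch step in
#' `attr(, "switchStep")`.
#'
#' @param snapshot a [Snapshot-class] from a homeostatic run.
#' @param HNew humidity after the switch (e.g. 50 or 0; the snapshot's own
#'   humidity gives the control run).
#' @param preSteps steps at the original humidity before the switch
#'   (500 at full scale).
#' @param postSteps steps after the switch (2500 at full scale).
#' @return A [SimulationResult-class]; `attr(trajectoryMetrics(res),
#'   "switchStep")` holds the absolute step index of the switch.
#' @export
humiditySwitchProtocol <- function(snapshot, HNew, preSteps = 500L,
                                   postSteps = 2500L) {
  stopifnot(is(snapshot, "Snapshot"))
  config <- snapshot@config
  H0 <- humidityAt(config, snapshot@step)
  switchStep <- snapshot@step + as.integer(preSteps)
  config@humidity <- data.frame(
    fromStep = c(0L, switchStep), H = c(H0, HNew)
  )
  config@steps <- snapshot@step + as.integer(preSteps) + as.integer(postSteps)
  res <- runSimulation(config, init = snapshot)
  attr(res@metrics, "switchStep") <- switchStep
  res
}

#' In silico tape stripping
#'
#' Removes the stratum corneum (`"SC_only"`) or both the stratum corneum and
#' the stratum granulosum (`"SC_and_SG"`) from a tissue; all other cells are
#' untouched. The water and calcium carried by the removed cells leave the
#' system; the amounts are attached as `attr(, "removed")` so they can be
#' logged as a boundary outflow. Applying the same mode twice is idempotent.
#'
#' @param tissue a [Tissue-class].
#' @param mode `"SC_only"` or `"SC_and_SG"`.
#' @return The stripped [Tissue-class] with a `removed` attribute
#'   (named numeric: water, caMobile, caBound, nCells).
#' @export
tapeStrip <- function(tissue, mode = c("SC_only", "SC_and_SG")) {
  mode <- match.arg(mode)
  types <- if (mode == "SC_only") "SC" else c("SC", "SG")
  cl <- tissue@cells
  rm <- cl$type %in% types
  removed <- c(
    water = sum(cl$water[rm]), caMobile = sum(cl$caMobile[rm]),
    caBound = sum(cl$caBound[rm]), nCells = sum(rm)
  )
  tissue@cells <- cl[!rm, , drop = FALSE]
  attr(tissue, "removed") <- removed
  tissue
}
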