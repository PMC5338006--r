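# Shared reduced-scale simulation runs, computed once per test session and
# reused across test files (growth runs are the expensive part of the suite).

.runCache <- new.env(parent = emptyenv())

cachedRun <- function(key, maker) {
  if (is.null(.runCache[[key]])) .runCache[[key]] <- maker()
  .runCache[[key]]
}

growthSteps <- function(H) {
  # Lower humidity prolongs the pre-homeostatic phase; give those runs longer.
  if (H >= 100) 1200L else if (H >= 50) 1500L else 1800L
}

growthConfig <- function(H, steps = growthSteps(H), seed = 101L, ...) {
  defaultConfig("reduced", steps = steps, seed = seed, humidity = H, ...)
}

cachedGrowthRun <- function(H, ...) {
  cachedRun(paste0("growth", H), function() runSimulation(growthConfig(H, ...)))
}

# Homeostasis detection tuned to the reduced-scale noise level: total
# thickness at the deepest sample points, 150-step window, 12% band.
timeToHomeostasis <- function(result, window = 150L, tolerance = 0.12) {
  tot <- thicknessSeries(trajectoryMetrics(result), "deepest", "total")
  detectHomeostasis(tot, window = window, tolerance = tolerance)
}
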