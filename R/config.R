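#' @include AllClasses.R forces.R behaviour.R transport.R membrane.R
NULL

#' Create a simulation configuration
#'
#' @param steps total simulation steps.
#' @param dtMinutes simulated minutes per step (default 30).
#' @param seed RNG seed (fixed before any stochastic call of the run).
#' @param humidity either a single value in [0, 100] or a
#'   `data.frame(fromStep, H)` piecewise-constant schedule.
#' @param membrane a [MembraneGeometry-class].
#' @param forces,behaviour,transport parameter lists; entries override the
#'   defaults from [defaultForceParameters()], [defaultBehaviourParameters()]
#'   and [defaultTransportParameters()].
#' @param nStem number of stem cells to seed.
#' @param outputEvery cadence (steps) of per-cell records.
#' @param mechSubsteps mechanics relaxation sub-iterations per step.
#' @param scAdhesionArea `"fast"` (default) or `"accurate"` corneocyte
#'   adhesion-area mode.
#' @param profile profile label.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(steps = 1500L, dtMinutes = 30, seed = 42L,
                             humidity = 100, membrane = membraneGeometry(),
                             forces = list(), behaviour = list(),
                             transport = list(), nStem = 8L,
                             outputEvery = 25L, mechSubsteps = 3L,
                             scAdhesionArea = "fast", profile = "reduced") {
  if (is.numeric(humidity) && length(humidity) == 1L) {
    humidity <- data.frame(fromStep = 0L, H = humidity)
  }
  humidity <- humidity[order(humidity$fromStep), , drop = FALSE]
  rownames(humidity) <- NULL
  new("SimulationConfig",
    steps = as.integer(steps), dtMinutes = dtMinutes, seed = as.integer(seed),
    humidity = humidity, membrane = membrane,
    forces = utils::modifyList(defaultForceParameters(), forces),
    behaviour = utils::modifyList(defaultBehaviourParameters(), behaviour),
    transport = utils::modifyList(defaultTransportParameters(), transport),
    nStem = as.integer(nStem), outputEvery = as.integer(outputEvery),
    mechSubsteps = as.integer(mechSubsteps),
    scAdhesionArea = scAdhesionArea, profile = profile
  )
}

#' Ready-made configuration profiles
#'
#' `"reduced"` (the default, used throughout the tests and examples) simulates
#' one rete-ridge period (60 x 60 um, amplitude 10 um) with 8 stem cells and
#' shortened cell-cycle/maturation times, so a full growth-to-homeostasis run
#' completes in minutes on one CPU. `"paper"` scales the domain, stem-cell
#' count and phase times up to the full-tissue protocol (20,000 steps of 30
#' simulated minutes); such runs take many hours and are opt-in.
#'
#' @param profile `"reduced"` or `"paper"`.
#' @param ... overrides passed on to [simulationConfig()].
#' @return A [SimulationConfig-class].
#' @export
defaultConfig <- function(profile = c("reduced", "paper"), ...) {
  profile <- match.arg(profile)
  if (profile == "reduced") {
    simulationConfig(profile = "reduced", ...)
  } else {
    args <- list(
      steps = 20000L,
      membrane = membraneGeometry(
        mode = "undulated", amplitude = 20, period = 100, Lx = 200, Ly = 200
      ),
      nStem = 32L,
      behaviour = list(
        stemCycle = c(280, 360), taCycle = c(140, 180),
        sgMaturation = 160, adhesionPeak = 260, adhesionDecay = 0.0055,
        lowWaterPersist = 60
      ),
      transport = list(
        Dw = 2.5e-5, Dca = 2e-5, dermisRateCalcium = 0.007,
        tewlCoeff = 0.0035, bindRate = 0.007
      ),
      outputEvery = 100L,
      profile = "paper"
    )
    args <- utils::modifyList(args, list(...))
    do.call(simulationConfig, args)
  }
}

#' Humidity at a given step
#'
#' Evaluates the piecewise-constant humidity schedule.
#'
#' @param config a [SimulationConfig-class].
#' @param step step index (0-based; vectorized).
#' @return Humidity value(s) in [0, 100].
#' @export
humidityAt <- function(config, step) {
  sched <- config@humidity
  idx <- findInterval(step, sched$fromStep)
  idx[idx < 1L] <- 1L
  sched$H[idx]
}

#' Knockout configurations
#'
#' Returns a copy of the configuration with the corresponding barrier
#' component's effect on transport removed; every other field is identical.
#'
#' @param config a [SimulationConfig-class].
#' @param component `"tight_junctions"` or `"lipids"`.
#' @return The modified [SimulationConfig-class].
#' @export
knockoutConfig <- function(config, component = c("tight_junctions", "lipids")) {
  component <- match.arg(component)
  if (component == "tight_junctions") {
    config@transport$tjDisabled <- TRUE
  } else {
    config@transport$lipidDisabled <- TRUE
  }
  config
}

#' Read a simulation configuration from YAML
#'
#' The file may contain top-level scalars (`steps`, `seed`, `nStem`,
#' `outputEvery`, `mechSubsteps`, `scAdhesionArea`, `profile`, `dtMinutes`),
#' a `humidity` entry (scalar, or list of `{fromStep, H}` records), a
#' `membrane` section and `forces` / `behaviour` / `transport` sections whose
#' entries override the package defaults.
#'
#' @param path path to a YAML file.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c(
    "steps", "seed", "nStem", "outputEvery", "mechSubsteps",
    "scAdhesionArea", "profile", "dtMinutes"
  )) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$humidity)) {
    h <- raw$humidity
    args$humidity <- if (is.list(h)) {
      do.call(rbind, lapply(h, function(r) {
        data.frame(fromStep = as.integer(r$fromStep), H = as.numeric(r$H))
      }))
    } else {
      h
    }
  }
  if (!is.null(raw$membrane)) {
    args$membrane <- do.call(membraneGeometry, raw$membrane)
  }
  for (nm in c("forces", "behaviour", "transport")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(simulationConfig, args)
}
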