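#' @include AllClasses.R forces.R
NULL

#' Default behaviour parameters
#'
#' All times are in simulation steps, calcium in the units set by the dermis
#' content, water on the [0, 100] scale.
#'
#' @return Named list:
#' \describe{
#'   \item{stemCycle, taCycle}{uniform ranges (steps) from which cell-cycle
#'     lengths are drawn at each division.}
#'   \item{caThreshold}{mobile-calcium threshold for homeostatic SS -> SG
#'     differentiation.}
#'   \item{lowWaterThreshold}{water level below which a cell counts as
#'     water-starved.}
#'   \item{lowWaterPersist}{consecutive water-starved steps after which an SS
#'     or SG cell desiccates to a dead corneocyte.}
#'   \item{sgMaturation}{SG residence time before homeostatic cornification.}
#'   \item{shapeTargets}{per-type target semi-axes (um); corneocytes flatten to
#'     30 um diameter and 0.9 um height.}
#'   \item{shapeRate}{exponential relaxation rate of semi-axes per step.}
#'   \item{tjRate, lipidRate}{homeostatic barrier-component production rates.}
#'   \item{prematureMult}{production multiplier of the premature (low-calcium)
#'     pathway.}
#'   \item{prematureLipidProduction}{if `TRUE` (default) the premature pathway
#'     in SS/SG produces lipids as well as tight junctions; `FALSE` restricts
#'     premature production to tight junctions.}
#'   \item{lowCaThreshold}{mobile-calcium level below which SS/SG activate the
#'     premature pathway.}
#'   \item{adhesionInit, adhesionPeak, adhesionDecay}{corneocyte adhesion
#'     maturity: initial level, age of peak (steps), and multiplicative decay
#'     rate thereafter (enzymatic bond degradation).}
#'   \item{desqThreshold}{mean per-neighbour adhesive strength (force per unit
#'     area) below which a surface corneocyte desquamates.}
#'   \item{daughterOffset}{lateral placement radius of a daughter cell (um).}
#' }
#' @export
defaultBehaviourParameters <- function() {
  list(
    stemCycle = c(40, 55),
    taCycle = c(20, 28),
    caThreshold = 2,
    lowWaterThreshold = 15,
    lowWaterPersist = 30,
    sgMaturation = 25,
    shapeTargets = list(
      STEM = c(5, 5, 5), TA = c(5, 5, 5), SB = c(5, 5, 5),
      SS = c(6.5, 6.5, 3.5), SG = c(8, 8, 2.2), SC = c(15, 15, 0.45)
    ),
    shapeRate = 0.25,
    tjRate = 0.06,
    lipidRate = 0.06,
    prematureMult = 4,
    prematureLipidProduction = TRUE,
    lowCaThreshold = 0.4,
    adhesionInit = 0.25,
    adhesionPeak = 40,
    adhesionDecay = 0.005,
    desqThreshold = 5e-4,
    daughterOffset = 2
  )
}

drawCycle <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

#' Attempt cell divisions
#'
#' Proliferative cells (stem and transit-amplifying) in membrane contact divide
#' once their age in type reaches their drawn cycle length. Stem cells divide
#' asymmetrically into one stem cell and one TA daughter with three divisions
#' left; TA cells with divisions left produce one non-proliferative SB daughter
#' and lose one division; a TA cell whose division counter is exhausted
#' converts to a non-proliferative SB cell without producing a daughter.
#' Daughters are placed next to the mother with a small random lateral offset,
#' and the mother's water and mobile calcium are split half/half (totals
#' conserved).
#'
#' @param tissue a [Tissue-class].
#' @param behaviour behaviour parameter list.
#' @return `list(tissue, nDivisions, nExhausted)`.
#' @export
attemptDivisions <- function(tissue, behaviour = defaultBehaviourParameters()) {
  cl <- tissue@cells
  ready <- cl$type %in% PROLIFERATIVE_TYPES & cl$membraneContact &
    cl$ageInType >= cl$cycleLen
  exhausted <- which(ready & cl$type == "TA" & cl$taLeft == 0L)
  if (length(exhausted)) {
    cl$type[exhausted] <- "SB"
    cl$ageInType[exhausted] <- 0L
  }
  dividing <- which(ready)
  dividing <- setdiff(dividing, exhausted)
  if (!length(dividing)) {
    tissue@cells <- cl
    return(list(tissue = tissue, nDivisions = 0L, nExhausted = length(exhausted)))
  }
  k <- length(dividing)
  ang <- runif(k, 0, 2 * pi)
  motherCycle <- integer(k)
  isStem <- cl$type[dividing] == "STEM"
  motherCycle[isStem] <- drawCycle(sum(isStem), behaviour$stemCycle)
  motherCycle[!isStem] <- drawCycle(sum(!isStem), behaviour$taCycle)
  daughterCycle <- drawCycle(k, behaviour$taCycle)

  daughters <- cl[dividing, , drop = FALSE]
  daughters$id <- tissue@nextId + seq_len(k) - 1L
  daughters$type <- ifelse(isStem, "TA", "SB")
  daughters$taLeft <- ifelse(isStem, 3L, 0L)
  daughters$cycleLen <- daughterCycle
  daughters$age <- 0L
  daughters$ageInType <- 0L
  off <- behaviour$daughterOffset
  daughters$x <- daughters$x + off * cos(ang)
  daughters$y <- daughters$y + off * sin(ang)
  daughters$water <- cl$water[dividing] / 2
  daughters$caMobile <- cl$caMobile[dividing] / 2
  daughters$caBound <- 0
  daughters$tj <- 0
  daughters$lipid <- 0
  daughters$adhesion <- 1
  daughters$premature <- FALSE
  daughters$desiccated <- FALSE
  daughters$lowWaterClock <- 0L

  cl$water[dividing] <- cl$water[dividing] / 2
  cl$caMobile[dividing] <- cl$caMobile[dividing] / 2
  cl$ageInType[dividing] <- 0L
  cl$cycleLen[dividing] <- motherCycle
  taMother <- dividing[!isStem]
  cl$taLeft[taMother] <- cl$taLeft[taMother] - 1L

  tissue@cells <- rbind(cl, daughters)
  tissue@nextId <- tissue@nextId + k
  list(tissue = tissue, nDivisions = k, nExhausted = length(exhausted))
}

#' Update differentiation state
#'
#' Applies the lineage rules on the current (frozen) types, so each cell makes
#' at most one transition per step: TA/SB cells that lost membrane contact
#' become SS; SS cells reaching the calcium threshold become SG (homeostatic),
#' SS cells with low water become SG flagged premature; SG cells older than the
#' maturation time cornify to SC; SS/SG cells whose water has been below the
#' low-water threshold for the persistence time desiccate immediately to dead
#' SC. The low-water clock is advanced first; transitions reset the age in
#' type, and new corneocytes start at the initial adhesion maturity.
#'
#' @inheritParams attemptDivisions
#' @return `list(tissue, transitions)` where `transitions` is a named integer
#'   vector of event counts.
#' @export
updateDifferentiation <- function(tissue, behaviour = defaultBehaviourParameters()) {
  cl <- tissue@cells
  if (!nrow(cl)) return(list(tissue = tissue, transitions = integer(0)))
  cl$lowWaterClock <- ifelse(cl$water < behaviour$lowWaterThreshold,
    cl$lowWaterClock + 1L, 0L
  )
  type0 <- cl$type

  toSS <- type0 %in% c("TA", "SB") & !cl$membraneContact
  desiccate <- type0 %in% c("SS", "SG") &
    cl$lowWaterClock >= behaviour$lowWaterPersist
  cornify <- type0 == "SG" & !desiccate & cl$ageInType >= behaviour$sgMaturation
  toSGhomeo <- type0 == "SS" & !desiccate & cl$caMobile >= behaviour$caThreshold
  toSGpremature <- type0 == "SS" & !desiccate & !toSGhomeo &
    cl$water < behaviour$lowWaterThreshold

  change <- toSS | desiccate | cornify | toSGhomeo | toSGpremature
  cl$type[toSS] <- "SS"
  cl$type[toSGhomeo | toSGpremature] <- "SG"
  cl$premature[toSGpremature] <- TRUE
  cl$type[cornify | desiccate] <- "SC"
  cl$desiccated[desiccate] <- TRUE
  cl$adhesion[cornify | desiccate] <- behaviour$adhesionInit
  cl$ageInType[change] <- 0L

  tissue@cells <- cl
  list(tissue = tissue, transitions = c(
    toSS = sum(toSS), toSG = sum(toSGhomeo), toSGpremature = sum(toSGpremature),
    toSC = sum(cornify), desiccated = sum(desiccate)
  ))
}

#' Relax cell shapes toward their type targets
#'
#' Semi-axes relax exponentially toward the per-type target shape
#' (`semi <- semi + rate * (target - semi)`), so cells flatten progressively
#' after each differentiation step; the distance to the target is
#' non-increasing and the target is a fixed point.
#'
#' @inheritParams attemptDivisions
#' @return The updated [Tissue-class].
#' @export
updateShape <- function(tissue, behaviour = defaultBehaviourParameters()) {
  cl <- tissue@cells
  if (!nrow(cl)) return(tissue)
  tg <- do.call(rbind, behaviour$shapeTargets)[cl$type, , drop = FALSE]
  r <- behaviour$shapeRate
  cl$a <- cl$a + r * (tg[, 1L] - cl$a)
  cl$b <- cl$b + r * (tg[, 2L] - cl$b)
  cl$c <- cl$c + r * (tg[, 3L] - cl$c)
  tissue@cells <- cl
  tissue
}

#' Produce barrier components
#'
#' Homeostatic pathway: SG cells (and live corneocytes) produce tight junctions
#' toward saturation; live corneocytes produce lipids. Premature (rescue)
#' pathway: SS and SG cells whose mobile calcium falls below the low-calcium
#' threshold produce tight junctions -- and, with
#' `prematureLipidProduction = TRUE`, lipids -- at the premature multiplier.
#' Desiccated corneocytes are dead and produce nothing.
#'
#' @inheritParams attemptDivisions
#' @return The updated [Tissue-class].
#' @export
updateBarrierComponents <- function(tissue, behaviour = defaultBehaviourParameters()) {
  cl <- tissue@cells
  if (!nrow(cl)) return(tissue)
  liveSC <- cl$type == "SC" & !cl$desiccated
  homeoTj <- cl$type == "SG" | liveSC
  cl$tj[homeoTj] <- cl$tj[homeoTj] + behaviour$tjRate * (1 - cl$tj[homeoTj])
  cl$lipid[liveSC] <- cl$lipid[liveSC] + behaviour$lipidRate * (1 - cl$lipid[liveSC])
  prem <- cl$type %in% c("SS", "SG") & cl$caMobile < behaviour$lowCaThreshold
  if (any(prem)) {
    m <- behaviour$prematureMult
    cl$tj[prem] <- cl$tj[prem] + m * behaviour$tjRate * (1 - cl$tj[prem])
    if (isTRUE(behaviour$prematureLipidProduction)) {
      cl$lipid[prem] <- cl$lipid[prem] + m * behaviour$lipidRate * (1 - cl$lipid[prem])
    }
  }
  tissue@cells <- cl
  tissue
}

#' Corneocyte adhesion maturation and decay
#'
#' Corneocyte adhesion maturity rises linearly from its initial level to 1
#' while the cell's age in type is below the peak age (strong, mostly lateral
#' bonds), then decays multiplicatively toward 0 (enzymatic degradation of the
#' bonds). The maturity is the effective adhesion level used by
#' [contactForces()] and by the desquamation rule. Non-corneocytes are left
#' untouched.
#'
#' @inheritParams attemptDivisions
#' @return The updated [Tissue-class].
#' @export
updateCorneocyteAdhesion <- function(tissue, behaviour = defaultBehaviourParameters()) {
  cl <- tissue@cells
  sc <- cl$type == "SC"
  if (!any(sc)) return(tissue)
  grow <- sc & cl$ageInType < behaviour$adhesionPeak
  decay <- sc & !grow
  rate <- (1 - behaviour$adhesionInit) / behaviour$adhesionPeak
  cl$adhesion[grow] <- pmin(1, cl$adhesion[grow] + rate)
  cl$adhesion[decay] <- cl$adhesion[decay] * (1 - behaviour$adhesionDecay)
  tissue@cells <- cl
  tissue
}

#' Desquamation check
#'
#' A surface-exposed corneocyte desquamates when its mean adhesive strength per
#' neighbour contact -- the per-type-pair adhesion coefficient times the pair's
#' effective adhesion level, i.e. force per unit contact area -- falls below
#' the desquamation threshold. A surface corneocyte with no neighbours has mean
#' strength 0 (it is detached) and desquamates; buried corneocytes never do.
#'
#' @inheritParams attemptDivisions
#' @param graph the current [ContactGraph-class].
#' @param forces force parameter list (adhesion coefficients).
#' @return Logical vector (one per cell): remove this cell now.
#' @export
checkDesquamation <- function(tissue, graph, forces = defaultForceParameters(),
                              behaviour = defaultBehaviourParameters()) {
  cl <- tissue@cells
  n <- nrow(cl)
  out <- logical(n)
  scCells <- which(cl$type == "SC" & graph@exposed)
  if (!length(scCells)) return(out)
  e <- graph@edges
  meanStrength <- numeric(n)
  if (nrow(e)) {
    lvl <- effectiveAdhesionLevel(cl)
    s <- adhesionCoef(cl$type[e$i], cl$type[e$j], forces) * pmin(lvl[e$i], lvl[e$j])
    idx <- c(e$i, e$j)
    tot <- rowsum(c(s, s), idx)
    deg <- tabulate(idx, nbins = n)
    meanStrength[as.integer(rownames(tot))] <- tot
    meanStrength <- ifelse(deg > 0L, meanStrength / pmax(deg, 1L), 0)
  }
  out[scCells] <- meanStrength[scCells] < behaviour$desqThreshold
  out
}
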