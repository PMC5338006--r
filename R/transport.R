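#' @include AllClasses.R contact.R
NULL

#' Default transport parameters
#'
#' Water is on the [0, 100] scale (the dermis pins the top of the scale);
#' calcium is in units of the dermis content. Diffusivities are per um^2 of
#' accurate contact area per step.
#'
#' @return Named list:
#' \describe{
#'   \item{Dw, Dca}{water and calcium diffusivity coefficients.}
#'   \item{kWaterMax, kCaMax}{per-interface exchange-coefficient caps keeping
#'     the explicit per-step update stable on very large flat contacts.}
#'   \item{alpha}{advection coupling: mobile calcium carried per unit water
#'     flux, as a fraction of the donor cell's calcium.}
#'   \item{dermisWater, dermisCalcium}{fixed contents of the dermal reservoir.}
#'   \item{dermisRateWater, dermisRateCalcium}{exchange coefficients of
#'     membrane-contacting cells with the dermis (fraction of the content
#'     difference per step).}
#'   \item{tewlCoeff}{evaporative water loss per um^2 of exposed area per step
#'     at zero humidity and no barrier.}
#'   \item{tewlFloor}{baseline fraction of the maximal evaporation remaining
#'     at saturating humidity (H = 100); keeps a small upward water pull --
#'     and with it the advective calcium supply to the VE/SC border -- alive
#'     at high humidity. 0 disables evaporation entirely at H = 100.}
#'   \item{depositionFraction}{fraction of the evaporated water's calcium
#'     concentration lost as insoluble surface deposits.}
#'   \item{bindRate}{fraction of a corneocyte's mobile calcium bound
#'     (immobilized) per step.}
#'   \item{sTjWater, sLipWater, sTjCalcium, sLipCalcium}{barrier damping
#'     strengths of tight junctions and lipids on water and calcium flow
#'     (the two species are damped to different degrees).}
#'   \item{tjDisabled, lipidDisabled}{knockout switches removing the
#'     corresponding component's effect on transport.}
#' }
#' @export
defaultTransportParameters <- function() {
  list(
    Dw = 1.5e-3,
    Dca = 3e-5,
    kWaterMax = 0.06,
    kCaMax = 0.05,
    alpha = 1.5,
    dermisWater = 100,
    dermisCalcium = 1,
    dermisRateWater = 0.25,
    dermisRateCalcium = 0.3,
    tewlCoeff = 0.05,
    tewlFloor = 0.15,
    depositionFraction = 0.05,
    bindRate = 0.04,
    sTjWater = 1,
    sLipWater = 9,
    sTjCalcium = 19,
    sLipCalcium = 2,
    tjDisabled = FALSE,
    lipidDisabled = FALSE
  )
}

#' Barrier damping factor across a cell-cell interface
#'
#' Multiplicative factor in (0, 1] applied to all fluxes across an interface:
#' \eqn{1 / (1 + s_{tj} \max(tj_A, tj_B)) \times
#'      1 / (1 + s_{lip} \max(lip_A, lip_B))},
#' with species-specific strengths (tight junctions damp calcium more, lipids
#' damp water more). Equals 1 with no barrier components; strictly decreasing
#' in either component's level but bounded away from 0. A disabled (knocked
#' out) component contributes nothing regardless of its level.
#'
#' @param tjA,tjB,lipidA,lipidB component levels on both sides (vectorized).
#' @param transport transport parameter list.
#' @param species `"water"` or `"calcium"`.
#' @return Damping factors in (0, 1].
#' @export
pairDamping <- function(tjA, tjB, lipidA, lipidB,
                        transport = defaultTransportParameters(),
                        species = c("water", "calcium")) {
  species <- match.arg(species)
  sTj <- if (species == "water") transport$sTjWater else transport$sTjCalcium
  sLip <- if (species == "water") transport$sLipWater else transport$sLipCalcium
  fTj <- if (isTRUE(transport$tjDisabled)) 1 else 1 / (1 + sTj * pmax(tjA, tjB))
  fLip <- if (isTRUE(transport$lipidDisabled)) 1 else 1 / (1 + sLip * pmax(lipidA, lipidB))
  fTj * fLip
}

# Symmetric per-edge flux clamp: each edge may move at most 1/degree of the
# donor's available content out, and at most 1/degree of the receiver's free
# capacity in. Both endpoints see the same clamped flux, so conservation is
# exact and per-cell bounds hold after summing over edges.
clampEdgeFlux <- function(qHat, i, j, content, capacity, n) {
  deg <- tabulate(c(i, j), nbins = n)
  donor <- ifelse(qHat >= 0, i, j)
  recv <- ifelse(qHat >= 0, j, i)
  cap <- pmax(0, pmin(
    content[donor] / pmax(deg[donor], 1L),
    capacity[recv] / pmax(deg[recv], 1L)
  ))
  sign(qHat) * pmin(abs(qHat), cap)
}

applyEdgeFlux <- function(values, q, i, j, n) {
  acc <- rowsum(c(-q, q), c(i, j))
  values[as.integer(rownames(acc))] <- values[as.integer(rownames(acc))] + acc[, 1L]
  values
}

#' Diffusive water exchange between neighbouring cells
#'
#' Pairwise flux \eqn{q_{AB} = D_w \cdot A_{acc} \cdot damp_{AB} (w_A - w_B)}
#' across every contact (accurate contact area, water-specific barrier
#' damping), applied with a symmetric per-interface clamp so no cell leaves
#' [0, 100] and the interior total is exactly conserved. The signed fluxes are
#' returned for the advective calcium coupling.
#'
#' @param tissue a [Tissue-class].
#' @param graph the current [ContactGraph-class].
#' @param transport transport parameter list.
#' @return `list(tissue, fluxes)`; `fluxes[k] > 0` means water moved from edge
#'   endpoint `i` to `j`.
#' @export
waterStep <- function(tissue, graph, transport = defaultTransportParameters()) {
  cl <- tissue@cells
  e <- graph@edges
  if (!nrow(e)) return(list(tissue = tissue, fluxes = numeric(0)))
  damp <- pairDamping(cl$tj[e$i], cl$tj[e$j], cl$lipid[e$i], cl$lipid[e$j],
    transport, "water"
  )
  k <- pmin(transport$Dw * e$areaAccurate, transport$kWaterMax) * damp
  qHat <- k * (cl$water[e$i] - cl$water[e$j])
  q <- clampEdgeFlux(qHat, e$i, e$j, cl$water, 100 - cl$water, nrow(cl))
  cl$water <- applyEdgeFlux(cl$water, q, e$i, e$j, nrow(cl))
  tissue@cells <- cl
  list(tissue = tissue, fluxes = q)
}

#' Calcium exchange: diffusion plus water-coupled transport
#'
#' Per interface, a diffusive part
#' \eqn{D_{ca} \cdot A_{acc} \cdot damp_{AB} (ca_A - ca_B)} plus an advective
#' part \eqn{\alpha \cdot ca_{up} \cdot q_{AB}} carried by the water flux of
#' this step (`up` = the donor cell of the water flux). Clamped per interface
#' so mobile calcium stays non-negative; the interior total is exactly
#' conserved.
#'
#' @inheritParams waterStep
#' @param waterFluxes signed per-edge water fluxes from [waterStep()].
#' @return `list(tissue, fluxes)`.
#' @export
calciumStep <- function(tissue, graph, waterFluxes,
                        transport = defaultTransportParameters()) {
  cl <- tissue@cells
  e <- graph@edges
  if (!nrow(e)) return(list(tissue = tissue, fluxes = numeric(0)))
  damp <- pairDamping(cl$tj[e$i], cl$tj[e$j], cl$lipid[e$i], cl$lipid[e$j],
    transport, "calcium"
  )
  k <- pmin(transport$Dca * e$areaAccurate, transport$kCaMax) * damp
  qDiff <- k * (cl$caMobile[e$i] - cl$caMobile[e$j])
  upstream <- ifelse(waterFluxes >= 0, e$i, e$j)
  # The barrier holds back advected calcium as well (filtration): the carried
  # flux sees the calcium-specific damping of the interface, which is what
  # lets calcium pile up just below the barrier instead of washing through.
  qAdv <- transport$alpha * cl$caMobile[upstream] * waterFluxes * damp
  qHat <- qDiff + qAdv
  q <- clampEdgeFlux(qHat, e$i, e$j, cl$caMobile,
    rep(Inf, nrow(cl)),
    n = nrow(cl)
  )
  cl$caMobile <- applyEdgeFlux(cl$caMobile, q, e$i, e$j, nrow(cl))
  tissue@cells <- cl
  list(tissue = tissue, fluxes = q)
}

#' Boundary exchange: dermal reservoir and evaporation (TEWL)
#'
#' Membrane-contacting cells exchange water and calcium with a fixed-content
#' dermal reservoir (flux proportional to the content difference).
#' Surface-exposed cells lose water by evaporation:
#' `tewlCoeff * exposedArea * damp * ((1 - tewlFloor) * (100 - H)/100 +
#' tewlFloor)`, damped only by the surface cell's own barrier components (the
#' exterior is barrier-free); evaporation decreases with humidity, is maximal
#' at H = 0, and retains the `tewlFloor` baseline at H = 100 (zero if
#' `tewlFloor = 0`). As water
#' evaporates, a fraction of its calcium concentration is lost as insoluble
#' surface deposits. All boundary fluxes are returned so a global balance can
#' be audited.
#'
#' @inheritParams waterStep
#' @param membrane a [MembraneGeometry-class] (unused beyond interface
#'   symmetry; exposure and membrane contact are read from the graph/tissue).
#' @param H ambient humidity in [0, 100].
#' @return `list(tissue, ledger)` with ledger entries `dermisWaterIn`,
#'   `dermisCalciumIn`, `tewlOut`, `depositionOut`.
#' @export
boundaryExchange <- function(tissue, graph, membrane = NULL,
                             transport = defaultTransportParameters(), H = 100) {
  cl <- tissue@cells
  n <- nrow(cl)
  if (!n) {
    return(list(tissue = tissue, ledger = c(
      dermisWaterIn = 0, dermisCalciumIn = 0, tewlOut = 0, depositionOut = 0
    )))
  }
  basal <- cl$membraneContact
  dw <- numeric(n)
  dw[basal] <- transport$dermisRateWater * (transport$dermisWater - cl$water[basal])
  dw <- pmin(pmax(dw, -cl$water), 100 - cl$water)
  cl$water <- cl$water + dw

  dca <- numeric(n)
  dca[basal] <- transport$dermisRateCalcium *
    (transport$dermisCalcium - cl$caMobile[basal])
  dca <- pmax(dca, -cl$caMobile)
  cl$caMobile <- cl$caMobile + dca

  loss <- numeric(n)
  dep <- numeric(n)
  exposed <- graph@exposed
  evapFactor <- (1 - transport$tewlFloor) * (100 - H) / 100 + transport$tewlFloor
  if (any(exposed) && evapFactor > 0) {
    damp <- pairDamping(cl$tj[exposed], 0, cl$lipid[exposed], 0, transport, "water")
    raw <- transport$tewlCoeff * graph@exposedArea[exposed] * damp * evapFactor
    raw <- pmin(raw, cl$water[exposed])
    conc <- cl$caMobile[exposed] / pmax(cl$water[exposed], 1)
    loss[exposed] <- raw
    dep[exposed] <- pmin(
      transport$depositionFraction * conc * raw,
      cl$caMobile[exposed]
    )
    cl$water[exposed] <- cl$water[exposed] - raw
    cl$caMobile[exposed] <- cl$caMobile[exposed] - dep[exposed]
  }
  tissue@cells <- cl
  list(tissue = tissue, ledger = c(
    dermisWaterIn = sum(dw), dermisCalciumIn = sum(dca),
    tewlOut = sum(loss), depositionOut = sum(dep)
  ))
}

#' Corneocyte calcium binding
#'
#' Corneocytes immobilize a fixed fraction of their mobile calcium per step
#' (`transfer = bindRate * caMobile`), moving it to the inert bound pool;
#' the per-cell total (mobile + bound) is invariant. Bound calcium neither
#' diffuses nor advects, so the stratum corneum acts as the sink that shapes
#' the epidermal calcium gradient.
#'
#' @inheritParams waterStep
#' @return `list(tissue, bindingTransfer)`.
#' @export
bindCalcium <- function(tissue, transport = defaultTransportParameters()) {
  cl <- tissue@cells
  sc <- cl$type == "SC"
  transfer <- numeric(nrow(cl))
  transfer[sc] <- transport$bindRate * cl$caMobile[sc]
  cl$caMobile <- cl$caMobile - transfer
  cl$caBound <- cl$caBound + transfer
  tissue@cells <- cl
  list(tissue = tissue, bindingTransfer = sum(transfer))
}
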