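#' @include AllClasses.R contact.R
NULL

#' Default force parameters
#'
#' Forces use overdamped dynamics: a cell's displacement per mechanics
#' sub-iteration is `mobility` times its net force, clamped to `dispCap`.
#' Repulsion is a linear spring in overlap depth; adhesion is proportional to
#' the contact area times a per-type-pair coefficient times the pair's
#' effective adhesion level (corneocytes use their adhesion maturity, all other
#' cells level 1). Basal-capable cells within `attachRange` of the membrane
#' feel a restoring membrane-adhesion spring.
#'
#' @return Named list of parameters:
#' \describe{
#'   \item{kRep}{repulsion stiffness (force per um of overlap).}
#'   \item{kAdhViable}{adhesion coefficient for viable-viable pairs
#'     (force per um^2).}
#'   \item{kAdhSC}{adhesion coefficient when both cells are corneocytes.}
#'   \item{kAdhSCViable}{adhesion coefficient for corneocyte-viable pairs.}
#'   \item{kMem}{membrane-adhesion spring stiffness for basal cells.}
#'   \item{attachRange}{membrane attachment range (um).}
#'   \item{contactTol}{membrane-contact flag tolerance (um).}
#'   \item{mobility}{displacement per unit force (overdamped drag inverse).}
#'   \item{dispCap}{maximum displacement per sub-iteration (um).}
#' }
#' @export
defaultForceParameters <- function() {
  list(
    kRep = 0.4,
    kAdhViable = 0.004,
    kAdhSC = 0.005,
    kAdhSCViable = 0.004,
    kMem = 0.15,
    attachRange = 2,
    contactTol = 0.8,
    mobility = 1,
    dispCap = 2
  )
}

# Per-edge adhesion coefficient from the cell types at both ends.
adhesionCoef <- function(typeA, typeB, forces) {
  scA <- typeA == "SC"
  scB <- typeB == "SC"
  ifelse(scA & scB, forces$kAdhSC,
    ifelse(scA | scB, forces$kAdhSCViable, forces$kAdhViable)
  )
}

# Effective adhesion level of each cell: corneocytes use their maturity,
# everyone else full level.
effectiveAdhesionLevel <- function(cl) {
  ifelse(cl$type == "SC", cl$adhesion, 1)
}

#' Pairwise contact forces
#'
#' Computes the net repulsion + adhesion force on every cell from an annotated
#' contact graph. Repulsion acts along the contact axis with magnitude
#' `kRep * depth` (zero at zero overlap, strictly increasing in overlap);
#' adhesion is attractive with magnitude
#' `kAdh(typeA, typeB) * min(levelA, levelB) * area`, where the area is the
#' fast (sphere-based) approximation when both cells are corneocytes under
#' `scAdhesionArea = "fast"` (the default mode, giving corneocytes their
#' lateral-dominant adhesion), and the accurate approximation otherwise.
#'
#' @param tissue a [Tissue-class].
#' @param graph the current [ContactGraph-class].
#' @param forces force parameter list (see [defaultForceParameters()]).
#' @param scAdhesionArea `"fast"` or `"accurate"`: which area scales
#'   corneocyte-corneocyte adhesion.
#' @return An n x 3 matrix of net forces.
#' @export
contactForces <- function(tissue, graph, forces = defaultForceParameters(),
                          scAdhesionArea = c("fast", "accurate"),
                          membrane = NULL) {
  scAdhesionArea <- match.arg(scAdhesionArea)
  cl <- tissue@cells
  n <- nrow(cl)
  Fm <- matrix(0, n, 3L)
  e <- graph@edges
  if (!nrow(e)) return(Fm)
  if (!is.null(membrane)) {
    # Refresh the contact axis and overlap depth from the current positions
    # (radial extents and areas are kept from the graph build), so repeated
    # relaxation sub-iterations act on up-to-date geometry.
    dx <- wrapDelta(cl$x[e$j] - cl$x[e$i], membrane@Lx)
    dy <- wrapDelta(cl$y[e$j] - cl$y[e$i], membrane@Ly)
    dz <- cl$z[e$j] - cl$z[e$i]
    d <- pmax(sqrt(dx^2 + dy^2 + dz^2), 1e-9)
    e$ux <- dx / d
    e$uy <- dy / d
    e$uz <- dz / d
    e$depth <- pmax(0, e$rA + e$rB - d)
  }
  lvl <- effectiveAdhesionLevel(cl)
  typeA <- cl$type[e$i]
  typeB <- cl$type[e$j]
  anySC <- typeA == "SC" | typeB == "SC"
  # Corneocyte adhesion uses the sphere-based fast area: its overestimate at
  # narrow lateral edges and underestimate at broad flat faces gives
  # corneocytes strong lateral and weak apico-basal adhesion, which drives
  # raft formation and interdigitation. The "accurate" mode is the
  # column-stacking control.
  area <- if (scAdhesionArea == "fast") {
    ifelse(anySC, e$areaFast, e$areaAccurate)
  } else {
    e$areaAccurate
  }
  kAdh <- adhesionCoef(typeA, typeB, forces)
  # Signed magnitude along the A->B axis, acting on A (action-reaction on B):
  # positive pulls A towards B (adhesion), negative pushes apart (repulsion).
  f <- kAdh * pmin(lvl[e$i], lvl[e$j]) * area - forces$kRep * e$depth
  idx <- c(e$i, e$j)
  w <- rbind(
    cbind(f * e$ux, f * e$uy, f * e$uz),
    cbind(-f * e$ux, -f * e$uy, -f * e$uz)
  )
  acc <- rowsum(w, idx)
  Fm[as.integer(rownames(acc)), ] <- Fm[as.integer(rownames(acc)), , drop = FALSE] + acc
  Fm
}

#' One overdamped position update
#'
#' Applies contact forces plus the basal membrane-adhesion spring, displaces
#' every cell by `mobility` times its net force with the per-step displacement
#' clamped to `dispCap`, wraps lateral coordinates periodically, projects any
#' cell pushed below the membrane back onto its surface, and refreshes the
#' membrane-contact flags. Stem cells are pinned to their seeded positions
#' (the proliferative compartment is static).
#'
#' @inheritParams contactForces
#' @param membrane a [MembraneGeometry-class].
#' @return The updated [Tissue-class].
#' @export
integrateStep <- function(tissue, graph, forces = defaultForceParameters(),
                          membrane = membraneGeometry(),
                          scAdhesionArea = "fast") {
  cl <- tissue@cells
  n <- nrow(cl)
  if (!n) return(tissue)
  Fm <- contactForces(tissue, graph, forces, scAdhesionArea, membrane)
  # Membrane adhesion: basal-capable cells close to the membrane are pulled
  # back towards resting height h + c.
  h <- membraneHeight(cl$x, cl$y, membrane)
  gap <- cl$z - cl$c - h
  basal <- cl$type %in% BASAL_TYPES & gap < forces$attachRange
  Fm[basal, 3L] <- Fm[basal, 3L] - forces$kMem * gap[basal]
  if (any(!is.finite(Fm))) {
    bad <- cl$id[which(rowSums(!is.finite(Fm)) > 0L)[1L]]
    stop("non-finite force on cell ", bad)
  }
  disp <- forces$mobility * Fm
  nrm <- sqrt(rowSums(disp^2))
  over <- nrm > forces$dispCap
  if (any(over)) {
    disp[over, ] <- disp[over, , drop = FALSE] * (forces$dispCap / nrm[over])
  }
  disp[cl$type == "STEM", ] <- 0
  cl$x <- wrapCoord(cl$x + disp[, 1L], membrane@Lx)
  cl$y <- wrapCoord(cl$y + disp[, 2L], membrane@Ly)
  cl$z <- cl$z + disp[, 3L]
  # Rigid membrane: project cells pushed below back onto the surface.
  h <- membraneHeight(cl$x, cl$y, membrane)
  below <- cl$z - cl$c < h
  cl$z[below] <- h[below] + cl$c[below]
  cl$membraneContact <- (cl$z - cl$c - h) < forces$contactTol
  tissue@cells <- cl
  tissue
}
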