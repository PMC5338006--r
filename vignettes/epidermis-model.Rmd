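---
title: "A self-organizing 3D epidermis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A self-organizing 3D epidermis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EpidermaSim)
```

# The model

EpidermaSim simulates the human epidermis as an off-lattice, cell-centre
agent-based system. Each cell is an axis-aligned ellipsoid (lateral semi-axes
$a, b$; vertical semi-axis $c$ along the apical--basal direction) carrying a
behavioural state: lineage type (stem, transit-amplifying, non-proliferative
basal, spinous, granular, corneocyte), water content on an arbitrary $[0,100]$
scale, mobile and bound calcium, tight-junction and lipid levels, and a
corneocyte adhesion maturity. Three coupled layers of dynamics run per step:

1. **Behaviour** -- proliferation, differentiation, shape change, barrier
   production, adhesion maturation, desquamation.
2. **Mechanics** -- contact detection between ellipsoids, repulsion/adhesion
   forces scaled by contact area, overdamped position updates over a rigid
   (optionally undulated) basement membrane with periodic lateral boundaries.
3. **Transport** -- water diffusion between direct neighbours, calcium
   diffusion plus water-coupled transport, exchange with a fixed-content
   dermal reservoir below, evaporation (TEWL) to the environment above, and
   calcium binding by corneocytes.

One simulation step nominally represents 30 minutes; the reduced profile used
throughout the tests compresses the biological time constants (see
*Profiles*).

## Ellipsoid contact geometry

All forces and fluxes are scaled by cell--cell contact areas, for which two
approximations coexist:

* **Fast (sphere-based).** Each cell is replaced by a sphere whose radius is
  its radial extent along the centre--centre line,
  $r(u) = (u_x^2/a^2 + u_y^2/b^2 + u_z^2/c^2)^{-1/2}$, and the area of the
  sphere--sphere intersection circle is used. For strongly oblate cells this
  *overestimates* the narrow lateral contacts and *underestimates* the broad
  apico-basal contacts.
* **Accurate (separating-plane cross-section).** The overlap region of the
  two ellipsoids is cut by the plane normal to the contact axis at the
  mid-point of the overlap segment; each planar section is an ellipse, and the
  area of their convex intersection is integrated exactly along polar rays
  with a trapezoidal angular quadrature (48 angles by default; the integrand
  is smooth and periodic, so the rule converges spectrally). The unit tests
  verify agreement with the closed sphere/co-axial-oblate forms and with a
  Monte-Carlo oracle to within 2--3%.

Transport always uses the accurate area (the physical interface). Adhesion of
any contact involving a corneocyte uses the fast area: its bias gives
corneocytes strong lateral and weak apico-basal adhesion -- which is what
human corneocytes show -- and this single rule produces the interdigitated,
raft-like stratum corneum. Setting `scAdhesionArea = "accurate"` in the
configuration is the control experiment in which adhesion is proportional to
the true contact area; corneocytes then prefer vertically aligned stacking.

Overlap depth along the centre line, $\delta = \max(0, r_A + r_B - d)$,
defines contact ("direct neighbours"); repulsion is a linear spring in
$\delta$, adhesion is $k_{adh}(\mathrm{type}_A, \mathrm{type}_B) \cdot
\min(\mathrm{level}_A, \mathrm{level}_B) \cdot \mathrm{area}$, where viable
cells have level 1 and corneocytes their adhesion maturity. Positions follow
overdamped dynamics (displacement = mobility x net force, clamped to a 2 um
per-substep cap). Stem cells are pinned to their seeded positions: the
proliferative compartment is static.

## The behavioural model

* Stem cells divide asymmetrically (stem + TA daughter with 3 divisions
  left); TA cells divide asymmetrically up to three times, producing
  non-proliferative basal (SB) daughters, then convert to SB themselves.
  Division requires membrane contact; cycle lengths are drawn per division
  from uniform ranges. Daughters get half of the mother's water and mobile
  calcium (totals conserved).
* TA/SB cells that lose membrane contact become spinous (SS).
* SS cells differentiate to granular (SG) when their mobile calcium reaches
  `caThreshold` (homeostatic route) or immediately -- flagged premature --
  when their water falls below `lowWaterThreshold`.
* SG cells cornify to corneocytes (SC) after `sgMaturation` steps; SS/SG
  cells whose water stays below the threshold for `lowWaterPersist`
  consecutive steps desiccate directly into dead corneocytes.
* Each transition switches the cell's target shape; semi-axes relax
  exponentially toward the target (corneocytes flatten to 30 um diameter,
  0.9 um height).
* SG cells and live corneocytes produce tight junctions; live corneocytes
  produce lipids; SS/SG cells whose calcium falls below `lowCaThreshold`
  produce both prematurely at `prematureMult` times the homeostatic rate
  (set `prematureLipidProduction = FALSE` for the alternative reading in
  which premature production is restricted to tight junctions). Desiccated
  corneocytes are passive obstacles and produce nothing.
* Corneocyte adhesion maturity rises linearly to its peak at
  `adhesionPeak` steps of corneocyte age, then decays multiplicatively
  (enzymatic bond degradation). A surface-exposed corneocyte desquamates
  when its mean per-neighbour adhesive strength falls below
  `desqThreshold`; a detached surface corneocyte (no neighbours) always
  desquamates.

## Transport and the barrier feedback loops

Fluxes act between direct neighbours only, so transport through a stack of
flat cells takes many more hops than through round cells -- tortuosity is
emergent, not parameterized. Per interface and step:

* water: $q = \min(D_w A_{acc}, k_{max}) \cdot damp_w \cdot (w_A - w_B)$;
* calcium: diffusive part $\min(D_{ca} A_{acc}, k_{max}) \cdot damp_{ca}
  \cdot (ca_A - ca_B)$ plus an advective part $\alpha \cdot ca_{up} \cdot q
  \cdot damp_{ca}$ carried by the water flux ($up$ = the donor cell of the
  water flux).

The damping factor of an interface is
$1/(1 + s_{tj}\max(tj)) \times 1/(1 + s_{lip}\max(lip))$ with
species-specific strengths: tight junctions damp calcium strongly and water
weakly, lipids the reverse. The advected calcium is damped too (the barrier
filters what the water carries); without this the advective chain cannot
accumulate calcium anywhere and no peak forms at the VE/SC border.

Boundaries: membrane-contacting cells exchange with a fixed-content dermis
(water 100, calcium 1 -- calcium is measured in units of the dermal content);
surface-exposed cells evaporate
$tewl \cdot A_{exp} \cdot damp \cdot f(H)$ with
$f(H) = (1 - f_0)(100 - H)/100 + f_0$. The baseline $f_0$ (`tewlFloor`,
default 0.15) keeps a small evaporative pull alive at $H = 100$; it is what
sustains the upward water flux -- and with it the advective calcium supply to
the differentiation front -- under a mature barrier at high humidity. With
$f_0 = 0$ the law reduces to the strictly linear form with zero TEWL at
saturation. A fraction of the calcium concentration of evaporated water is
lost as insoluble surface deposits; corneocytes additionally move mobile
calcium to an inert bound pool each step.

These pieces close the feedback loops: TEWL drives upward water flow; water
flow carries calcium to the top of the viable epidermis where the barrier
holds it; the calcium peak drives SS to SG differentiation; SG and SC build
the barrier; the barrier damps TEWL and calcium flow. The premature (low
calcium / low water) pathways bootstrap an initial barrier in a growing
tissue and rescue it under dry conditions.

Numerical safeguards: all pairwise fluxes pass through a symmetric per-edge
clamp (at most $1/\mathrm{degree}$ of the donor's content and of the
receiver's free capacity per interface), which keeps water in $[0, 100]$ and
calcium non-negative while conserving totals exactly -- the per-step ledger
audits $\Delta(\mathrm{total})$ against boundary fluxes to $10^{-8}$ in the
tests. The per-interface exchange coefficients are capped (`kWaterMax`,
`kCaMax`) so the explicit update remains stable on very large flat contacts.

## Scheduler, determinism, snapshots

Each step executes, in a fixed documented order: behaviour -> contact-graph
rebuild -> mechanics sub-iterations (3 by default; contact axes and overlap
depths are refreshed from current positions between sub-iterations, cached
areas are reused) -> transport -> desquamation -> metrics. A single RNG
stream is seeded once per run; snapshots serialize the complete state
including the RNG state, so `loadSnapshot(saveSnapshot(x))` reproduces the
state exactly and a resumed run is step-for-step identical to an
uninterrupted one (asserted in the tests).

# Profiles and the choice of defaults

Two configuration profiles ship with the package:

* **`reduced`** (default): one rete-ridge period (60 x 60 um, amplitude
  10 um), 8 stem cells, compressed time constants (stem cycle 40--55 steps,
  TA cycle 20--28, SG maturation 25, corneocyte adhesion peak 40 with slow
  decay). A 1,200-step growth run completes in about two minutes on one CPU;
  all tests and the acceptance script use this scale.
* **`paper`**: 200 x 200 um, 32 stem cells, 20,000 steps of 30 minutes with
  proportionally slower rates -- the full-tissue protocol. Such runs take
  many hours and are opt-in.

Almost none of the rate constants of the original model are published; every
one is exposed in the configuration, and the reduced-profile defaults are the
package's own parameterization, calibrated so that the reduced tissue
reproduces the qualitative behaviours described above (self-organized
stratification, calcium peak below the SC, humidity-dependent growth,
barrier buffering) with morphology as close as the reduced scale allows to
the reported ranges (viable epidermis 22--72 um, stratum corneum 23--28 um
between rete-ridge troughs and crests). Design choices made where the
original is silent, and worth knowing about:

* *TEWL at saturating humidity.* "Inversely proportional to H" is
  implemented as the affine factor above. A strictly linear law (zero TEWL
  at H = 100) was tried first and leaves the model without any upward water
  flux at high humidity: calcium then peaks at the dermis, differentiation
  happens at the bottom of the tissue and stratification inverts. A small
  evaporative baseline restores the reported behaviour; `tewlFloor = 0`
  recovers the strict law.
* *Advective filtration.* The barrier damps the advected calcium flux, not
  only diffusion; this is what lets calcium pile up below the stratum
  corneum instead of washing through it.
* *Threshold above the dermis level.* The homeostatic SS to SG calcium
  threshold (2, twice the dermal content) can only be crossed inside the
  advective accumulation zone at the top of the viable epidermis, never by
  dermal equilibration alone -- placing the differentiation front at the
  VE/SC border.
* *Fast-area adhesion for every corneocyte contact.* See the geometry
  section; restricting the fast area to corneocyte-corneocyte pairs leaves
  plates tethered to viable neighbours and destroys the layering.
* *Surface exposure* is defined by depth below the local tissue surface
  (within 1.5 um of the topmost covering body), which admits the full
  rugged top layer; membrane contact is a 0.8 um tolerance band above the
  membrane surface.
* *Homeostasis* is not defined operationally in the original; here it is
  thickness stability -- the earliest step from which total thickness stays
  within a tolerance band of its window mean (window 150 steps and 12%
  relative tolerance at the reduced scale, where a single desquamation event
  moves the sampled thickness by a few percent).
* *Isolated surface corneocytes desquamate* (their mean adhesion is vacuously
  zero); daughters split water and calcium half/half; coincident centres are
  resolved by a tiny random lateral displacement from the simulation RNG
  stream; lateral boundaries are periodic.

# What the fixtures emulate -- and what they do not

The programmatic fixtures (`makeColumn()`, `makeSlab()`,
`makeLatticePoints()`) provide miniature tissues with construction-time
ground truth: a single cell column with a dermis below and evaporation above
reproduces the one-dimensional gradient physics (monotone water profile,
calcium peak below a corneocyte band, steepening with falling humidity); the
slab provides exact layer boundaries for the thickness and cross-section
analyses; the lattices provide known Delaunay topology. Passing these tests
validates the transport operators, the measurement code and the topology
pipeline -- they do not by themselves validate full-tissue morphogenesis,
which involves the mechanics/behaviour coupling at a scale the fixtures do
not reach.

# Known limitations

* At the reduced scale (a 60 um box holding 30 um corneocyte plates above
  8 pinned stem cells) the mechanical sorting of plates is imperfect: the
  differentiation front tends to sit low over the rete-ridge trough, some
  corneocytes remain embedded in the viable epidermis, and the measured
  deep-trough viable thickness underruns the full-scale range while the
  stratum corneum span overruns it. The per-module physics (contact areas,
  force laws, transport operators, conservation, the column-gradient
  behaviour) is verified independently of this emergent limitation; the
  acceptance suite reports the emergent morphology honestly rather than
  relaxing its targets.
* The proliferative compartment is static (pinned stem cells, fixed division
  rules); there is no apoptosis, no immune or pigment cells, no substrate
  remodelling, and no inertial mechanics.
* Ellipsoids are axis-aligned; cells flatten but never rotate.
* Transport is strictly cell-to-cell; there is no extracellular continuum.

# A worked example

```{r example, eval = FALSE}
cfg <- defaultConfig("reduced", steps = 1200L, seed = 101L, humidity = 100)
res <- runSimulation(cfg)
res

m <- trajectoryMetrics(res)
tail(thicknessSeries(m, "deepest", "total"))
detectHomeostasis(thicknessSeries(m, "deepest", "total"),
  window = 150, tolerance = 0.12
)
depthProfile(res@tissue, cfg@membrane, "caMobile", binHeight = 5)

# Perturbation protocols
prot <- humiditySwitchProtocol(res@snapshot, HNew = 0,
  preSteps = 60L, postSteps = 440L
)
stripped <- tapeStrip(res@tissue, "SC_only")
koCfg <- knockoutConfig(cfg, "tight_junctions")
```
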