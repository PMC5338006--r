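# EpidermaSim

A self-organizing 3D simulation of the human epidermis for skin-biology
modellers: an off-lattice, cell-centre agent-based model in which every cell
is an axis-aligned ellipsoid — so the extremely flattened corneocytes of the
stratum corneum (30 µm wide, under 1 µm high) have a realistic shape — and in
which barrier formation, trans-epidermal water loss (TEWL), and water and
calcium transport are coupled through explicit feedback loops.

## The model in brief

* **Geometry.** Cell bodies are ellipsoids with semi-axes $(a, b, c)$; the
  radial extent along a unit direction $u$ is
  $r(u) = (u_x^2/a^2 + u_y^2/b^2 + u_z^2/c^2)^{-1/2}$, and overlap along the
  centre line, $\delta = \max(0, r_A + r_B - d)$, defines contact. Two
  contact-area approximations coexist: a fast sphere-based one (overestimates
  narrow lateral contacts, underestimates broad flat ones) used for
  corneocyte adhesion — the bias that produces interdigitation — and an
  accurate separating-plane cross-section used for transport.
* **Mechanics.** Linear-spring repulsion in $\delta$, area-proportional
  adhesion, overdamped position updates over a rigid, optionally undulated
  (rete-ridge) basement membrane with periodic lateral boundaries.
* **Behaviour.** Asymmetric stem and transit-amplifying divisions feed a
  differentiation cascade (basal → spinous → granular → corneocyte) driven by
  calcium accumulation and water starvation; granular cells and corneocytes
  build the barrier (tight junctions, lipids); corneocyte adhesion matures,
  decays, and surface corneocytes desquamate below an adhesion threshold.
* **Transport.** Water diffuses between direct neighbours; calcium diffuses
  and is carried by the water flux; the dermis below is a fixed source, the
  environment above an evaporative sink scaled by ambient humidity
  $H \in [0, 100]$; the barrier locally damps every flux. Corneocytes bind
  calcium, shaping the epidermal calcium gradient that peaks at the border
  between viable epidermis and stratum corneum.

Everything is exposed through S4 classes (`Tissue`, `SimulationConfig`,
`ContactGraph`, `Snapshot`, `TrajectoryMetrics`) with accessors, YAML
configuration files, exact-resume snapshots, and analysis tools: layer
thickness at rete-ridge troughs/crests, depth-binned water/calcium profiles,
calcium histograms over time, planar cross sections and Delaunay neighbour
topology. See `vignette("epidermis-model")` for the full model description
and design choices.

## Worked example

```r
library(EpidermaSim)

cfg <- defaultConfig("reduced", steps = 1200L, seed = 101L, humidity = 100)
res <- runSimulation(cfg)
res
#> SimulationResult after 1200 steps
#> Tissue with 294 cells
#>    STEM: 8  TA: 3  SB: 3  SS: 181  SG: 2  SC: 97
#>   z range [-5.0, 57.7] um; total water 26559.2, mobile calcium 148.14

m <- trajectoryMetrics(res)
detectHomeostasis(thicknessSeries(m, "deepest", "total"),
  window = 150, tolerance = 0.12)
#> [1] 700
```

The run grows a stratified tissue from 8 seeded stem cells: the counts show
the four layers (basal compartment, spinous, granular, cornified), and the
thickness series stabilizes around step 700. Perturbation protocols operate
on the final snapshot:

```r
prot <- humiditySwitchProtocol(res@snapshot, HNew = 0,
  preSteps = 60L, postSteps = 440L)    # barrier buffering after a dry switch
stripped <- tapeStrip(res@tissue, "SC_only")          # in silico tape strip
ko <- runSimulation(knockoutConfig(cfg, "lipids"))    # barrier knockout
```

A thin command-line front end over these functions ships in
`inst/scripts/epidermasim-cli.R` (`grow`, `switch-humidity`, `tape-strip`,
`knockout`, `analyze`), with example YAML profiles under `inst/extdata/`.

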