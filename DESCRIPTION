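Package: EpidermaSim
Title: Self-Organizing 3D Epidermis Simulation with Ellipsoid Cell Mechanics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An off-lattice, cell-centre agent-based simulator of human epidermal
    stratification and barrier formation. Cells are axis-aligned ellipsoids whose
    contact areas scale adhesive forces and cell-to-cell transport; a keratinocyte
    behavioural model (asymmetric stem/transit-amplifying proliferation, calcium- and
    water-triggered differentiation, tight-junction and lipid production, corneocyte
    adhesion maturation and desquamation) couples to diffusive water flow, water-coupled
    calcium transport, a dermal source and an evaporative sink controlled by ambient
    humidity. Includes experiment protocols (growth, humidity switch, tape stripping,
    barrier-component knockouts), snapshotting with exact resume, and the analysis tools
    used to validate morphology: layer thickness at rete-ridge troughs and crests,
    depth-binned water and calcium profiles, calcium histograms over time, planar cross
    sections and Delaunay neighbour topology.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'EpidermaSim-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'membrane.R'
    'geometry.R'
    'contact.R'
    'transport.R'
    'forces.R'
    'behaviour.R'
    'config.R'
    'engine.R'
    'delaunay.R'
    'analysis.R'
    'fixtures.R'
    'protocols.R'
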