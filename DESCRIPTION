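Package: scwnet
Title: Energetic Interaction Networks and QTAIM Classification for Supercritical Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the microstructure of supercritical water as a
    complex network. Molecular configurations of rigid four-site water are
    read from fixed-width coordinate/velocity frame files; pairs of molecules
    are connected when their Coulomb plus Lennard-Jones plus relative kinetic
    energy, penalized by a weighted hydrogen thermal-energy term, is negative
    and no third body lies in an interference cylinder between them. The
    resulting graphs are summarized by network density, average degree,
    PageRank and connected components; component-size distributions are
    modelled by a power law n_c(s) = A * s^b; the thermal weight lambda is
    calibrated against reference cluster-size distributions; representative
    frames and components are selected by principal component analysis; and
    QTAIM bond-critical-point property tables are classified into
    noncovalent, partially covalent and covalent interactions. A synthetic
    configuration generator with planted clusters makes every stage testable
    without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'scwnet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'forcefield.R'
    'frame.R'
    'thermo.R'
    'gro-io.R'
    'energetics.R'
    'network.R'
    'topology.R'
    'powerlaw.R'
    'calibration.R'
    'selection.R'
    'qtaim.R'
    'synthetic.R'
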