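Package: dimerfes
Title: Dimerization Free-Energy Surfaces of Rigid Aromatic Molecules by
    Well-Tempered Metadynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for computing and analysing dimerization
    free-energy surfaces (FES) of small planar aromatic molecules. Provides
    synthetic rigid-molecule generators, Lennard-Jones plus reaction-field
    nonbonded energetics, the collective variables used for aromatic
    stacking (centre-of-geometry distance, inter-ring torsion, plane-normal
    angle), rigid-body Metropolis Monte Carlo and overdamped Langevin
    samplers, a well-tempered metadynamics bias engine with PLUMED-style
    HILLS/COLVAR text I/O, FES post-processing (time-dependent-offset
    reweighting, entropic distance correction, zero-shifting, binding-mode
    extraction, profile comparison) and block-analysis error estimation with
    a convergence diagnostic.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
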