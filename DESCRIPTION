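Package: phorekin
Title: Common Pharmacophore Hypotheses, 3D Database Matching and GPCR
    Signaling Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ligand-based virtual screening and receptor signaling
    analysis. Perceives typed pharmacophore features (acceptor, donor,
    hydrophobe, negative, positive, aromatic ring) from 3D molecules or
    abstract site-set files, enumerates feature-type variants, discovers
    common pharmacophore arrangements shared by active ligands, aligns and
    ranks hypotheses with a weighted survival score, and searches conformer
    databases for geometric matches scored by fitness. A companion kinetics
    module builds ordinary-differential-equation models of GPCR signaling
    networks (Michaelis-Menten and mass-action rate laws), simulates agonist
    dose responses, classifies insulin and cAMP response directions, supports
    SBML exchange, and recovers rate parameters from noisy trajectories.
    Includes a bundled GPR142 beta-cell signaling network and synthetic-data
    generators for planted-pharmacophore and kinetic-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    deSolve,
    minpack.lm,
    xml2,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
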