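Package: dimerscope
Title: Analysis of pH-Dependent Peptide Dimerization from Replica-Exchange Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing conformational ensembles of small peptide
    dimers, in particular the amyloid-beta 12-24 fragment, as produced by
    replica-exchange molecular dynamics (REMD). Provides pH-dependent
    protonation and counterion accounting, a toy replica-exchange Monte
    Carlo engine with Metropolis exchange statistics and replica-walk
    diagnostics, Kabsch-Sander backbone hydrogen-bond detection with
    DSSP-style secondary-structure assignment, beta-sheet registry
    classification (parallel i-j and antiparallel i+j patterns),
    dihedral-angle principal component analysis with free-energy
    landscapes and basin extraction, quasiharmonic configurational
    entropy, potentials of mean force over inter-chain distances,
    side-chain contact maps, solvation radial distribution functions,
    block-averaged error estimation, and a family of synthetic-ensemble
    generators with known ground truth so that every analysis stage can
    be validated without running microsecond molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
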