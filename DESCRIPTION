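Package: tandemLBD
Title: Tandem Ligand-Binding-Domain Evolution in TGF-beta Family Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of tandem ligand-binding-domain
    (LBD) multiplications in TGF-beta family receptors: de-novo annotation of
    tandem LBD copies by iterative local alignment, intra-protein identity
    profiles and ligand-epitope retention scoring, pairwise JTT+Gamma
    maximum-likelihood amino-acid distances with site-bootstrap variances,
    molecular-clock weighted regression with duplication-specific rates, and
    an octant-occupancy spatial embedding metric that scores whether an
    inter-domain linker threads through a ligand dimer. A synthetic-data
    generator (clock-evolving domain clades, multi-LBD gene models, toy
    ligand/linker structures) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
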