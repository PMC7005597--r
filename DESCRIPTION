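Package: glowdock
Title: Information-Driven Rigid-Body Protein-Protein Docking by Glowworm
    Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rigid-body protein-protein docking in which ambiguous residue
    restraints (active/passive interface residues on either binding partner)
    are exploited before sampling, by filtering swarms of candidate poses to
    the restrained receptor surface and pre-orienting initial ligand poses,
    and during sampling, by biasing a distance-binned statistical pair
    potential with the fraction of satisfied contact restraints at every
    step of a glowworm swarm optimization. Includes constructors for
    degraded-information restraint scenarios (partial and partially wrong
    interfaces, single-residue and single-pair restraints), a CAPRI-style
    evaluation layer (fnat, interface and ligand RMSD, quality classes,
    Top-N success rates, a-posteriori restraint filtering), and generators
    of synthetic two-body complexes with known interfaces so the whole
    pipeline is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
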