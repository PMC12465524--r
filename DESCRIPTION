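Package: evoscreen
Title: Evolutionary Screening of Ultra-Large Combinatorial Compound Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for virtual screening of make-on-demand combinatorial
    chemical libraries defined by reaction SMARTS building rules and substrate
    building blocks. Implements an evolutionary (genetic) optimizer over
    library addresses with a size-normalized docking fitness (lid_root2), a
    pluggable docking-oracle contract with a synthetic landscape for offline
    testing, and the complete hit-triage cascade: hard physicochemical
    filters, traffic-light property banding, PAINS substructure screening,
    redocking consistency and receptor-ensemble consensus filters, ECFP4
    fingerprint clustering, greedy similarity budget pruning, hit-space
    partner expansion, off-target counter screening, and binding-site
    residue-contact consensus mapping with RMSD-score funnel tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    cluster,
    bio3d,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
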