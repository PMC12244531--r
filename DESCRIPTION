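Package: condensinhic
Title: Hi-C and FISH Quantification of Condensin II-Dependent Chromosome
    Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for measuring how condensin II levels modulate
    long-range chromosomal interactions. Reads sparse binned Hi-C contact
    matrices, balances them by iterative correction, calls A/B compartments
    from observed/expected eigenvectors and pericentric (P) compartments by
    k-means on the first three components, and quantifies distance-stratified
    contact metrics: P(s) decay curves and crossovers, short/long contact
    ratios, trans-contact proportions, chromatin-state-stratified interaction
    strengths, numbered compartment-pair scores with fold changes, and
    stratum-adjusted map reproducibility. Includes differential contact maps,
    insulation-based TAD boundaries with a boundary-change taxonomy,
    virtual 4C with size-matched control anchors, and 3D FISH quantification
    (domain counts, surface area, intermixing, probe-pair contacts and
    power-law distance scaling). A forward simulator with a planted condensin
    activity parameter provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
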