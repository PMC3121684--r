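Package: agscan
Title: Proteome-Scale Analysis of Protein Aggregation Propensity and Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating intrinsic protein aggregation propensity to
    protein turnover at proteome scale. Calls aggregation-prone segments from
    per-residue beta-aggregation propensity profiles (at least five consecutive
    residues above a 5 percent score threshold), scores gatekeeper residues
    (P, R, K, E, D) in the five-residue flanks of each segment, stratifies
    proteins into short- and long-living groups by protein stability index
    (PSI), compares per-protein and per-segment aggregation metrics between
    groups with Mann-Whitney and Kolmogorov-Smirnov tests including length-
    and expression-stratified controls, computes chaperone-binding enrichment
    across four PSI categories, and correlates binned segment propensity with
    per-segment thermodynamic stability. A configurable synthetic proteome
    generator with planted group effects makes every pipeline stage testable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
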