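Package: apscreen
Title: Aggregation-Propensity Screening of Self-Assembling Oligopeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening stack for self-assembling oligopeptides: sequence-space
    enumeration and Latin-hypercube sampling of penta- to decapeptides,
    Wimley-White whole-residue hydrophilicity (logP) with min-max normalization,
    aggregation-propensity (AP) scoring from solvent-accessible surface area
    ratios including the hydrophilicity-corrected scores AP_H and AP_HC, a
    transformer-based regression network for AP prediction trained on
    coarse-grained molecular dynamics style labels (here produced by a built-in
    synthetic surrogate), aggregation-law composition statistics across AP
    ranges, and transferability analysis of concatenated and mixed
    two-pentapeptide systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lhs,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
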