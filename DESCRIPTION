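Package: glycolinker
Title: Plant Cell Wall Glycomics from Linkage, Antibody, CAZome and
    Growth Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for combinatorial glycomic analysis of plant cell
    walls and the bacteria that degrade them. Converts GC-MS peak tables
    of partially methylated alditol acetates (PMAAs) into replicate-
    aggregated molar percent glycosidic-linkage profiles, estimates
    polysaccharide composition by a deterministic three-pass allocation
    of linkages to polysaccharide classes (with fraction-specific rules
    for sequential cell-wall extracts), processes antibody-based glycome
    screens (ELISA panels and microarray polymer profiling), aggregates
    and compares CAZyme family counts across bacterial genomes, and
    classifies bacterial growth proficiency on non-starch polysaccharide
    substrates. A forward simulator generates linkage profiles, wall
    fractionations, antibody plates and growth curves with known ground
    truth so that every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
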