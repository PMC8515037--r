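Package: oilnet
Title: Dose-Effect Weighted Network Pharmacology for Volatile Oils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for dose-effect weighted network pharmacology of
    transdermally applied essential oils. Computes Kovats retention indices
    from GC-MS retention times and an n-alkane ladder, converts octanol-water
    partition coefficients (log P) into transdermal absorption fractions,
    and propagates content-weighted component scores through component ->
    target -> pathway cascades (the Z/T/N weight coefficients). Re-ranks
    pathway-enrichment results by pathway weight instead of enrichment
    p-value, screens differential-expression tables by fold-change and
    p-value thresholds, intersects target sets, assembles bipartite
    component-target networks with SIF and GraphML export, and normalizes
    molecular-docking scores against per-target positive controls
    (S = Z * A / B). Includes seeded generators for every input so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
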