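Package: pathact
Title: Pathway Activity Inference and Topology-Aware Significance from
    RNA-Seq Ortholog Mappings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers metabolic pathway activity levels from per-sample sets of
    expressed KEGG ortholog groups using an iterative uniform binary activity
    model, assesses per-pathway significance with topology-aware permutation
    null models (vertex label swapping and degree-preserving edge swapping) on
    directed enzyme graphs parsed from KGML pathway maps, and compares two
    samples through activity-level ratios and a differential-significance
    probability (probDiff). Includes seeded synthetic generators for pathway
    families, pathway graphs and KGML fixtures so the full pipeline runs
    without KEGG access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
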