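Package: dgerank
Title: Gene-Expression-Driven Multi-Tier Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks small-molecule drugs for repurposing against a disease by
    combining structure-based drug-target screening with systems-biology
    annotation. A composite virtual-screening score integrates docking,
    spherical-harmonic shape similarity, per-descriptor continuous Tanimoto
    similarity and a binding-site contact correction to call per-target hits;
    hits are collapsed to gene-level drug-target tables, connected to diseases
    through gene-disease catalogs, annotated with pathway and molecular-function
    enrichment, and expanded through high-confidence protein-protein
    interactions. Differential-expression tables define a four-tier disease
    profile that is matched to every drug by hypergeometric over-representation
    at the gene, pathway, function and interaction tiers; normalized tier
    values are combined into a weighted association Z-score used for ranking
    and for multi-study consensus lists. Includes seeded synthetic-data
    generators for all inputs so the full workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
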