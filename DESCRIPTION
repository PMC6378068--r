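Package: netpharm
Title: Network Pharmacology Screening, Enrichment and Pathway Integration for Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative systems-pharmacology pipeline for dissecting the
    multi-compound, multi-target mechanism of herbal formulas. Provides ADME
    screening of herbal constituents (oral bioavailability, a Tanimoto-type
    drug-likeness index against a reference descriptor profile, and Caco-2
    permeability, with whitelist rescue of pharmacologically established
    compounds), assembly of compound-target maps with confidence filtering of
    predicted interactions, intersection with disease gene lists,
    over-representation analysis of gene-set collections with
    Benjamini-Hochberg FDR control, construction and degree analysis of
    bipartite compound-target and target-pathway networks with GraphML/SIF
    export, and assembly of an integrated disease pathway annotated by
    therapeutic modules (proliferation, apoptosis, inflammation). Deterministic
    synthetic-data generators supply fixture pipelines and planted-enrichment
    scenarios with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
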