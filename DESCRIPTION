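Package: scaffpred
Title: Scaffold Protein Prediction from Interactomes and Domain Architectures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts scaffold protein candidates from protein-protein
    interaction networks using structural evidence: multi-partner direct
    interaction, domain-domain interactions mediated through distinct
    scaffold domain regions, and triad co-membership in protein complexes.
    Candidates are classified into Type I/II/III by which criteria they
    satisfy, with hub proteins (competitive binding through one region)
    filtered out. Includes readers for edge-list and PSI-MI TAB interaction
    files, Pfam-style domain tables and GMT gene sets; confusion-matrix
    performance metrics against gold-standard lists; 2x2 association
    statistics (chi-square, risk ratio, odds ratio); hypergeometric term
    enrichment with Bonferroni or Benjamini-Hochberg correction;
    scaffold-partner annotation agreement summaries; and a seeded synthetic
    data generator that plants ground-truth scaffold motifs and hub decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
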