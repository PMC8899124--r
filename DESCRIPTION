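Package: dimscreen
Title: Driver-Induced Modular Screening of Drug-Combination Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential co-expression analysis of multi-arm drug-combination
    expression studies. From genes-by-samples expression matrices with a
    five-arm design (sham, vehicle, two monotherapies, combination), the
    package screens differentially expressed genes (one-way ANOVA, fold
    change, multiplicity correction), builds weighted co-expression networks
    per condition (soft-thresholded correlation, topological overlap),
    detects modules by average-linkage clustering with a modularity-optimal
    tree cut, classifies drug-responsive (On-) and conserved modules by
    cross-condition Jaccard similarity, screens combination-specific additive
    modules, and identifies minimum-control driver genes by structural
    network controllability (maximum matching), validated against standard
    node-importance indicators. A synthetic-study generator with planted
    differential expression, planted modules and planted driver hubs supports
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
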