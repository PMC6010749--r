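Package: phylobeta
Title: Phylogeny-Based Explicit Bayesian Logistic Models for Taxon Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian logistic regression for binary taxon
    occurrence in which the environmental slope of each taxon is drawn from
    the slope of its ancestor node, cascading down a rooted phylogenetic
    topology (branch lengths ignored). Provides a Metropolis-within-Gibbs
    sampler with conjugate updates for the tree interior, Bayes-decision
    evidence categories for every node, leave-genera-out cross-validation
    scored by ROC AUC, Robinson-Foulds distances and a greedy supertree
    heuristic, and a synthetic-data generator emulating a stream-survey
    study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pROC,
    withr
Config/testthat/edition: 3
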