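Package: rawr
Title: Random Walk Resampling for Phylogenetic Support Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-aware non-parametric resampling of multiple sequence
    alignments by reversal random walks over alignment columns (RAWR), with a
    teleportation variant and the classical phylogenetic bootstrap. Resampled
    replicates are unaligned, re-aligned and used to re-estimate trees; branch
    support is the fraction of re-estimated trees displaying each bipartition
    of the annotation tree. Includes a multi-locus partitioned protocol,
    evaluation machinery (bipartition confusion classes, precision-recall
    curves and PR-AUC, normalized Robinson-Foulds distance, sum-of-pairs
    alignment error, average normalized Hamming distance, gappiness), built-in
    progressive alignment and neighbor-joining backends plus adapters for
    external aligners and tree estimators, and a GTR+indel sequence evolution
    simulator that emits true alignments with full homology tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
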