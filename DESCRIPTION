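Package: omicsforge
Title: Co-Expression Networks, Functional Modules and Chromatin-State
    Segmentation for Multi-Omics Resources
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytical engine for building multi-dimensional omics
    resources: Pearson/mutual-rank gene co-expression networks with
    AUROC-based threshold tuning against gene-set prior knowledge,
    overlapping functional-module detection by k-clique percolation,
    hypergeometric gene-set enrichment with Benjamini-Hochberg FDR,
    promoter motif enrichment against a randomized gene background,
    and ChromHMM-style chromatin-state segmentation of binarized
    epigenomic marks with a multivariate Bernoulli-emission hidden
    Markov model trained by Baum-Welch EM. Includes seeded synthetic
    data generators with planted ground truth for every input the
    pipeline consumes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
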