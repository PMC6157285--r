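Package: lipidBN
Title: Bayesian Network Analysis of Genotype, Methylation and Triglyceride Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Conditional-Gaussian Bayesian network analysis of cohorts with
    mixed genotype, CpG methylation and blood-lipid measurements. Provides a
    decomposable BIC score for networks over mixed discrete and continuous
    nodes, constraint-aware hill-climbing structure search with random
    restarts, bootstrap model averaging with per-edge strength and direction
    probabilities and an ECDF-based strength threshold, the supporting
    epigenome- and genome-wide regression scans (with methylation principal
    components, Bonferroni thresholds and genomic-control inflation factors),
    and a synthetic-cohort generator that emulates a lipid-lowering
    drug-response study in which causal SNP effects on triglyceride change are
    modified by paired CpG methylation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, BayesianNetwork, Regression,
    MethylationArray, SNP, Lipidomics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
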