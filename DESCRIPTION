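Package: parallevol
Title: Parallelism of Transcriptomic and Metabolomic Evolutionary Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how parallel the molecular response of replicate
    experimentally evolved populations is at two levels of the trait
    hierarchy, the transcriptome and the metabolome. Provides per-population
    differential-abundance calling (negative-binomial GLM likelihood-ratio
    tests for read counts; an exact small-sample permutation test for
    metabolite abundances), pairwise parallelism statistics (Jaccard index of
    significant-feature sets, Pearson correlation of log2 fold changes),
    permutation nulls for population-specific heterogeneity, a
    downsampling-equalized comparison between molecular levels, and a joint
    pathway analysis combining per-omic global-test p-values with Fisher's
    method. A synthetic-data generator emulating a hierarchical
    redundancy model (gene modules aggregating into metabolite shifts) makes
    the full pipeline testable without access to the original deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
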