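Package: doseDE
Title: Gene-Dose Differential Expression and Trajectory Timing for Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Maintainer", "doseDE", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for single-nucleus RNA-seq studies of allelic series
    (knockout / heterozygote / wild type). Provides per-cell quality control, log
    normalization, LISI mixing scores, cell-cycle scoring and cluster marker detection;
    pseudobulk negative-binomial GLM differential expression with pairwise Wald tests and
    an ordinal gene-dose likelihood-ratio test; dose-response classification of
    repressed versus activated genes and a downsampled DEG-burden statistic; moderated
    tests on per-sample cell-type proportions; root-anchored graph pseudotime with
    Moran's I dynamic-gene detection, Kolmogorov-Smirnov shift tests and a
    Kullback-Leibler divergence permutation test for expression timing; hypergeometric
    and expression-matched resampling gene-set enrichment; and AUCell-style regulon
    activity with regulon specificity scores. Includes a synthetic-data generator that
    plants known dose-response and maturation-delay structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    limma,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
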