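Package: ycmscan
Title: Y-Chromosome Microdeletion Detection from STS Capture Depth
Version: 0.1.0
Authors@R:
    person("STS Depth", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Detects Y-chromosomal microdeletions (YCMs) from targeted-capture
    sequencing depth over sequence-tagged sites (STSs). Implements a quality
    control cascade for sample-by-STS depth matrices (IQR outlier removal,
    median-depth cutoff, per-sample normalization, standard-deviation filter),
    three depth-derived predictors, a radial-basis-kernel support vector
    machine deletion classifier with repeated cross-validated grid search,
    merging of per-STS deletion calls into genomic intervals under a 100-kb
    connection rule with a multi-copy skip rule, Y haplogroup assignment from
    SNP marker genotypes against a configurable haplogroup tree, and
    case-control cohort statistics (chi-square, Kruskal-Wallis, one-sided
    Fisher association, annotation-category enrichment). A synthetic-cohort
    simulator with planted deletion architectures and truth labels makes the
    whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
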