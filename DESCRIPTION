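Package: admixscan
Title: Supervised Admixture Deconvolution and Locus-Specific Differentiation Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing tri-continentally admixed cohorts genotyped on
    SNP arrays: genotype QC and LD thinning, reference-defined principal
    component analysis with projection of external samples, maximum-likelihood
    admixture decomposition (unsupervised and supervised with fixed proxy
    panels) under the binomial independent-loci model, selection of supervising
    proxy panels by principal-component extremity, Hudson Fst estimation
    (parameter and sample-corrected forms) with genome-wide ratio-of-averages
    aggregation and percentile-bootstrap confidence intervals, locus-specific
    branch length (LSBL) and population branch statistic (PBS) selection scans
    with region grouping, Hotelling tests of ancestry means, TREEMIX count
    export, and a Balding-Nichols simulator of admixed cohorts with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
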