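Package: altsweep
Title: Multi-Statistic Genome Scans for Recent Positive Selection in a
    Focal Population
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects signatures of recent positive selection in a focal
    population contrasted with two reference populations. Implements
    per-SNP locus-specific branch lengths (LSBL) from pairwise
    Weir-Cockerham FST, sliding-window heterozygosity ratios (lnRH),
    Tajima's D and the standardized difference of D, and a whole-genome
    long-range-haplotype (EHH/REHH) test with gamma-tail significance and
    false-discovery-rate control. Significance is assessed against
    genome-wide empirical distributions; significant markers are
    clustered into megabase candidate regions with a hypergeometric test,
    genes are ranked against a per-gene extreme-value null with
    Kolmogorov-Smirnov pathway enrichment, and a forward-time
    Wright-Fisher simulator of three-population sweep data provides
    ground-truth inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
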