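Package: sweepscan
Title: Selective-Sweep Scans in Domesticated Populations with PBS, iHS and
    Haplotype Diversity
Version: 0.1.0
Authors@R:
    person("Sweepscan", "Developers", email = "sweepscan@example.org",
           role = c("aut", "cre"))
Description: Genome-wide scans for directional selection in a three-population
    design (two domesticated breeds plus a wild outgroup): the population
    branch statistic (PBS) from Hudson-style F_ST in SNP-count sliding
    windows, the integrated haplotype score (iHS) from extended haplotype
    homozygosity with outgroup-based allele polarization, and a
    distinct-haplotype-count diversity statistic (H). Includes gene-level
    outlier calling with a 1 kb flank rule, QTL-overlap enrichment by set
    resampling with Bonferroni correction, and synthetic-data generators (a
    structured-coalescent simulator without recombination and a forward
    Wright-Fisher simulator with recombination and planted sweeps) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
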