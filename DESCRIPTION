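Package: imprintr
Title: Imprintome Inference from Reciprocal-Cross Allele-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genomic imprinting (maternally and paternally expressed
    genes, MEGs and PEGs) in seed endosperm from reciprocal crosses of two
    polymorphic diploid parents. Parses parental genotypes from VCF, filters
    and classifies SNPs into imprinting-informative categories (reciprocal
    homozygous and single-parent heterozygous sites), extracts and merges
    per-library allelic read counts, transforms discriminant-allele counts
    into per-gene maternal proportions for each cross direction, tests
    departures from the ploidy-determined null with chi-squared tests under
    Benjamini-Hochberg FDR control, and calls moderate and strong MEGs/PEGs
    from reciprocal thresholds. Also provides exact contingency-table
    enrichment statistics for gene-set overlaps (including cross-species
    imprinted-gene comparisons via ortholog maps) and a fully seeded
    beta-binomial simulator of reciprocal-cross endosperm data with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    withr,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
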