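Package: TagGS
Title: Tag-SNP Discovery and Genomic Selection for Dual-Trait Crop Breeding
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis toolkit for breeding programs that combine
    marker-assisted selection on a major-gene quality trait with genomic
    selection on a low-heritability yield trait. Provides multi-environment
    phenotype modelling (REML variance components, broad-sense heritability,
    BLUEs), a mixed-linear-model genome-wide association scan with kinship
    correction and noncentral chi-square power analysis, linkage-
    disequilibrium haplotype-block detection and tag-SNP selection with
    regression and genotype-class validation, VanRaden genomic-relationship
    GBLUP with cross-validated predictive ability, and a selection-intensity
    elite-retention decision tool. A founder-mosaic population simulator
    generates genotypes with block LD structure and multi-environment
    phenotypes with known ground truth for end-to-end exercise of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    vcfR,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociationStudies, SNP, LinkageDisequilibrium,
    GenomicVariation, Regression
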