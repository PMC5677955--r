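Package: mosaicburden
Title: Mosaic Protein-Truncating Variants in Blood DNA and Solid-Tumor Cancer Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of mosaic (clonal-hematopoiesis) protein-truncating
    variants in the leukemia-associated genes PPM1D, TET2, ASXL1 and DNMT3A
    from blood-derived exome genotypes, and case-control analysis of their
    association with solid-tumor cancers. Provides a binomial allele-balance
    mosaic caller with depth gating, covariate-adjusted logistic association
    of carrier status with cancer, age-matched resampling burden tests per
    cancer phenotype and per gene with Bonferroni control, paired blood/tumor
    allele-balance depletion tests, exon-position enrichment summaries, and a
    synthetic cohort generator that emulates the study design so the whole
    pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    VariantAnnotation
Suggests:
    MASS,
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
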