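Package: snpEDV
Title: SNP-Based Screening of Essentially Derived Varieties and Minimal
    Identification Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for investigating essentially derived varieties (EDVs) in
    clonally propagated crops from biallelic SNP genotypes.  Reads diploid
    genotype matrices from VCF, computes per-locus diversity statistics
    (minor allele frequency, missing rate, observed heterozygosity, gene
    diversity and polymorphic information content), applies two-stage
    core-SNP filtering with flanking-uniqueness and uniform genome coverage,
    builds pairwise genetic-similarity matrices (GS = NS/(NS+ND)) with
    positive-control threshold calibration for indisputable derivation
    calls, selects core germplasm by least-distance stepwise sampling, and
    constructs minimal SNP identification panels by greedy discernibility
    maximization.  Includes a structured-population genotype simulator
    (Balding-Nichols model with admixture, clonal derivatives and positive
    controls) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
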