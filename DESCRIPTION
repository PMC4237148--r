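Package: ecoscan
Title: Population-Genomic Scans of Ecotype Differentiation from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-population biallelic SNP data that
    separates neutral from putatively selected differentiation. Implements
    Weir-Cockerham fixation-index estimation, an FDIST-style outlier scan
    calibrated by bisection against a simulated neutral
    (heterozygosity, FST) envelope with FDR control, reciprocal
    fixed-difference detection with a Poisson-binomial sampling null,
    between- versus within-ecotype differentiation contrasts
    (Mann-Whitney rank tests and Yates-corrected chi-square), gene
    annotation enrichment with matched neutral background lists, and
    conversion of diffusion-scaled demographic parameters to natural units.
    Includes a hierarchical Balding-Nichols genotype simulator with planted
    selected, balancing and fixed loci for validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
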