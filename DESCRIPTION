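Package: sectorLOH
Title: Mapping Mitotic Recombination from Sectored-Colony SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mapping mitotic reciprocal crossovers and
    their associated gene-conversion tracts in hybrid diploid yeast from
    allele-specific SNP hybridization ratios. Converts per-sector allele-ratio
    profiles into zygosity calls and loss-of-heterozygosity (LOH) segments,
    combines red/white sector pairs into four-chromatid allele counts,
    classifies conversion tracts (3:1, 4:0, hybrid, complex), infers G1 versus
    G2 lesion timing, estimates tract lengths, and tests genome-feature
    enrichment at crossover breakpoints. Includes a synthetic-data module that
    simulates sector pairs with full ground truth, tandem-array copy-number
    dynamics, and the rate and proportion statistics (Wilson score intervals,
    Fisher exact, chi-square, Mann-Whitney) used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
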