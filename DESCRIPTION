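Package: syntpi
Title: Cross-Species Windowed Nucleotide Diversity in Regions of Conserved Synteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps fixed-size genomic windows between two assemblies through
    UCSC chain lift-over with collinearity retention filters, computes
    coverage-filtered per-window nucleotide diversity (pi) per population from
    VCF genotypes, audits trans-species (shared) polymorphism, assembles
    per-window genomic covariates (coding-sequence density, intergenic GC,
    repeat density, length-weighted dS, recombination rate), and explains
    diversity variation with multiple linear regression and principal-component
    regression. Ships a calibrated two-species synthetic-data generator with a
    shared linked-selection landscape and known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
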