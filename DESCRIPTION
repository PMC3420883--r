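Package: tas2rdiv
Title: Population Genetics of Bitter Taste Receptor (TAS2R) Haplotype
    Diversification in Chimpanzee Subspecies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for phased coding-sequence haplotypes of the
    chimpanzee bitter taste receptor (cTAS2R) gene family across subspecies.
    Catalogues single-nucleotide variants, indels, segregating pseudogenes
    (loss of start codon, premature stop, frameshift) and whole-gene
    deletions; collapses nucleotide- and protein-level haplotypes and
    summarises their sharing between populations; computes nucleotide
    diversity (pi), synonymous and non-synonymous diversity (Nei-Gojobori
    site and pathway counting), between-population divergence (dXY),
    per-site FST, and Tajima's D with a coalescent-simulated null; runs a
    Monte Carlo null for the expected number of shared haplotypes between
    two populations; and detects ectopic gene-conversion tracts between
    paralogous receptor genes. Includes a coalescent-based synthetic-data
    generator emulating the two-subspecies study design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
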