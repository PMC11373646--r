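Package: ampliparent
Title: Amplicon Panel Genotyping, Population Genetics, and Parentage Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for SNP amplicon-panel genotyping workflows in aquaculture
    and population genetics: import of hotspot variant-caller genotype tables
    and genepop files, technical-replicate concordance and missingness
    filtering, per-locus statistics (allele frequencies, heterozygosity,
    Weir-Cockerham F_ST, exact Hardy-Weinberg tests, private alleles, Ritland
    relatedness, PCA), marker selection and flank-window extraction for panel
    design, kappa-coefficient kinship likelihoods with a genotyping-error
    model, likelihood-ratio parentage assignment with strong-trio discovery,
    pedigree-free null-allele detection from Mendelian incompatibilities, and
    a pedigree simulator (Balding-Nichols populations, full-sib families,
    null alleles, genotyping error) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
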