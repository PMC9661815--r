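Package: fourgamete
Title: Exact Two-Locus Haplotype Phasing When the Four-Gamete Test Fails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact phasing of two-locus haplotypes for pairs of biallelic SNPs
    at which fewer than four haplotypes segregate (the four-gamete test fails),
    by detecting the empty corner of the 3x3 two-locus genotype-count table.
    Provides direct (non-iterative) estimation of linkage disequilibrium (D,
    D', r2) from the phased gametes with an Excoffier-Slatkin EM baseline for
    comparison; haplotyping of recombination-free chromosomal regions scored
    by polymorphism information content and heterozygosity; and a
    third-haplotype genome-wide association test under a mixed model with a
    VanRaden genomic relationship matrix and effective-tests
    Benjamini-Hochberg false discovery rate control. Includes a seeded
    simulator of two-locus and multi-SNP region genotypes and phenotypes so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
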