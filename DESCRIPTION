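Package: bolterseq
Title: Transposon Excision Footprint Genotyping at the Potato StCDF1 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify potato 'bolter' sports as somatic transposon
    excision events at the maturity locus StCDF1. Classifies targeted and
    long-amplicon sequencing reads into a catalog of StCDF1 alleles by exact
    junction patterns, infers tetraploid allele dosage from read counts with
    PCR amplification-bias-aware multinomial likelihood, discovers novel
    excision-footprint alleles by alignment to the wild-type variable
    region, predicts the protein consequence of indel alleles, and tests
    clonal identity and mosaicism of candidate bolters from genome-wide
    multilocus allele calls. Includes a seeded read and cohort simulator
    emulating the two sequencing designs of the bolter assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
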