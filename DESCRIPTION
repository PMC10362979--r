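Package: mdace
Title: Genotyping of Acetylcholinesterase Insecticide-Resistance Alleles
    in the Housefly
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reference-anchored analysis of Sanger consensus sequences of the
    Musca domestica acetylcholinesterase (ACE2) gene fragment spanning the
    organophosphate/carbamate resistance codons 260, 316, 342 and 407.
    Provides global alignment to an annotated reference with intron excision,
    RR/RS/SS genotype calling from IUPAC ambiguity codes (Sanger double
    peaks), SNP cataloguing with transition/transversion and
    synonymous/nonsynonymous classification, resistance-allele nomenclature
    against a published allele catalog with novel-allele detection,
    population frequency summaries, Tamura-Nei distance and neighbor-joining
    phylogenetics with bootstrap, and a synthetic-cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
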