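Package: privar
Title: Private Variant Prioritization for Rare-Disease Case Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A whole-genome case-versus-cohort variant prioritization
    pipeline for rare monogenic disorders, modelled on the workflow used
    to nominate candidate variants for canine hyperostotic disorders
    (craniomandibular osteopathy and calvarial hyperostotic syndrome).
    Provides transcript-aware consequence annotation with HGVS g./c./p.
    nomenclature including 3'-rule indel normalization, private-variant
    filtering against a population variant catalog under dominant,
    recessive and shared-across-cases inheritance modes, position-weight
    scoring of U2-type GT-AG donor splice sites, mutant protein
    prediction for frameshift and stop-altering alleles, collagen
    Gly-X-Y repeat classification, per-case summary tables with
    homozygous/heterozygous splits, and a deterministic synthetic-data
    generator (reference genome, gene models, cohort and case VCFs with
    machine-readable truth sets) so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
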