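Package: vcfscreen
Title: Screening VCF Files for Known Phenotype-Associated Variants in
    Domestic Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical screening of variant call format (VCF) files against a
    catalogue of known phenotype-associated variants (e.g. an OMIA export),
    with per-sample zygosity calling, breed-aware partitioning of hits into
    standardized report tables with Mendelian breeding advice, exon-level
    localization of variants from BED12 transcript annotation, and
    within-individual average heterozygosity over loci called in every sample
    of a multi-sample VCF. Includes a deterministic synthetic fixture
    generator producing coherent VCF/VOI/BED/FASTA bundles with known ground
    truth, an HTML + TSV report writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    Rsamtools,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
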