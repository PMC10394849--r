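#' @title Mendelian breeding advice
#' @description Verbatim advice texts for phenotype-associated non-reference
#'   variants, keyed by inheritance pattern and by whether the variant was
#'   found homozygous or heterozygous. The texts follow standard veterinary
#'   genetic-counselling practice; sex-conditional phrasing ("If animal is
#'   female: ...") is kept verbatim because sex is never inferred from the
#'   VCF.
#' @name advice
NULL

advice_homozygous <- c(
  AUTOSOMAL_DOMINANT = paste0(
    "Animal can NOT be used for breeding purposes. Offspring would be ",
    "carrier or homozygous and might develop symptoms"),
  AUTOSOMAL_RECESSIVE = paste0(
    "ONLY combine with wild type animal! Offspring will be carrier and, ",
    "on its turn, can ONLY be combined with wild type animal"),
  MITOCHONDRIAL = paste0(
    "If animal is female: animal can NOT be used for breeding purposes. ",
    "Mitochondria are inherited maternally"),
  X_LINKED_DOMINANT = paste0(
    "Do NOT use animal for breeding purposes because all offspring will ",
    "inherit the defective X chromosome"),
  X_LINKED_RECESSIVE = paste0(
    "Do NOT use animal for breeding purposes as all male offspring will ",
    "inherit the defective X chromosome and will thus be affected"),
  Y_LINKED = paste0(
    "The animal is male and can NOT be used for breeding purposes as ",
    "every male offspring will inherit the defective Y chromosome"),
  UNKNOWN = paste0(
    "Not able to provide breeding advice because inheritance pattern was ",
    "not included in the input file")
)

advice_heterozygous <- c(
  AUTOSOMAL_DOMINANT = "Animal can NOT be used for breeding purposes",
  AUTOSOMAL_RECESSIVE = paste0(
    "Animal can be used for breeding purposes but ONLY if combined with ",
    "a wild type animal. Offspring will be \u00b1 50% carrier and \u00b1 ",
    "50% wild type"),
  MITOCHONDRIAL = paste0(
    "If animal is female: animal can NOT be used for breeding purposes. ",
    "Mitochondria are inherited maternally. If animal is male: animal ",
    "can be used"),
  X_LINKED_DOMINANT = paste0(
    "If animal is female: do NOT use animal for breeding purposes ",
    "because \u00b1 50% of the offspring will inherit the defective X ",
    "chromosome If animal is male, only one X chromosome is present. ",
    "Accordingly, affected animals can NOT be used for breeding purposes ",
    "as all female offspring will be carrier and thus will be affected"),
  X_LINKED_RECESSIVE = paste0(
    "If animal is female: animal can NOT be used for breeding purposes ",
    "as \u00b1 50% of male offspring will inherit the defective X ",
    "chromosome and these male animals will develop symptoms If animal ",
    "is male, only one X chromosome will be present. Affected animals ",
    "can be used ONLY if combined with a wild type female animal. Female ",
    "offspring will be carrier of the variant"),
  Y_LINKED = paste0(
    "The animal is male and can NOT be used for breeding purposes as ",
    "every male offspring will inherit the defective Y chromosome"),
  UNKNOWN = paste0(
    "Not able to provide breeding advice because inheritance pattern was ",
    "not included in the input file")
)

#' General side note rendered with the homozygous advice table
#' @return character scalar.
#' @export
advice_side_note <- function() {
  paste0("Important general side note: Do NOT use animal if this would ",
         "harm the welfare of the animal itself, or the progeny. ",
         "Furthermore, the animal must be capable of carrying out a ",
         "healthy pregnancy")
}

#' Note on mitochondrial heteroplasmy rendered with the heterozygous table
#' @return character scalar.
#' @export
advice_heteroplasmy_note <- function() {
  paste0("Mitochondrial heteroplasmy is the situation in which more than ",
         "one type of mtDNA is present within a cell. Levels of ",
         "heteroplasmy can vary between cells and tissues of one ",
         "individual and influence the threshold for disease phenotype")
}

#' Breeding advice for an inheritance pattern and zygosity class
#'
#' Total over every inheritance code (including `UNKNOWN`, which yields
#' the "not able to provide breeding advice" text) and both advice
#' classes. A Y-linked variant found in a (hemizygous, reported with the
#' homozygous class) state uses the Y-linked text of the heterozygous
#' table, which has the only printed Y-linked row.
#'
#' @param inheritance one of the canonical inheritance codes (see
#'   [parse_inheritance()]); unrecognized values fall back to `UNKNOWN`.
#' @param advice_class `"HOMOZYGOUS"` or `"HETEROZYGOUS"`.
#' @return the advice text, a non-empty character scalar.
#' @export
breeding_advice <- function(inheritance,
                            advice_class = c("HOMOZYGOUS", "HETEROZYGOUS")) {
  advice_class <- match.arg(advice_class)
  tab <- if (advice_class == "HOMOZYGOUS") advice_homozygous
         else advice_heterozygous
  if (!inheritance %in% names(tab)) inheritance <- "UNKNOWN"
  unname(tab[[inheritance]])
}
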