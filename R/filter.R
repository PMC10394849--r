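#' @title Variant filtering against the VOI catalogue
#' @description Zygosity calling at each variant-of-interest locus,
#'   breed-aware partitioning into the standardized report tables, and
#'   gene-wide collection of the remaining variants.
#' @name variant_filter
NULL

#' Verbatim text used for alleles of an uncalled locus
#' @return character scalar.
#' @export
no_call_text <- function() {
  "A call could not be made for this sample at this given locus"
}

zygosity_labels <- c(
  HOM_REF = "Homozygous reference",
  HET = "Heterozygous",
  HOM_NONREF = "Homozygous",
  HEMI_REF = "Hemizygous reference",
  HEMI_NONREF = "Hemizygous",
  NO_CALL = "Zygosity could not be determined"
)

#' Human-readable zygosity label
#' @param zygosity canonical zygosity code(s).
#' @return character vector of report labels (e.g. `"Heterozygous"`,
#'   `"Zygosity could not be determined"`).
#' @export
zygosity_label <- function(zygosity) {
  unname(zygosity_labels[zygosity])
}

#' Call zygosity for one sample at one site
#'
#' Resolves the GT allele indices against REF/ALT into allele strings and
#' classifies the genotype: `HET` when the two called alleles differ,
#' `HOM_NONREF` when both equal and differ from REF, `HOM_REF` when both
#' equal REF; haploid genotypes become `HEMI_REF`/`HEMI_NONREF`; any
#' missing index (including half-calls) is a `NO_CALL`, whose allele texts
#' are the verbatim no-call sentence. Multi-allelic sites are not split:
#' indices are resolved against the full ALT list, so a `1/2` genotype is
#' heterozygous with two non-reference alleles.
#'
#' @param ref REF allele string.
#' @param alt ALT field (comma-separated allele strings, possibly empty).
#' @param gt GT string for the sample (e.g. `"0/1"`).
#' @param context optional label used in error messages (record/sample).
#' @return list with `zygosity` (canonical code), `allele_1`, `allele_2`
#'   (allele strings, the no-call text for uncalled loci, `NA` for the
#'   absent second allele of a haploid call).
#' @export
call_zygosity <- function(ref, alt, gt, context = NULL) {
  g <- parse_gt(gt)
  alleles <- c(ref, if (nzchar(alt) && alt != ".")
    strsplit(alt, ",", fixed = TRUE)[[1L]])
  if (!g$called) {
    return(list(zygosity = "NO_CALL", allele_1 = no_call_text(),
                allele_2 = no_call_text()))
  }
  idx <- c(g$a1, if (g$ploidy == 2L) g$a2)
  if (any(idx < 0L | idx >= length(alleles))) {
    stop("allele index out of range (GT '", gt, "', ", length(alleles) - 1L,
         " ALT allele(s))", if (!is.null(context)) paste0(" at ", context))
  }
  if (g$ploidy == 1L) {
    return(list(
      zygosity = if (g$a1 == 0L) "HEMI_REF" else "HEMI_NONREF",
      allele_1 = alleles[g$a1 + 1L], allele_2 = NA_character_))
  }
  zyg <- if (g$a1 != g$a2) "HET"
         else if (g$a1 == 0L) "HOM_REF"
         else "HOM_NONREF"
  # report alleles in index order so 0/1 and 1/0 render identically
  idx <- sort(idx)
  list(zygosity = zyg, allele_1 = alleles[idx[1L] + 1L],
       allele_2 = alleles[idx[2L] + 1L])
}

normalize_breed <- function(x) {
  tolower(trimws(gsub("[[:space:]]+", " ", x)))
}

non_reference_zygosities <- c("HET", "HOM_NONREF", "HEMI_NONREF")
homozygous_class_zygosities <- c("HOM_NONREF", "HEMI_NONREF")

build_report_row <- function(voi_row, zygosity, allele_1, allele_2,
                             locus_status, vcf_ref, annotations) {
  ann <- if (is.null(annotations)) "" else
    format_locations(locate_position(annotations, voi_row$chrom, voi_row$pos))
  mism <- !is.na(voi_row$ref_allele) && !is.na(vcf_ref) &&
    toupper(substr(voi_row$ref_allele, 1L, 1L)) != toupper(substr(vcf_ref, 1L, 1L))
  data.frame(
    chrom = voi_row$chrom, pos = voi_row$pos, gene = voi_row$gene,
    ref_allele = if (is.na(vcf_ref)) voi_row$ref_allele else vcf_ref,
    allele_1 = allele_1,
    allele_2 = if (is.na(allele_2)) "" else allele_2,
    zygosity = zygosity, inheritance = voi_row$inheritance,
    phenotype = voi_row$phenotype, locus_status = locus_status,
    allele_mismatch = mism, annotation = ann,
    voi_row = voi_row$source_row, stringsAsFactors = FALSE)
}

empty_report_rows <- function() {
  data.frame(chrom = character(0), pos = integer(0), gene = character(0),
             ref_allele = character(0), allele_1 = character(0),
             allele_2 = character(0), zygosity = character(0),
             inheritance = character(0), phenotype = character(0),
             locus_status = character(0), allele_mismatch = logical(0),
             annotation = character(0), voi_row = integer(0),
             stringsAsFactors = FALSE)
}

#' Filter a sample against the variants-of-interest catalogue
#'
#' The core screening step. Every clean VOI row is looked up in the VCF by
#' chromosome + position (1-based): loci absent from the VCF or with a
#' missing genotype surface as no-calls rather than being dropped, so the
#' user can never mistake "not assessed" for "not carried". Rows are then
#' partitioned into exactly one of three tables:
#' \itemize{
#'   \item `priority` — non-reference (or no-call) loci whose VOI breeds
#'     include the sample's breed (case-insensitive, whitespace-normalized
#'     match): the variants with an established genotype-phenotype
#'     association in this breed.
#'   \item `other_breed` — non-reference (or no-call) loci not known to
#'     segregate in this breed; associations can be breed-specific, so
#'     these need careful interpretation.
#'   \item `hom_ref` — loci where the sample is homozygous (or hemizygous)
#'     reference; relevant for mate selection.
#' }
#' Breeding-advice rows (`advice_hom`, `advice_het`) are attached for
#' every non-reference hit. Transcript annotations, when supplied, are
#' attached to each row. A disagreement between the VOI reference allele
#' and the VCF REF is flagged in the `allele_mismatch` column but never
#' changes routing.
#'
#' @param sample_view a single-sample `vcf_table` (see [extract_sample()]).
#' @param voi a clean `voi_table` (after [qc_voi()], or any `voi_table`
#'   with complete rows).
#' @param annotations optional list of `transcript_annotation`.
#' @param breed the sample's breed; if blank, a warning is issued and all
#'   non-reference rows are routed to `other_breed`.
#' @param progress show a progress bar while filtering (default `FALSE`).
#' @return a `filter_result`: list with data.frames `priority`,
#'   `other_breed`, `hom_ref`, `advice_hom`, `advice_het`, plus
#'   `sample_name` and `breed`.
#' @export
filter_variants <- function(sample_view, voi, annotations = NULL,
                            breed = "", progress = FALSE) {
  stopifnot(inherits(sample_view, "vcf_table"),
            inherits(voi, "voi_table"))
  if (length(sample_view$sample_names) != 1L) {
    stop("filter_variants needs a single-sample view; use extract_sample()")
  }
  if (nrow(voi) == 0L) {
    stop("the variants-of-interest table is empty after quality control; ",
         "nothing to filter")
  }
  if (!any(unique(voi$chrom) %in% unique(sample_view$fix$chrom))) {
    stop("none of the VOI chromosomes appear in the VCF; the two files ",
         "likely use different chromosome nomenclatures - consider ",
         "rename_chromosomes() with a chromosome-name map")
  }
  blank_breed <- is.na(breed) || !nzchar(trimws(breed))
  if (blank_breed) {
    warning("no breed given; all non-reference variants will be reported ",
            "in the other-breed table")
  }
  breed_norm <- if (blank_breed) NA_character_ else normalize_breed(breed)
  key <- paste(sample_view$fix$chrom, sample_view$fix$pos)
  pb <- if (progress) utxt_progress(nrow(voi)) else NULL
  rows <- vector("list", nrow(voi))
  routes <- character(nrow(voi))
  for (i in seq_len(nrow(voi))) {
    vr <- voi[i, , drop = FALSE]
    hit <- match(paste(vr$chrom, vr$pos), key)
    if (is.na(hit)) {
      row <- build_report_row(vr, "NO_CALL", no_call_text(), no_call_text(),
                              "ABSENT_FROM_VCF", NA_character_, annotations)
    } else {
      z <- call_zygosity(sample_view$fix$ref[hit], sample_view$fix$alt[hit],
                         sample_view$gt[hit, 1L],
                         context = paste0(vr$chrom, ":", vr$pos, " sample ",
                                          sample_view$sample_names))
      status <- if (z$zygosity == "NO_CALL") "MISSING_GT" else "CALLED"
      row <- build_report_row(vr, z$zygosity, z$allele_1, z$allele_2,
                              status, sample_view$fix$ref[hit], annotations)
    }
    breed_match <- !is.na(breed_norm) &&
      breed_norm %in% normalize_breed(vr$breeds[[1L]])
    routes[i] <- if (row$zygosity %in% c(non_reference_zygosities, "NO_CALL")) {
      if (breed_match) "priority" else "other_breed"
    } else "hom_ref"
    rows[[i]] <- row
    if (!is.null(pb)) utils::setTxtProgressBar(pb, i)
  }
  if (!is.null(pb)) close(pb)
  all_rows <- do.call(rbind, rows)
  pick <- function(what) {
    r <- all_rows[routes == what, , drop = FALSE]
    if (nrow(r) == 0L) empty_report_rows() else r
  }
  result <- list(priority = pick("priority"),
                 other_breed = pick("other_breed"),
                 hom_ref = pick("hom_ref"),
                 sample_name = sample_view$sample_names,
                 breed = breed)
  non_ref <- all_rows[all_rows$zygosity %in% non_reference_zygosities, ,
                      drop = FALSE]
  advice_for <- function(rows_df, class) {
    if (nrow(rows_df) == 0L) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        gene = character(0), zygosity = character(0),
                        inheritance = character(0), advice = character(0),
                        voi_row = integer(0), stringsAsFactors = FALSE))
    }
    data.frame(chrom = rows_df$chrom, pos = rows_df$pos, gene = rows_df$gene,
               zygosity = rows_df$zygosity, inheritance = rows_df$inheritance,
               advice = vapply(rows_df$inheritance, breeding_advice,
                               character(1), advice_class = class),
               voi_row = rows_df$voi_row, stringsAsFactors = FALSE)
  }
  result$advice_hom <- advice_for(
    non_ref[non_ref$zygosity %in% homozygous_class_zygosities, , drop = FALSE],
    "HOMOZYGOUS")
  result$advice_het <- advice_for(
    non_ref[non_ref$zygosity == "HET", , drop = FALSE], "HETEROZYGOUS")
  structure(result, class = "filter_result")
}

utxt_progress <- function(n) {
  utils::txtProgressBar(min = 0, max = n, style = 3)
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Variant screening result for sample '", x$sample_name, "' (breed: ",
      if (nzchar(x$breed)) x$breed else "unspecified", ")\n", sep = "")
  cat("  priority (segregating in breed): ", nrow(x$priority), "\n", sep = "")
  cat("  other breeds:                    ", nrow(x$other_breed), "\n", sep = "")
  cat("  homozygous reference:            ", nrow(x$hom_ref), "\n", sep = "")
  cat("  advice rows (hom/het):           ", nrow(x$advice_hom), "/",
      nrow(x$advice_het), "\n", sep = "")
  invisible(x)
}

#' Collect the remaining variants inside the VOI genes
#'
#' For cases of genetic heterogeneity where the causal variant is not in
#' the catalogue: returns every VCF record of the sample whose position
#' falls within the union of transcript spans of any VOI gene, excluding
#' exact chromosome+position matches to VOI rows. Genes with no transcript
#' in the annotation are reported in the `skipped_genes` attribute.
#'
#' @param sample_view a single-sample `vcf_table`.
#' @param voi a clean `voi_table`.
#' @param annotations list of `transcript_annotation`; must cover the VOI
#'   genes to be useful.
#' @return data.frame of report rows (chrom, pos, gene, alleles, zygosity,
#'   annotation), sorted by chromosome then position, with attribute
#'   `skipped_genes`.
#' @export
extra_filter <- function(sample_view, voi, annotations) {
  stopifnot(inherits(sample_view, "vcf_table"), inherits(voi, "voi_table"))
  if (length(sample_view$sample_names) != 1L) {
    stop("extra_filter needs a single-sample view; use extract_sample()")
  }
  genes <- unique(voi$gene[!is.na(voi$gene)])
  ann_genes <- vapply(annotations, `[[`, character(1), "gene")
  skipped <- setdiff(genes, ann_genes)
  voi_key <- paste(voi$chrom, voi$pos)
  out <- list()
  for (g in setdiff(genes, skipped)) {
    txs <- annotations[ann_genes == g]
    for (i in seq_len(nrow(sample_view$fix))) {
      chrom <- sample_view$fix$chrom[i]
      pos <- sample_view$fix$pos[i]
      inside <- any(vapply(txs, function(tx) {
        tx$chrom == chrom && pos >= tx$span[1L] && pos <= tx$span[2L]
      }, logical(1)))
      if (!inside || paste(chrom, pos) %in% voi_key) next
      z <- call_zygosity(sample_view$fix$ref[i], sample_view$fix$alt[i],
                         sample_view$gt[i, 1L])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, gene = g,
        ref_allele = sample_view$fix$ref[i],
        allele_1 = z$allele_1,
        allele_2 = if (is.na(z$allele_2)) "" else z$allele_2,
        zygosity = z$zygosity,
        annotation = format_locations(
          locate_position(annotations, chrom, pos)),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0), gene = character(0),
               ref_allele = character(0), allele_1 = character(0),
               allele_2 = character(0), zygosity = character(0),
               annotation = character(0), stringsAsFactors = FALSE)
  res <- res[!duplicated(paste(res$chrom, res$pos, res$gene)), , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped_genes") <- skipped
  res
}
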