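#' @title Within-individual average heterozygosity
#' @description Diversity monitoring for breeding programs: the average
#'   heterozygosity He = n_het / n_shared per sample, computed only over
#'   loci called in every sample of the multi-sample VCF so that the
#'   denominator is identical for all samples.
#' @name diversity
NULL

#' Loci called in every sample
#'
#' A locus is shared when every sample's genotype has both allele indices
#' present (no missing index, no half-call). Haploid genotypes cannot be
#' heterozygous, so any locus that is haploid in at least one sample is
#' excluded too, keeping the denominator comparable across samples.
#' File order is preserved.
#'
#' @param table a multi-sample `vcf_table`.
#' @return data.frame with columns `chrom` and `pos` of the shared loci.
#' @export
shared_called_loci <- function(table) {
  stopifnot(inherits(table, "vcf_table"))
  if (length(table$sample_names) < 1L || nrow(table$fix) < 1L) {
    stop("shared_called_loci needs at least one sample and one record")
  }
  ok <- rep(TRUE, nrow(table$fix))
  for (s in seq_along(table$sample_names)) {
    g <- parse_gt(table$gt[, s])
    ok <- ok & g$called & g$ploidy == 2L
  }
  data.frame(chrom = table$fix$chrom[ok], pos = table$fix$pos[ok],
             stringsAsFactors = FALSE)
}

#' Per-sample average heterozygosity
#'
#' For each sample, He = n_het / n_shared where n_het is the number of
#' heterozygous genotypes among the loci called in all samples and
#' n_shared is the size of that shared set — identical for every sample,
#' so estimates are comparable. A genotype is heterozygous when its two
#' called allele indices differ (multi-allelic genotypes such as 1/2
#' count as heterozygous). He is an exact ratio of integers.
#'
#' @param table a multi-sample `vcf_table`.
#' @param populations optional sample-to-population assignment: a named
#'   character vector or a path to a two-column headerless TSV (sample,
#'   population). Samples without an entry get the default label `"all"`.
#' @return a `diversity_summary`: data.frame with columns `sample`,
#'   `population`, `n_het`, `n_shared`, `he`.
#' @export
heterozygosity <- function(table, populations = NULL) {
  stopifnot(inherits(table, "vcf_table"))
  if (is.character(populations) && length(populations) == 1L &&
      is.null(names(populations)) && file.exists(populations)) {
    df <- utils::read.table(populations, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
    populations <- stats::setNames(df[[2L]], df[[1L]])
  }
  ok <- rep(TRUE, nrow(table$fix))
  het <- matrix(FALSE, nrow(table$fix), length(table$sample_names))
  for (s in seq_along(table$sample_names)) {
    g <- parse_gt(table$gt[, s])
    ok <- ok & g$called & g$ploidy == 2L
    het[, s] <- !is.na(g$a1) & !is.na(g$a2) & g$a1 != g$a2
  }
  n_shared <- sum(ok)
  if (n_shared == 0L) {
    stop("no locus is called in every sample; average heterozygosity is ",
         "undefined (He = n_het / n_shared would divide by zero)")
  }
  pop <- rep("all", length(table$sample_names))
  if (!is.null(populations)) {
    hit <- table$sample_names %in% names(populations)
    pop[hit] <- unname(populations[table$sample_names[hit]])
  }
  n_het <- colSums(het[ok, , drop = FALSE])
  out <- data.frame(sample = table$sample_names, population = pop,
                    n_het = as.integer(n_het), n_shared = n_shared,
                    he = as.integer(n_het) / n_shared,
                    stringsAsFactors = FALSE)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

format_he <- function(he) sprintf("%.15f", he)

utils::globalVariables(c("sample", "he", "highlight"))

diversity_table_df <- function(summary) {
  data.frame(ID = summary$sample,
             Heterozygosity = format_he(summary$he),
             Population = summary$population,
             stringsAsFactors = FALSE)
}

he_barchart <- function(summary, labels = FALSE, highlight = NULL,
                        title = "Heterozygosity per population") {
  df <- as.data.frame(summary)
  df$sample <- factor(df$sample, levels = df$sample)
  df$highlight <- if (is.null(highlight)) FALSE else df$sample == highlight
  p <- ggplot2::ggplot(df, ggplot2::aes(x = sample, y = he,
                                        fill = highlight)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "#D55E00")) +
    ggplot2::facet_grid(. ~ population, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "Heterozygosity (He)", title = title) +
    ggplot2::theme_minimal()
  if (!labels) {
    p <- p + ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }
  p
}

#' Write diversity tables and bar charts
#'
#' Writes the per-population table (ID, Heterozygosity to 15 decimals,
#' Population) and four bar-chart variants: (A) unannotated, (B) all
#' samples labeled, (C) the sample of interest highlighted, (D) the
#' maximum-He sample highlighted (ties broken by table order, noted in
#' the log). A sub-folder per sample holds that sample's table and the
#' graphs. File paths are printed instead of opening a browser.
#'
#' @param summary a `diversity_summary`.
#' @param sample_of_interest sample highlighted in chart C (default: the
#'   first sample).
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
diversity_outputs <- function(summary, sample_of_interest = NULL, out_dir) {
  stopifnot(inherits(summary, "diversity_summary"))
  if (is.null(sample_of_interest)) {
    sample_of_interest <- summary$sample[1L]
  } else if (!sample_of_interest %in% summary$sample) {
    stop("unknown sample_of_interest '", sample_of_interest,
         "'; samples: ", paste(summary$sample, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tab_path <- file.path(out_dir, "diversity_population.tsv")
  utils::write.table(diversity_table_df(summary), tab_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, tab_path)
  max_i <- which(summary$he == max(summary$he))
  if (length(max_i) > 1L) {
    message("tie for maximum heterozygosity between samples ",
            paste(summary$sample[max_i], collapse = ", "),
            "; highlighting the first in table order")
  }
  max_sample <- summary$sample[max_i[1L]]
  charts <- list(
    he_overview.png = he_barchart(summary, labels = FALSE),
    he_annotated.png = he_barchart(summary, labels = TRUE),
    he_sample_of_interest.png = he_barchart(summary, labels = TRUE,
                                            highlight = sample_of_interest),
    he_maximum.png = he_barchart(summary, labels = TRUE,
                                 highlight = max_sample))
  for (nm in names(charts)) {
    path <- file.path(out_dir, nm)
    ggplot2::ggsave(path, charts[[nm]], width = 6, height = 4, dpi = 96)
    files <- c(files, path)
  }
  for (s in summary$sample) {
    sdir <- file.path(out_dir, s)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    srow <- summary[summary$sample == s, , drop = FALSE]
    spath <- file.path(sdir, "diversity.tsv")
    utils::write.table(diversity_table_df(srow), spath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, spath)
    for (nm in names(charts)) {
      dest <- file.path(sdir, nm)
      file.copy(file.path(out_dir, nm), dest, overwrite = TRUE)
      files <- c(files, dest)
    }
  }
  message("diversity outputs written under ", normalizePath(out_dir))
  invisible(files)
}
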