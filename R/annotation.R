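#' @title Transcript annotation from BED12
#' @description Build transcript/exon models from a UCSC-table-browser-style
#'   BED12 file and localize genomic positions in exons and introns for
#'   clinical reporting.
#' @name annotation
NULL

bed12_fields <- c("chrom", "chromStart", "chromEnd", "name", "score",
                  "strand", "thickStart", "thickEnd", "itemRgb",
                  "blockCount", "blockSizes", "blockStarts")

split_ints <- function(x) {
  as.integer(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1L]])
}

#' Build transcript annotation from a BED12 file
#'
#' Each BED12 line becomes one transcript. Blocks are converted from the
#' BED 0-based half-open convention to 1-based inclusive exon intervals:
#' `exon_start = chromStart + blockStart + 1`,
#' `exon_end = exon_start + blockSize - 1`. The gene symbol is looked up in
#' `gene_map` (transcript id -> gene) when given, otherwise the BED `name`
#' field is used for both.
#'
#' @param bed_path path to a BED12 file (no header; UCSC table-browser
#'   export). Extra leading columns (e.g. a `bin` column) can be skipped
#'   with `skip_cols`.
#' @param gene_map optional transcript-to-gene table: a named character
#'   vector or a path to a two-column headerless TSV (transcript, gene).
#' @param skip_cols number of leading columns to ignore before the 12 BED
#'   fields (default 0).
#' @return list of `transcript_annotation` objects, each with
#'   `transcript_id`, `gene`, `chrom`, `strand`, `exons` (matrix with
#'   columns start/end, 1-based inclusive, sorted by genomic start) and
#'   `span` (c(start, end)).
#' @export
build_annotation <- function(bed_path, gene_map = NULL, skip_cols = 0L) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  if (is.character(gene_map) && length(gene_map) == 1L &&
      is.null(names(gene_map)) && file.exists(gene_map)) {
    gm <- utils::read.table(gene_map, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "")
    gene_map <- stats::setNames(gm[[2L]], gm[[1L]])
  }
  lines <- readLines(bed_path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "track") &
    !startsWith(lines, "browser") & !startsWith(lines, "#")
  out <- vector("list", sum(keep))
  j <- 0L
  for (ln in which(keep)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (skip_cols > 0L) f <- f[-seq_len(skip_cols)]
    if (length(f) < 12L) {
      stop("BED12 parse error at line ", ln, " of '", bed_path,
           "': expected 12 fields, found ", length(f))
    }
    chrom <- f[1L]
    chrom_start <- as.integer(f[2L])
    chrom_end <- as.integer(f[3L])
    name <- f[4L]
    strand <- f[6L]
    if (!strand %in% c("+", "-")) {
      stop("BED12 parse error at line ", ln, ": strand must be '+' or '-', ",
           "found '", strand, "'")
    }
    block_count <- as.integer(f[10L])
    sizes <- split_ints(f[11L])
    starts <- split_ints(f[12L])
    if (length(sizes) != block_count || length(starts) != block_count) {
      stop("BED12 parse error at line ", ln, ": blockCount is ",
           block_count, " but blockSizes/blockStarts have ",
           length(sizes), "/", length(starts), " entries")
    }
    exon_start <- chrom_start + starts + 1L
    exon_end <- exon_start + sizes - 1L
    if (any(exon_end > chrom_end)) {
      stop("BED12 parse error at line ", ln, ": block(s) extend past ",
           "chromEnd (", chrom_end, ")")
    }
    if (starts[1L] != 0L || exon_end[block_count] != chrom_end) {
      stop("BED12 parse error at line ", ln, ": blocks must start at ",
           "chromStart and end at chromEnd")
    }
    ord <- order(exon_start)
    exons <- cbind(start = exon_start[ord], end = exon_end[ord])
    if (block_count > 1L && any(exons[-1L, "start"] <= exons[-block_count, "end"])) {
      stop("BED12 parse error at line ", ln, ": overlapping blocks")
    }
    gene <- if (!is.null(gene_map) && name %in% names(gene_map))
      unname(gene_map[name]) else name
    j <- j + 1L
    out[[j]] <- structure(
      list(transcript_id = name, gene = gene, chrom = chrom,
           strand = strand, exons = exons,
           span = c(exons[1L, "start"], exons[block_count, "end"])),
      class = "transcript_annotation")
  }
  out
}

#' Localize a genomic position within transcripts
#'
#' For every transcript on `chrom` whose span contains `pos`, reports the
#' region as an exon or intron index in transcription order: on the `-`
#' strand exon 1 is the genomically last exon, and an intron takes the
#' index of the exon preceding it in transcription order. Transcripts not
#' containing the position are omitted; an empty result means the position
#' lies outside every transcript.
#'
#' @param annotations list of `transcript_annotation` from
#'   [build_annotation()].
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @return data.frame with columns `transcript_id`, `gene`, `region`
#'   (`"exon"` or `"intron"`) and `k` (1-based index in transcription
#'   order); zero rows if no transcript overlaps.
#' @export
locate_position <- function(annotations, chrom, pos) {
  stopifnot(pos >= 1)
  hits <- list()
  for (tx in annotations) {
    if (tx$chrom != chrom || pos < tx$span[1L] || pos > tx$span[2L]) next
    n <- nrow(tx$exons)
    in_exon <- which(pos >= tx$exons[, "start"] & pos <= tx$exons[, "end"])
    if (length(in_exon)) {
      genomic_k <- in_exon[1L]
      k <- if (tx$strand == "+") genomic_k else n - genomic_k + 1L
      region <- "exon"
    } else {
      # genomic index of the exon immediately left of pos
      left <- max(which(tx$exons[, "end"] < pos))
      k <- if (tx$strand == "+") left else n - left
      region <- "intron"
    }
    hits[[length(hits) + 1L]] <- data.frame(
      transcript_id = tx$transcript_id, gene = tx$gene,
      region = region, k = k, stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(transcript_id = character(0), gene = character(0),
                  region = character(0), k = integer(0),
                  stringsAsFactors = FALSE)
}

format_locations <- function(loc) {
  if (nrow(loc) == 0L) return("outside transcripts")
  paste(sprintf("%s:%s %d", loc$transcript_id, loc$region, loc$k),
        collapse = "; ")
}
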