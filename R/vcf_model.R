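#' Parse a genotype (GT) string
#'
#' Splits VCF GT strings such as `"0/1"`, `"1|0"`, `"."` or `"./1"` into
#' allele indices. Separators `/` and `|` are treated identically (phase is
#' recorded but unused downstream). A genotype with any missing index —
#' including half-calls like `"./1"` — is a no-call. Haploid genotypes
#' (single index, e.g. chrY or mitochondria) have `ploidy == 1` and a
#' missing second index.
#'
#' @param gt character vector of GT subfield strings (`NA` treated as `"./."`).
#' @return data.frame with columns `a1`, `a2` (integer allele indices,
#'   `NA` when missing), `ploidy` (1 or 2), `phased` and `called` (logical;
#'   `called` is `TRUE` only when every index of the genotype is present).
#' @export
parse_gt <- function(gt) {
  gt <- as.character(gt)
  gt[is.na(gt) | gt == ""] <- "./."
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")
  n_tok <- lengths(parts)
  if (any(n_tok > 2)) {
    stop("unsupported ploidy (>2) in genotype(s): ",
         paste(unique(gt[n_tok > 2]), collapse = ", "))
  }
  tok1 <- vapply(parts, `[`, character(1), 1L)
  tok2 <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1))
  a1 <- suppressWarnings(as.integer(ifelse(tok1 == ".", NA, tok1)))
  a2 <- suppressWarnings(as.integer(ifelse(is.na(tok2) | tok2 == ".", NA, tok2)))
  ploidy <- ifelse(n_tok == 1L, 1L, 2L)
  called <- !is.na(a1) & (ploidy == 1L | !is.na(a2))
  data.frame(a1 = a1, a2 = a2, ploidy = ploidy, phased = phased,
             called = called)
}

read_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

validate_vcf_lines <- function(lines, path) {
  if (length(lines) == 0L) {
    stop("VCF parse error in '", path, "': file is empty")
  }
  if (!startsWith(lines[1L], "##fileformat=VCF")) {
    stop("VCF parse error in '", path,
         "': first line must be a '##fileformat=VCF' meta line, found: ",
         substr(lines[1L], 1, 60))
  }
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) == 0L) {
    first_bad <- which(!startsWith(lines, "##"))[1L]
    stop("VCF parse error in '", path, "': no '#CHROM' header line",
         if (!is.na(first_bad))
           paste0("; first non-meta line is line ", first_bad, ": ",
                  substr(lines[first_bad], 1, 60)))
  }
  hdr <- hdr[1L]
  if (any(!startsWith(lines[seq_len(hdr - 1L)], "##"))) {
    bad <- which(!startsWith(lines[seq_len(hdr - 1L)], "##"))[1L]
    stop("VCF parse error in '", path, "': line ", bad,
         " precedes the #CHROM header but is not a '##' meta line")
  }
  n_fields_hdr <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  data_idx <- if (hdr < length(lines)) seq(hdr + 1L, length(lines)) else integer(0)
  data_idx <- data_idx[nzchar(lines[data_idx])]
  n_fields <- vapply(strsplit(lines[data_idx], "\t", fixed = TRUE),
                     length, integer(1))
  bad <- data_idx[n_fields != n_fields_hdr]
  if (length(bad)) {
    stop("VCF parse error in '", path, "': line ", bad[1L], " has ",
         n_fields[match(bad[1L], data_idx)], " fields but the header has ",
         n_fields_hdr)
  }
  list(n_meta = hdr - 1L, n_header = 1L, n_data = length(data_idx),
       n_columns = n_fields_hdr)
}

#' Read a VCF file into a table
#'
#' Parses a VCF v4.x file (plain or gzipped) into a `vcf_table`: the fixed
#' site columns, the GT subfield per sample, and the file attributes (number
#' of meta lines, header lines, variants and columns). Parsing is backed by
#' \pkg{vcfR}; a pre-validation pass reports malformed headers and data
#' lines with their line numbers. Only CHROM/POS/ID/REF/ALT/QUAL/FILTER and
#' the GT subfield are modeled; INFO and other FORMAT subfields are ignored.
#' Record order is kept exactly as in the file.
#'
#' @param path path to a VCF file.
#' @param verbose print the file attributes to the console (default `TRUE`,
#'   mirroring the on-load summary a clinician sees).
#' @return a `vcf_table`: list with `sample_names`, `fix` (data.frame with
#'   columns chrom, pos, id, ref, alt, qual, filter), `gt` (character matrix
#'   of GT strings, variants x samples) and `attributes`.
#' @export
read_vcf <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- read_vcf_lines(path)
  counts <- validate_vcf_lines(lines, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    fix <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), qual = character(0),
                      filter = character(0), stringsAsFactors = FALSE)
  } else {
    fix <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = ifelse(is.na(fix$ID), ".", fix$ID),
                      ref = fix$REF, alt = ifelse(is.na(fix$ALT), "", fix$ALT),
                      qual = ifelse(is.na(fix$QUAL), ".", fix$QUAL),
                      filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
                      stringsAsFactors = FALSE)
  }
  if (ncol(v@gt) > 1L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt[is.na(gt)] <- "./."
    sample_names <- colnames(v@gt)[-1L]
    colnames(gt) <- sample_names
  } else {
    sample_names <- character(0)
    gt <- matrix(character(0), nrow = nrow(fix), ncol = 0L)
  }
  if (anyDuplicated(sample_names)) {
    stop("VCF parse error in '", path, "': duplicated sample names: ",
         paste(unique(sample_names[duplicated(sample_names)]), collapse = ", "))
  }
  out <- structure(
    list(sample_names = sample_names, fix = fix, gt = gt,
         attributes = list(n_meta_lines = counts$n_meta,
                           n_header_lines = counts$n_header,
                           n_variants = counts$n_data,
                           n_columns = counts$n_columns)),
    class = "vcf_table")
  if (verbose) print(out)
  out
}

#' @export
print.vcf_table <- function(x, ...) {
  a <- x$attributes
  cat("VCF file attributes\n")
  cat("  meta lines:   ", a$n_meta_lines, "\n", sep = "")
  cat("  header lines: ", a$n_header_lines, "\n", sep = "")
  cat("  variants:     ", a$n_variants, "\n", sep = "")
  cat("  columns:      ", a$n_columns, "\n", sep = "")
  cat("  samples:      ", if (length(x$sample_names))
    paste(x$sample_names, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}

#' Number of variant records in a `vcf_table`
#' @param table a `vcf_table`.
#' @return integer count of records.
#' @export
n_variants <- function(table) nrow(table$fix)

#' Read a chromosome-name map
#'
#' Two-column headerless TSV: source name, target name. The map must be
#' injective (no two sources mapping to the same target).
#'
#' @param path path to the TSV file.
#' @return named character vector (names = source, values = target).
#' @export
read_chrom_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("chromosome map '", path, "' must have two columns")
  map <- stats::setNames(df[[2L]], df[[1L]])
  check_chrom_map(map)
  map
}

check_chrom_map <- function(map) {
  if (length(map) == 0L) stop("chromosome map is empty")
  if (anyDuplicated(names(map)))
    stop("chromosome map has duplicated source names: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "))
  if (anyDuplicated(map))
    stop("chromosome map is not injective; duplicated targets: ",
         paste(unique(map[duplicated(map)]), collapse = ", "))
  invisible(map)
}

#' Harmonize chromosome names in a VCF table
#'
#' Renames every record whose chromosome is a source name of `map` to the
#' mapped target (e.g. `"1"` to `"chr1"`). Records whose chromosome is not
#' in the map are left untouched and their names are returned, deduplicated
#' in first-seen order — a report, not an error. Record order is preserved.
#'
#' @param table a `vcf_table`.
#' @param map named character vector (source -> target) or path to a
#'   two-column TSV readable by [read_chrom_map()].
#' @return list with elements `table` (the renamed `vcf_table`) and
#'   `unmapped` (character vector of chromosome names not covered by the map).
#' @export
rename_chromosomes <- function(table, map) {
  stopifnot(inherits(table, "vcf_table"))
  if (is.character(map) && is.null(names(map)) && length(map) == 1L &&
      file.exists(map)) {
    map <- read_chrom_map(map)
  }
  check_chrom_map(map)
  chrom <- table$fix$chrom
  hit <- chrom %in% names(map)
  table$fix$chrom[hit] <- unname(map[chrom[hit]])
  unmapped <- unique(chrom[!hit])
  list(table = table, unmapped = unmapped)
}

#' Extract a single-sample view of a VCF table
#'
#' Keeps all records — including those where the sample is homozygous
#' reference or has no call, which the homozygous-reference report table
#' needs. Extraction is idempotent.
#'
#' @param table a `vcf_table`.
#' @param sample_name one of `table$sample_names`.
#' @return a one-sample `vcf_table` with the same records.
#' @export
extract_sample <- function(table, sample_name) {
  stopifnot(inherits(table, "vcf_table"))
  if (!sample_name %in% table$sample_names) {
    stop("unknown sample '", sample_name, "'; available samples: ",
         paste(table$sample_names, collapse = ", "))
  }
  table$gt <- table$gt[, sample_name, drop = FALSE]
  table$sample_names <- sample_name
  table$attributes$n_columns <- 9L + 1L
  table
}

#' Write a `vcf_table` to a VCF file
#'
#' Minimal writer used by the fixture generator: `##fileformat` meta line,
#' optional `##contig` lines, `#CHROM` header, and data rows with a GT-only
#' FORMAT. Output is deterministic (no timestamps).
#'
#' @param table a `vcf_table`.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for
#'   `##contig` meta lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, contigs = NULL) {
  stopifnot(inherits(table, "vcf_table"))
  meta <- "##fileformat=VCFv4.2"
  if (!is.null(contigs)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(contigs), as.integer(contigs)))
  }
  meta <- c(meta, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", table$sample_names), collapse = "\t")
  fx <- table$fix
  if (nrow(fx)) {
    rows <- paste(fx$chrom, fx$pos, fx$id, fx$ref, fx$alt, fx$qual,
                  fx$filter, ".", "GT", sep = "\t")
    if (ncol(table$gt)) {
      gt_cols <- apply(table$gt, 1L, paste, collapse = "\t")
      rows <- paste(rows, gt_cols, sep = "\t")
    }
  } else {
    rows <- character(0)
  }
  writeLines(c(meta, header, rows), path)
  invisible(path)
}
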