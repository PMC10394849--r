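#' @title Variants-of-interest catalogue
#' @description Parsing and quality control of the catalogue of known
#'   phenotype-associated variants (VOI) that a sample is screened against.
#' @name voi
NULL

canonical_voi_cols <- c("chrom", "pos", "gene", "ref_allele", "var_allele",
                        "inheritance", "phenotype", "breeds", "assembly",
                        "species")

# header synonyms accepted in USER mode when no explicit column_map is given
user_header_synonyms <- list(
  chrom = c("chrom", "chromosome", "chr"),
  pos = c("pos", "position", "location"),
  gene = c("gene", "gene_symbol"),
  ref_allele = c("ref_allele", "ref", "reference", "reference_allele"),
  var_allele = c("var_allele", "var", "alt", "variant", "variant_allele",
                 "alt_allele"),
  inheritance = c("inheritance", "inheritance_pattern", "mode_of_inheritance"),
  phenotype = c("phenotype", "phene", "disease"),
  breeds = c("breeds", "breed"),
  assembly = c("assembly", "genome_assembly", "genome", "reference_genome"),
  species = c("species")
)

inheritance_levels <- c("AUTOSOMAL_DOMINANT", "AUTOSOMAL_RECESSIVE",
                        "MITOCHONDRIAL", "X_LINKED_DOMINANT",
                        "X_LINKED_RECESSIVE", "Y_LINKED", "UNKNOWN")

#' Parse inheritance-pattern labels
#'
#' Maps free-text labels ("Autosomal recessive", "X-linked dominant", ...)
#' to the canonical codes. Blank or unrecognized entries become `UNKNOWN`,
#' which downstream triggers the "not able to provide breeding advice" rows
#' of the advice tables.
#'
#' @param x character vector of labels.
#' @return character vector of canonical codes.
#' @export
parse_inheritance <- function(x) {
  key <- gsub("[^a-z]+", " ", tolower(trimws(as.character(x))))
  key <- trimws(gsub(" +", " ", key))
  out <- rep("UNKNOWN", length(key))
  out[key %in% c("autosomal dominant", "ad")] <- "AUTOSOMAL_DOMINANT"
  out[key %in% c("autosomal recessive", "ar")] <- "AUTOSOMAL_RECESSIVE"
  out[key %in% c("mitochondrial", "mt")] <- "MITOCHONDRIAL"
  out[key %in% c("x linked dominant", "xld")] <- "X_LINKED_DOMINANT"
  out[key %in% c("x linked recessive", "xlr")] <- "X_LINKED_RECESSIVE"
  out[key %in% c("y linked", "yl")] <- "Y_LINKED"
  out
}

parse_pos <- function(x) {
  x <- gsub("[ ,]", "", as.character(x))
  suppressWarnings(as.integer(x))
}

voi_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

omia_header_map <- function() {
  path <- system.file("extdata", "omia_header_map.tsv", package = "vcfscreen")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  stats::setNames(df$canonical, df$source_header)
}

#' Parse a variants-of-interest file
#'
#' Reads a delimited VOI catalogue and adapts it to the canonical schema
#' (chrom, pos, gene, ref_allele, var_allele, inheritance, phenotype,
#' breeds, assembly, species). With `source = "OMIA"` a packaged header
#' preset maps the OMIA export dialect automatically; with
#' `source = "USER"` headers are matched case-insensitively against common
#' synonyms, or explicitly via `column_map`. Unrecognized columns are kept
#' unchanged as opaque extras. The breeds cell is split on `breed_delim`
#' into a list of breed names.
#'
#' @param path path to a TSV/CSV file with a header row.
#' @param source `"USER"` (default) or `"OMIA"`.
#' @param column_map optional named character vector mapping canonical
#'   field names to the file's column names, e.g.
#'   `c(chrom = "CHR", pos = "BP")`. Overrides synonym matching.
#' @param delimiter field delimiter; default sniffed from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param breed_delim delimiter separating breed names inside a cell
#'   (default `";"`).
#' @return a `voi_table`: data.frame with the canonical columns (breeds as
#'   a list column), `inheritance` as canonical codes, `source_row`
#'   (1-based input row), and any extra columns appended.
#' @export
parse_voi <- function(path, source = c("USER", "OMIA"), column_map = NULL,
                      delimiter = NULL, breed_delim = ";") {
  source <- match.arg(source)
  if (!file.exists(path)) stop("VOI file not found: ", path)
  raw <- utils::read.table(path, sep = voi_delimiter(path, delimiter),
                           header = TRUE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           check.names = FALSE, na.strings = character(0))
  if (source == "OMIA") {
    preset <- omia_header_map()
    hit <- names(preset) %in% names(raw)
    if (!any(hit)) {
      stop("none of the expected OMIA headers (",
           paste(names(preset)[seq_len(min(6L, length(preset)))],
                 collapse = ", "),
           ", ...) were found in '", path,
           "'; if this is a user-defined file, use source = \"USER\" with ",
           "an explicit column_map")
    }
    preset <- preset[hit]
    # first match wins per canonical field
    preset <- preset[!duplicated(preset)]
    column_map <- stats::setNames(names(preset), preset)
  }
  resolved <- character(0)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical_voi_cols)
    if (length(bad)) stop("column_map has unknown canonical fields: ",
                          paste(bad, collapse = ", "))
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      stop("column_map refers to columns absent from '", path, "': ",
           paste(missing_src, collapse = ", "))
    }
    resolved <- column_map
  } else {
    lower <- tolower(trimws(names(raw)))
    for (canon in names(user_header_synonyms)) {
      i <- which(lower %in% user_header_synonyms[[canon]])
      if (length(i)) resolved[canon] <- names(raw)[i[1L]]
    }
  }
  required <- c("chrom", "pos", "gene")
  absent <- setdiff(required, names(resolved))
  if (length(absent)) {
    stop("VOI file '", path, "' is missing required field(s) after column ",
         "mapping: ", paste(absent, collapse = ", "))
  }
  n <- nrow(raw)
  blank_to_na <- function(x) { x <- trimws(x); x[x == ""] <- NA; x }
  get_col <- function(canon) {
    if (canon %in% names(resolved)) blank_to_na(raw[[resolved[canon]]])
    else rep(NA_character_, n)
  }
  breeds_raw <- get_col("breeds")
  breeds <- lapply(breeds_raw, function(cell) {
    if (is.na(cell)) character(0)
    else trimws(strsplit(cell, breed_delim, fixed = TRUE)[[1L]])
  })
  out <- data.frame(chrom = get_col("chrom"),
                    pos = parse_pos(get_col("pos")),
                    gene = get_col("gene"),
                    ref_allele = get_col("ref_allele"),
                    var_allele = get_col("var_allele"),
                    inheritance = parse_inheritance(get_col("inheritance")),
                    phenotype = get_col("phenotype"),
                    assembly = get_col("assembly"),
                    species = get_col("species"),
                    source_row = seq_len(n),
                    stringsAsFactors = FALSE)
  out$breeds <- breeds
  extras <- setdiff(names(raw), unname(resolved))
  for (e in extras) out[[paste0("extra.", e)]] <- raw[[e]]
  class(out) <- c("voi_table", "data.frame")
  out
}

fasta_handle <- function(reference) {
  if (is.character(reference)) {
    seqs <- Biostrings::readDNAStringSet(reference)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs
  } else {
    reference
  }
}

#' Quality control of a variants-of-interest table
#'
#' Three optional checks, mirroring what a diagnostic lab needs before
#' filtering: (1) rows missing the chromosome, position, gene or genome
#' assembly are dropped; (2) if `assembly` is given, rows recorded against
#' a different assembly are excluded (variants mapped to another genome
#' version must not be used for position matching); (3) if `reference` is
#' given, the reference base at each retained position is compared
#' (case-insensitively) with the first base of the row's `ref_allele` —
#' indel REF strings start with the anchor base. Mismatching rows are
#' retained and flagged in the `ref_mismatch` column, never silently
#' dropped: the user is asked to manually check those locations. Rows on
#' chromosomes absent from the reference are reported as unverifiable.
#'
#' @param voi a `voi_table` from [parse_voi()].
#' @param assembly optional assembly label to keep (compared after
#'   trimming and case folding; no alias table).
#' @param reference optional reference genome: path to a FASTA file or a
#'   `Biostrings::DNAStringSet`.
#' @return list with `voi` (the clean `voi_table`, input order preserved,
#'   with a `ref_mismatch` logical column) and `report` (a
#'   `voi_qc_report`: n_input, dropped_incomplete, excluded_assembly,
#'   mismatched_reference, unverifiable, n_retained).
#' @export
qc_voi <- function(voi, assembly = NULL, reference = NULL) {
  stopifnot(inherits(voi, "voi_table"))
  n_input <- nrow(voi)
  incomplete <- is.na(voi$chrom) | is.na(voi$pos) | is.na(voi$gene) |
    is.na(voi$assembly)
  keep <- !incomplete
  excluded <- rep(FALSE, n_input)
  if (!is.null(assembly)) {
    norm <- function(x) tolower(trimws(x))
    excluded <- keep & norm(voi$assembly) != norm(assembly)
    keep <- keep & !excluded
  }
  clean <- voi[keep, , drop = FALSE]
  clean$ref_mismatch <- FALSE
  mism <- data.frame(source_row = integer(0), expected = character(0),
                     found = character(0), stringsAsFactors = FALSE)
  unverifiable <- integer(0)
  if (!is.null(reference) && nrow(clean)) {
    ref <- fasta_handle(reference)
    for (i in seq_len(nrow(clean))) {
      ra <- clean$ref_allele[i]
      if (is.na(ra) || !nzchar(ra)) next
      chrom <- clean$chrom[i]
      if (!chrom %in% names(ref) ||
          clean$pos[i] > Biostrings::width(ref[chrom])) {
        unverifiable <- c(unverifiable, clean$source_row[i])
        next
      }
      found <- toupper(as.character(
        Biostrings::subseq(ref[[chrom]], clean$pos[i], clean$pos[i])))
      expected <- toupper(substr(ra, 1L, 1L))
      if (found != expected) {
        clean$ref_mismatch[i] <- TRUE
        mism <- rbind(mism, data.frame(source_row = clean$source_row[i],
                                       expected = expected, found = found,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  report <- structure(
    list(n_input = n_input,
         dropped_incomplete = voi$source_row[incomplete],
         excluded_assembly = voi$source_row[excluded],
         mismatched_reference = mism,
         unverifiable = unverifiable,
         n_retained = nrow(clean)),
    class = "voi_qc_report")
  stopifnot(report$n_retained ==
              n_input - length(report$dropped_incomplete) -
              length(report$excluded_assembly))
  list(voi = clean, report = report)
}

#' @export
print.voi_qc_report <- function(x, ...) {
  cat("VOI quality-control report\n")
  cat("  input rows:            ", x$n_input, "\n", sep = "")
  cat("  dropped (incomplete):  ", length(x$dropped_incomplete),
      if (length(x$dropped_incomplete))
        paste0(" [rows ", paste(x$dropped_incomplete, collapse = ", "), "]"),
      "\n", sep = "")
  cat("  excluded (assembly):   ", length(x$excluded_assembly),
      if (length(x$excluded_assembly))
        paste0(" [rows ", paste(x$excluded_assembly, collapse = ", "), "]"),
      "\n", sep = "")
  cat("  reference mismatches:  ", nrow(x$mismatched_reference),
      " (retained and flagged; please check these locations manually)\n",
      sep = "")
  if (nrow(x$mismatched_reference)) {
    for (i in seq_len(nrow(x$mismatched_reference))) {
      m <- x$mismatched_reference[i, ]
      cat("    row ", m$source_row, ": expected ", m$expected,
          ", reference has ", m$found, "\n", sep = "")
    }
  }
  if (length(x$unverifiable)) {
    cat("  unverifiable rows (chromosome not in reference): ",
        paste(x$unverifiable, collapse = ", "), "\n", sep = "")
  }
  cat("  retained:              ", x$n_retained, "\n", sep = "")
  invisible(x)
}

#' Write a VOI QC report as TSV
#' @param report a `voi_qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "voi_qc_report"))
  rows <- data.frame(
    check = c("input", "dropped_incomplete", "excluded_assembly",
              "mismatched_reference", "unverifiable", "retained"),
    count = c(report$n_input, length(report$dropped_incomplete),
              length(report$excluded_assembly),
              nrow(report$mismatched_reference),
              length(report$unverifiable), report$n_retained),
    rows = c("", paste(report$dropped_incomplete, collapse = ","),
             paste(report$excluded_assembly, collapse = ","),
             paste(report$mismatched_reference$source_row, collapse = ","),
             paste(report$unverifiable, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
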