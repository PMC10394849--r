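#' @title Standardized HTML/TSV reports
#' @description Serializes screening and diversity results into five
#'   standardized HTML tables plus a combined self-contained report, with
#'   machine-readable TSV mirrors of every table.
#' @name report
NULL

inheritance_display <- c(
  AUTOSOMAL_DOMINANT = "Autosomal dominant",
  AUTOSOMAL_RECESSIVE = "Autosomal recessive",
  MITOCHONDRIAL = "Mitochondrial",
  X_LINKED_DOMINANT = "X linked dominant",
  X_LINKED_RECESSIVE = "X linked recessive",
  Y_LINKED = "Y linked",
  UNKNOWN = "NA"
)

#' Human-readable inheritance label
#' @param inheritance canonical inheritance code(s).
#' @return character vector of display labels.
#' @export
inheritance_label <- function(inheritance) {
  out <- unname(inheritance_display[inheritance])
  out[is.na(out)] <- "NA"
  out
}

status_display <- c(CALLED = "Called",
                    MISSING_GT = "No call in this sample",
                    ABSENT_FROM_VCF = "Locus absent from the VCF")

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

variant_display_df <- function(rows) {
  if (nrow(rows) == 0L) return(NULL)
  data.frame(
    Chromosome = sub("^chr", "", rows$chrom),
    Location = formatC(rows$pos, big.mark = ",", format = "d"),
    Gene = rows$gene,
    Reference = rows$ref_allele,
    `Allele 1` = rows$allele_1,
    `Allele 2` = rows$allele_2,
    Zygosity = zygosity_label(rows$zygosity),
    Inheritance = inheritance_label(rows$inheritance),
    Phenotype = ifelse(is.na(rows$phenotype), "", rows$phenotype),
    Status = unname(status_display[rows$locus_status]),
    Annotation = rows$annotation,
    `Allele mismatch` = ifelse(rows$allele_mismatch, "yes", ""),
    check.names = FALSE, stringsAsFactors = FALSE)
}

variant_display_cols <- c("Chromosome", "Location", "Gene", "Reference",
                          "Allele 1", "Allele 2", "Zygosity", "Inheritance",
                          "Phenotype", "Status", "Annotation",
                          "Allele mismatch")

advice_display_df <- function(rows) {
  if (nrow(rows) == 0L) return(NULL)
  data.frame(
    Chromosome = sub("^chr", "", rows$chrom),
    Location = formatC(rows$pos, big.mark = ",", format = "d"),
    Gene = rows$gene,
    Zygosity = zygosity_label(rows$zygosity),
    `Inheritance pattern` = inheritance_label(rows$inheritance),
    `Breeding advice` = rows$advice,
    check.names = FALSE, stringsAsFactors = FALSE)
}

advice_display_cols <- c("Chromosome", "Location", "Gene", "Zygosity",
                         "Inheritance pattern", "Breeding advice")

html_table <- function(df, cols, caption, id = "tbl") {
  head_cells <- paste0("<th onclick=\"sortTable(this)\">",
                       html_escape(cols), "</th>", collapse = "")
  if (is.null(df) || nrow(df) == 0L) {
    body <- paste0("<tr><td colspan=\"", length(cols),
                   "\" class=\"placeholder\">No variants</td></tr>")
  } else {
    body <- paste(vapply(seq_len(nrow(df)), function(i) {
      cells <- vapply(cols, function(cn)
        paste0("<td>", html_escape(as.character(df[i, cn])), "</td>"),
        character(1))
      paste0("<tr>", paste(cells, collapse = ""), "</tr>")
    }, character(1)), collapse = "\n")
  }
  paste0("<h2>", html_escape(caption), "</h2>\n",
         "<table id=\"", id, "\" class=\"report\">\n<thead><tr>",
         head_cells, "</tr></thead>\n<tbody>\n", body,
         "\n</tbody>\n</table>")
}

report_css <- paste(
  "body{font-family:sans-serif;margin:2em;}",
  "table.report{border-collapse:collapse;margin-bottom:2em;}",
  "table.report th,table.report td{border:1px solid #999;",
  "padding:4px 8px;text-align:left;}",
  "table.report th{background:#eee;cursor:pointer;}",
  "td.placeholder{font-style:italic;color:#666;}",
  ".note{font-size:0.9em;color:#444;max-width:60em;}", sep = "\n")

report_js <- paste(
  "function sortTable(th){",
  "var table=th.closest('table');var tbody=table.tBodies[0];",
  "var idx=Array.prototype.indexOf.call(th.parentNode.children,th);",
  "var rows=Array.prototype.slice.call(tbody.rows);",
  "var dir=th.dataset.dir==='asc'?-1:1;th.dataset.dir=dir===1?'asc':'desc';",
  "rows.sort(function(a,b){",
  "var x=a.cells[idx].textContent,y=b.cells[idx].textContent;",
  "var nx=parseFloat(x.replace(/,/g,'')),ny=parseFloat(y.replace(/,/g,''));",
  "if(!isNaN(nx)&&!isNaN(ny))return dir*(nx-ny);",
  "return dir*x.localeCompare(y);});",
  "rows.forEach(function(r){tbody.appendChild(r);});}", sep = "\n")

html_page <- function(title, body, metadata = NULL) {
  meta_html <- if (!is.null(metadata)) {
    items <- vapply(names(metadata), function(k)
      paste0("<li><b>", html_escape(k), ":</b> ",
             html_escape(as.character(metadata[[k]])), "</li>"),
      character(1))
    paste0("<div class=\"note\"><ul>", paste(items, collapse = ""),
           "</ul></div>\n")
  } else ""
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>",
         html_escape(title), "</title>\n<style>", report_css,
         "</style>\n<script>", report_js, "</script></head>\n<body>\n<h1>",
         html_escape(title), "</h1>\n", meta_html, body,
         "\n</body></html>\n")
}

write_tsv_mirror <- function(df, cols, path) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols),
      check.names = FALSE)
  }
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Render the standardized screening report
#'
#' Writes the five report tables — `priority`, `other_breed`, `hom_ref`,
#' `advice_hom`, `advice_het` — each as a raw HTML file plus a TSV mirror,
#' and a combined self-contained HTML report (`report.html`) with
#' client-side table sorting. Every table always renders its full column
#' set; an empty table gets a "No variants" placeholder row. A diversity
#' summary, when supplied, is appended to the combined report and mirrored
#' as TSV. TSV bodies are a pure function of the inputs (byte-identical
#' across runs); the run timestamp appears only in the combined report's
#' metadata block.
#'
#' @param result a `filter_result` from [filter_variants()].
#' @param diversity optional `diversity_summary` from [heterozygosity()].
#' @param out_dir output directory (created if needed; must be writable —
#'   checked before any file is produced).
#' @param metadata optional named list added to the combined report's
#'   metadata block (e.g. input file digests, sex annotation).
#' @return a `report_bundle`: list with `files` (named character vector of
#'   paths) and `metadata`, invisibly.
#' @export
render_report <- function(result, diversity = NULL, out_dir,
                          metadata = list()) {
  stopifnot(inherits(result, "filter_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L) {
    stop("output directory '", out_dir, "' is not writable; no report ",
         "files were produced")
  }
  meta <- c(list(sample = result$sample_name,
                 breed = if (nzchar(result$breed)) result$breed else
                   "unspecified",
                 tool = paste0("vcfscreen ",
                               utils::packageVersion("vcfscreen")),
                 generated = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
            metadata)
  tables <- list(
    priority = list(
      df = variant_display_df(result$priority), cols = variant_display_cols,
      caption = paste0("Priority: variants found in the sample and known ",
                       "to segregate in the breed"),
      note = NULL),
    other_breed = list(
      df = variant_display_df(result$other_breed),
      cols = variant_display_cols,
      caption = paste0("Variants found in the sample but not known to ",
                       "segregate in the breed (genotype-phenotype ",
                       "associations can be breed-specific)"),
      note = NULL),
    hom_ref = list(
      df = variant_display_df(result$hom_ref), cols = variant_display_cols,
      caption = paste0("Variants for which the sample is homozygous ",
                       "reference (relevant for mate selection)"),
      note = NULL),
    advice_hom = list(
      df = advice_display_df(result$advice_hom), cols = advice_display_cols,
      caption = "Breeding advice for variants found in a homozygous state",
      note = advice_side_note()),
    advice_het = list(
      df = advice_display_df(result$advice_het), cols = advice_display_cols,
      caption = "Breeding advice for variants found in a heterozygous state",
      note = advice_heteroplasmy_note())
  )
  files <- character(0)
  sections <- character(0)
  for (nm in names(tables)) {
    t <- tables[[nm]]
    section <- html_table(t$df, t$cols, t$caption, id = nm)
    if (!is.null(t$note)) {
      section <- paste0(section, "\n<p class=\"note\">",
                        html_escape(t$note), "</p>")
    }
    html_path <- file.path(out_dir, paste0(nm, ".html"))
    writeLines(html_page(t$caption, section), html_path)
    tsv_path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_mirror(t$df, t$cols, tsv_path)
    files[paste0(nm, ".html")] <- html_path
    files[paste0(nm, ".tsv")] <- tsv_path
    sections <- c(sections, section)
  }
  if (!is.null(diversity)) {
    stopifnot(inherits(diversity, "diversity_summary"))
    ddf <- diversity_table_df(diversity)
    sections <- c(sections,
                  html_table(ddf, names(ddf),
                             "Diversity: average heterozygosity per sample",
                             id = "diversity"))
    dpath <- file.path(out_dir, "diversity.tsv")
    write_tsv_mirror(ddf, names(ddf), dpath)
    files["diversity.tsv"] <- dpath
  }
  combined <- file.path(out_dir, "report.html")
  writeLines(html_page(
    paste0("Variant screening report - sample ", result$sample_name),
    paste(sections, collapse = "\n"), metadata = meta), combined)
  files["report.html"] <- combined
  message("report written: ", combined)
  invisible(structure(list(files = files, metadata = meta),
                      class = "report_bundle"))
}

#' Write the extra-variants table (HTML + TSV)
#'
#' Serializes the output of [extra_filter()] in the same style as the main
#' report tables.
#'
#' @param extra data.frame from [extra_filter()].
#' @param out_dir output directory.
#' @return named character vector of file paths, invisibly.
#' @export
write_extra_report <- function(extra, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("Chromosome", "Location", "Gene", "Reference", "Allele 1",
            "Allele 2", "Zygosity", "Annotation")
  df <- if (nrow(extra)) data.frame(
    Chromosome = sub("^chr", "", extra$chrom),
    Location = formatC(extra$pos, big.mark = ",", format = "d"),
    Gene = extra$gene, Reference = extra$ref_allele,
    `Allele 1` = extra$allele_1, `Allele 2` = extra$allele_2,
    Zygosity = zygosity_label(extra$zygosity),
    Annotation = extra$annotation,
    check.names = FALSE, stringsAsFactors = FALSE) else NULL
  caption <- "Other variants present in the genes of interest"
  html_path <- file.path(out_dir, "extra.html")
  writeLines(html_page(caption, html_table(df, cols, caption, id = "extra")),
             html_path)
  tsv_path <- file.path(out_dir, "extra.tsv")
  write_tsv_mirror(df, cols, tsv_path)
  skipped <- attr(extra, "skipped_genes")
  if (length(skipped)) {
    message("genes without transcript annotation were skipped: ",
            paste(skipped, collapse = ", "))
  }
  invisible(c(extra.html = html_path, extra.tsv = tsv_path))
}
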