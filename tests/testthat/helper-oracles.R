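# Test helpers: in-code construction of tiny VCF tables and independent
# brute-force oracles that re-derive expected values without touching the
# package's own parsing/counting code paths.

# build a vcf_table directly (no file round trip)
make_vcf <- function(chrom, pos, ref, alt, gt, samples = NULL) {
  gt <- as.matrix(gt)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(gt)))
  colnames(gt) <- samples
  structure(
    list(sample_names = samples,
         fix = data.frame(chrom = chrom, pos = as.integer(pos), id = ".",
                          ref = ref, alt = alt, qual = ".", filter = "PASS",
                          stringsAsFactors = FALSE),
         gt = gt,
         attributes = list(n_meta_lines = 2L, n_header_lines = 1L,
                           n_variants = length(pos),
                           n_columns = 9L + ncol(gt))),
    class = "vcf_table")
}

# build a voi_table directly
make_voi <- function(chrom, pos, gene, ref_allele = NA, var_allele = NA,
                     inheritance = "AUTOSOMAL_RECESSIVE",
                     phenotype = "phen", breeds = "Labrador retriever",
                     assembly = "canFam3") {
  n <- length(pos)
  out <- data.frame(chrom = chrom, pos = as.integer(pos), gene = gene,
                    ref_allele = rep_len(ref_allele, n),
                    var_allele = rep_len(var_allele, n),
                    inheritance = rep_len(inheritance, n),
                    phenotype = rep_len(phenotype, n),
                    assembly = rep_len(assembly, n), species = "dog",
                    source_row = seq_len(n), stringsAsFactors = FALSE)
  out$breeds <- lapply(rep_len(breeds, n), function(b)
    trimws(strsplit(b, ";", fixed = TRUE)[[1]]))
  class(out) <- c("voi_table", "data.frame")
  out
}

# independent re-parse of a written VCF: per-sample diversity counts
# (string splitting only, no package code)
oracle_diversity <- function(vcf_path) {
  lines <- readLines(vcf_path)
  data_lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  n_samples <- length(fields[[1]]) - 9L
  gt <- t(vapply(fields, function(f) sub(":.*$", "", f[10:(9 + n_samples)]),
                 character(n_samples)))
  gt <- matrix(gt, ncol = n_samples)
  split2 <- function(g) strsplit(g, "[/|]")
  called_diploid <- apply(gt, 2, function(col) {
    vapply(split2(col), function(p)
      length(p) == 2L && !any(p == "."), logical(1))
  })
  shared <- rowSums(matrix(called_diploid, ncol = n_samples)) == n_samples
  het <- apply(gt, 2, function(col) {
    vapply(split2(col), function(p)
      length(p) == 2L && !any(p == ".") && p[1] != p[2], logical(1))
  })
  het <- matrix(het, ncol = n_samples)
  list(n_shared = sum(shared),
       n_het = colSums(het[shared, , drop = FALSE]),
       he = colSums(het[shared, , drop = FALSE]) / sum(shared))
}

# independent locate oracle: walk the exons in TRANSCRIPTION order and
# label each position of the span from that walk
oracle_locate <- function(tx, pos) {
  ex <- tx$exons
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  ex <- ex[ord, , drop = FALSE]
  for (j in seq_len(nrow(ex))) {
    if (pos >= ex[j, "start"] && pos <= ex[j, "end"])
      return(list(region = "exon", k = j))
  }
  for (j in seq_len(nrow(ex) - 1L)) {
    gap <- sort(c(ex[j, ], ex[j + 1L, ]))
    if (pos > gap[2] && pos < gap[3]) return(list(region = "intron", k = j))
  }
  list(region = "outside", k = NA_integer_)
}

# independent exon-sum oracle straight from a BED12 line's blockSizes
bed_block_sum <- function(bed_line) {
  f <- strsplit(bed_line, "\t", fixed = TRUE)[[1]]
  sum(as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]]))
}
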