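#' @title Deterministic synthetic fixtures
#' @description Generates coherent VCF + VOI + BED12 + reference-FASTA
#'   bundles with known ground truth, so the whole screening workflow can
#'   be exercised and tested without any download. Genotypes are
#'   independent per-locus-per-sample draws (no linkage or population
#'   structure); identical spec + seed produces byte-identical files.
#' @name fixtures
NULL

#' Specification of a synthetic fixture bundle
#'
#' @param seed integer seed; the only source of randomness.
#' @param n_samples number of samples in the VCF (>= 1).
#' @param n_loci number of variant records (>= 1).
#' @param missing_rate per-genotype probability of a `./.` no-call, in
#'   \[0, 1).
#' @param het_rate probability that a called genotype is heterozygous.
#' @param n_voi number of catalogue rows drawn from the generated loci
#'   (<= n_loci).
#' @param n_breed_match how many VOI rows carry the matching breed
#'   (<= n_voi).
#' @param n_incomplete planted catalogue rows with a missing position
#'   (dropped by QC).
#' @param n_wrong_assembly planted rows recorded against a different
#'   assembly (excluded by QC).
#' @param n_ref_mismatch VOI rows whose reference allele is corrupted so
#'   it disagrees with the reference FASTA (flagged by QC).
#' @param n_chrom number of synthetic contigs.
#' @param contig_length length of each contig in bp (<= 100 kb).
#' @param assembly assembly label written on valid rows.
#' @param breed breed carried by matching VOI rows.
#' @param other_breed breed carried by the remaining rows.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_samples = 4L, n_loci = 50L,
                         missing_rate = 0.1, het_rate = 0.3,
                         n_voi = 8L, n_breed_match = 4L,
                         n_incomplete = 0L, n_wrong_assembly = 0L,
                         n_ref_mismatch = 0L, n_chrom = 3L,
                         contig_length = 60000L,
                         assembly = "canFam3",
                         breed = "Labrador retriever",
                         other_breed = "Golden Retriever") {
  spec <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
               n_loci = as.integer(n_loci), missing_rate = missing_rate,
               het_rate = het_rate, n_voi = as.integer(n_voi),
               n_breed_match = as.integer(n_breed_match),
               n_incomplete = as.integer(n_incomplete),
               n_wrong_assembly = as.integer(n_wrong_assembly),
               n_ref_mismatch = as.integer(n_ref_mismatch),
               n_chrom = as.integer(n_chrom),
               contig_length = as.integer(contig_length),
               assembly = assembly, breed = breed,
               other_breed = other_breed)
  with(spec, {
    if (n_samples < 1L || n_loci < 1L) stop("n_samples and n_loci must be >= 1")
    if (n_voi > n_loci) stop("inconsistent fixture spec: n_voi > n_loci")
    if (n_breed_match > n_voi) stop("inconsistent spec: n_breed_match > n_voi")
    if (n_ref_mismatch > n_voi) stop("inconsistent spec: n_ref_mismatch > n_voi")
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate outside [0, 1)")
    if (contig_length > 100000L) stop("contig_length must be <= 100 kb")
  })
  structure(spec, class = "fixture_spec")
}

inheritance_cycle <- c("Autosomal recessive", "Autosomal dominant",
                       "X linked recessive", "Mitochondrial",
                       "X linked dominant", "Y linked")

other_base <- function(base) {
  c(A = "G", C = "T", G = "A", T = "C")[[base]]
}

#' Generate a synthetic fixture bundle with known truth
#'
#' Writes a multi-sample VCF, a canonical-schema VOI TSV (with planted QC
#' defects when requested), a BED12 transcript file covering each VOI
#' gene, a reference FASTA (+ .fai index), and a chromosome-name map TSV.
#' The ground truth — shared-locus count, per-sample heterozygosity,
#' filter partition sizes for the first sample, QC defect counts, and the
#' extra-variant count — is computed by direct bookkeeping during
#' generation, before any parser runs.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return list with `files` (named paths), `truth` and `spec`.
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  contig_names <- paste0("chr", seq_len(spec$n_chrom))
  contigs <- stats::setNames(rep(spec$contig_length, spec$n_chrom),
                             contig_names)
  seqs <- vapply(contig_names, function(cn)
    paste(sample(bases, spec$contig_length, replace = TRUE), collapse = ""),
    character(1))

  # loci: sorted by contig then position, unique positions per contig
  chrom_idx <- sort(sample(spec$n_chrom, spec$n_loci, replace = TRUE))
  pos <- integer(spec$n_loci)
  for (ci in unique(chrom_idx)) {
    sel <- chrom_idx == ci
    pos[sel] <- sort(sample(seq(1000L, spec$contig_length - 1000L),
                            sum(sel)))
  }
  chrom <- contig_names[chrom_idx]
  ref <- substr(seqs[chrom_idx], pos, pos)
  alt <- vapply(ref, other_base, character(1))

  # genotypes: independent draws, per locus per sample
  gt <- matrix("", spec$n_loci, spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    u <- stats::runif(spec$n_loci)
    v <- stats::runif(spec$n_loci)
    w <- stats::runif(spec$n_loci)
    gt[, s] <- ifelse(u < spec$missing_rate, "./.",
                      ifelse(v < spec$het_rate, "0/1",
                             ifelse(w < 0.5, "0/0", "1/1")))
  }
  sample_names <- paste0("dog", seq_len(spec$n_samples))

  # truth: diversity
  shared <- rowSums(gt == "./.") == 0L
  n_shared <- sum(shared)
  n_het <- colSums(gt[shared, , drop = FALSE] == "0/1")
  he <- if (n_shared > 0L) n_het / n_shared else rep(NA_real_, spec$n_samples)

  # VOI rows drawn from the loci
  voi_idx <- sort(sample(spec$n_loci, spec$n_voi))
  voi_breed <- c(rep(spec$breed, spec$n_breed_match),
                 rep(spec$other_breed, spec$n_voi - spec$n_breed_match))
  voi_gene <- paste0("GENE", seq_len(spec$n_voi))
  voi_ref <- ref[voi_idx]
  mism_rows <- if (spec$n_ref_mismatch > 0L)
    sort(sample(spec$n_voi, spec$n_ref_mismatch)) else integer(0)
  voi_ref[mism_rows] <- vapply(voi_ref[mism_rows], other_base, character(1))
  voi <- data.frame(
    chrom = chrom[voi_idx], pos = pos[voi_idx], gene = voi_gene,
    ref_allele = voi_ref, var_allele = alt[voi_idx],
    inheritance = rep_len(inheritance_cycle, spec$n_voi),
    phenotype = paste0("Phenotype ", seq_len(spec$n_voi)),
    breeds = voi_breed, assembly = spec$assembly, species = "dog",
    stringsAsFactors = FALSE)
  # planted defects: incomplete rows (blank position) and wrong assembly
  defect <- function(n, gene_prefix, assembly, blank_pos) {
    if (n == 0L) return(NULL)
    data.frame(chrom = rep(contig_names[1L], n),
               pos = if (blank_pos) rep("", n)
                     else as.character(sample(seq(1000L, 2000L), n)),
               gene = paste0(gene_prefix, seq_len(n)),
               ref_allele = "A", var_allele = "G",
               inheritance = "Autosomal recessive",
               phenotype = paste0(gene_prefix, " phenotype"),
               breeds = spec$breed, assembly = assembly, species = "dog",
               stringsAsFactors = FALSE)
  }
  voi_out <- voi
  voi_out$pos <- as.character(voi_out$pos)
  voi_out <- rbind(voi_out,
                   defect(spec$n_incomplete, "INCGENE", spec$assembly, TRUE),
                   defect(spec$n_wrong_assembly, "ASMGENE",
                          paste0(spec$assembly, "_other"), FALSE))

  # BED12: one 3-exon transcript per VOI gene; the locus sits at the end
  # of exon 2 (chromStart = pos - 350; blocks 100/200/100 at 0/150/600)
  bed <- vapply(seq_len(spec$n_voi), function(i) {
    cs <- pos[voi_idx[i]] - 350L
    ce <- cs + 700L
    paste(chrom[voi_idx[i]], cs, ce, paste0(voi_gene[i], ".t1"), 0L,
          if (i %% 2L == 0L) "-" else "+", cs, ce, "0", 3L,
          "100,200,100", "0,150,600", sep = "\t")
  }, character(1))

  # truth: extra_filter counts gene-locus pairs of non-VOI records inside
  # a gene span
  span_start <- pos[voi_idx] - 349L
  span_end <- pos[voi_idx] + 350L
  n_extra <- 0L
  for (i in seq_len(spec$n_voi)) {
    inside <- chrom == chrom[voi_idx[i]] & pos >= span_start[i] &
      pos <= span_end[i] & !(seq_len(spec$n_loci) %in% voi_idx)
    n_extra <- n_extra + sum(inside)
  }

  # truth: filter partition for sample 1 against spec$breed
  gt1 <- gt[voi_idx, 1L]
  is_nocall <- gt1 == "./."
  is_homref <- gt1 == "0/0"
  match_breed <- voi_breed == spec$breed
  truth_partition <- list(
    priority = sum((is_nocall | !is_homref & !is_nocall) & match_breed),
    other_breed = sum((is_nocall | !is_homref & !is_nocall) & !match_breed),
    hom_ref = sum(is_homref),
    n_no_call = sum(is_nocall))

  files <- list(
    vcf = file.path(out_dir, "fixture.vcf"),
    voi = file.path(out_dir, "voi.tsv"),
    bed = file.path(out_dir, "annotation.bed"),
    fasta = file.path(out_dir, "reference.fa"),
    chrom_map = file.path(out_dir, "chrom_map.tsv"),
    gene_map = file.path(out_dir, "gene_map.tsv"))

  vcf <- structure(
    list(sample_names = sample_names,
         fix = data.frame(chrom = chrom, pos = pos, id = ".", ref = ref,
                          alt = alt, qual = ".", filter = "PASS",
                          stringsAsFactors = FALSE),
         gt = matrix(gt, spec$n_loci, spec$n_samples,
                     dimnames = list(NULL, sample_names)),
         attributes = list(n_meta_lines = 2L + spec$n_chrom,
                           n_header_lines = 1L,
                           n_variants = spec$n_loci,
                           n_columns = 9L + spec$n_samples)),
    class = "vcf_table")
  write_vcf(vcf, files$vcf, contigs = contigs)
  utils::write.table(voi_out, files$voi, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(bed, files$bed)
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- contig_names
  Biostrings::writeXStringSet(dna, files$fasta, width = 70L)
  Rsamtools::indexFa(files$fasta)
  writeLines(paste(seq_len(spec$n_chrom), contig_names, sep = "\t"),
             files$chrom_map)
  writeLines(paste(paste0(voi_gene, ".t1"), voi_gene, sep = "\t"),
             files$gene_map)

  truth <- list(
    n_shared = n_shared,
    n_het = stats::setNames(as.integer(n_het), sample_names),
    he = stats::setNames(he, sample_names),
    partition = truth_partition,
    qc = list(n_incomplete = spec$n_incomplete,
              n_wrong_assembly = spec$n_wrong_assembly,
              n_ref_mismatch = length(mism_rows),
              mismatch_source_rows = mism_rows),
    n_extra = n_extra,
    n_clean_voi = spec$n_voi)
  list(files = files, truth = truth, spec = spec)
}

#' Worked example: screening a yellow Labrador retriever
#'
#' Writes the bundled worked example: a one-sample VCF (`dog1`) with five
#' genotyped sites, the matching five-row catalogue — three variants with
#' an established association in the Labrador retriever (COL11A2 skeletal
#' dysplasia 2, MC1R red/yellow coat, ATP7A Menkes disease) and two
#' recorded for other breeds (FGF5 long hair, whose genotype is a
#' no-call, and a second MC1R site) — plus a minimal BED12 with one or
#' two transcripts per gene and a transcript-to-gene map. Genomic
#' coordinates follow the canine canFam3 assembly.
#'
#' @param out_dir output directory (created if needed).
#' @return named list of file paths (`vcf`, `voi`, `bed`, `gene_map`).
#' @export
labrador_example <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sites <- data.frame(
    chrom = c("chr3", "chr5", "chr5", "chr12", "chrX"),
    pos = c(24509367L, 63694334L, 63694460L, 22652874L, 60279238L),
    ref = c("G", "G", "C", "C", "C"),
    alt = c("A", "A", "T", "G", "T"),
    gt = c("./.", "1/1", "1/1", "0/1", "0/1"),
    stringsAsFactors = FALSE)
  vcf <- structure(
    list(sample_names = "dog1",
         fix = data.frame(chrom = sites$chrom, pos = sites$pos, id = ".",
                          ref = sites$ref, alt = sites$alt, qual = ".",
                          filter = "PASS", stringsAsFactors = FALSE),
         gt = matrix(sites$gt, ncol = 1L, dimnames = list(NULL, "dog1")),
         attributes = list(n_meta_lines = 6L, n_header_lines = 1L,
                           n_variants = 5L, n_columns = 10L)),
    class = "vcf_table")
  contigs <- c(chr3 = 24600000L, chr5 = 63800000L, chr12 = 22700000L,
               chrX = 60400000L)
  files <- list(vcf = file.path(out_dir, "dog1.vcf"),
                voi = file.path(out_dir, "voi.tsv"),
                bed = file.path(out_dir, "annotation.bed"),
                gene_map = file.path(out_dir, "gene_map.tsv"))
  write_vcf(vcf, files$vcf, contigs = contigs)
  voi <- data.frame(
    chrom = c("chr12", "chr5", "chrX", "chr3", "chr5"),
    pos = c(22652874L, 63694334L, 60279238L, 24509367L, 63694460L),
    gene = c("COL11A2", "MC1R", "ATP7A", "FGF5", "MC1R"),
    ref_allele = c("C", "G", "C", "G", "C"),
    var_allele = c("G", "A", "T", "A", "T"),
    inheritance = c("Autosomal recessive", "Autosomal recessive",
                    "X linked recessive", "Autosomal recessive",
                    "Autosomal dominant"),
    phenotype = c("Skeletal dysplasia 2", "Red/yellow coat",
                  "Menkes disease", "Long hair", "Black melanistic mask"),
    breeds = c("Labrador retriever", "Labrador retriever",
               "Labrador retriever", "Golden Retriever",
               "Golden Retriever"),
    assembly = "canFam3", species = "dog", stringsAsFactors = FALSE)
  utils::write.table(voi, files$voi, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tx_line <- function(chrom, pos, name, strand, offset = 350L) {
    cs <- pos - offset
    ce <- cs + 700L
    paste(chrom, cs, ce, name, 0L, strand, cs, ce, "0", 3L,
          "100,200,100", "0,150,600", sep = "\t")
  }
  bed <- c(
    tx_line("chr12", 22652874L, "COL11A2.t1", "+"),
    tx_line("chr12", 22652874L, "COL11A2.t2", "+", offset = 250L),
    tx_line("chr5", 63694334L, "MC1R.t1", "-"),
    tx_line("chrX", 60279238L, "ATP7A.t1", "+"),
    tx_line("chr3", 24509367L, "FGF5.t1", "-"))
  writeLines(bed, files$bed)
  writeLines(paste(c("COL11A2.t1", "COL11A2.t2", "MC1R.t1", "ATP7A.t1",
                     "FGF5.t1"),
                   c("COL11A2", "COL11A2", "MC1R", "ATP7A", "FGF5"),
                   sep = "\t"), files$gene_map)
  files
}
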