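test_that("call_zygosity resolves allele strings and classes", {
  cases <- list(
    # ref, alt, gt, zygosity, allele_1, allele_2
    list("C", "G", "0/1", "HET", "C", "G"),
    list("G", "A", "1/1", "HOM_NONREF", "A", "A"),
    list("C", "T", "0/0", "HOM_REF", "C", "C"),
    list("A", "G,T", "1/2", "HET", "G", "T"),
    list("A", "G", "1", "HEMI_NONREF", "G", NA_character_),
    list("A", "G", "0", "HEMI_REF", "A", NA_character_))
  for (cs in cases) {
    z <- call_zygosity(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(z$zygosity, cs[[4]])
    expect_equal(z$allele_1, cs[[5]])
    expect_equal(z$allele_2, cs[[6]])
  }
  nc <- call_zygosity("G", "A", "./.")
  expect_equal(nc$zygosity, "NO_CALL")
  expect_equal(nc$allele_1,
               "A call could not be made for this sample at this given locus")
  expect_equal(nc$allele_2, no_call_text())
  half <- call_zygosity("G", "A", "./1")
  expect_equal(half$zygosity, "NO_CALL")
  expect_error(call_zygosity("G", "A", "0/2", context = "chr1:5 sample x"),
               "out of range.*chr1:5")
})

test_that("call_zygosity is symmetric in allele order", {
  a <- call_zygosity("C", "G", "0/1")
  b <- call_zygosity("C", "G", "1/0")
  expect_equal(a, b)
})

test_that("breeding advice is total and verbatim", {
  patterns <- c("AUTOSOMAL_DOMINANT", "AUTOSOMAL_RECESSIVE", "MITOCHONDRIAL",
                "X_LINKED_DOMINANT", "X_LINKED_RECESSIVE", "Y_LINKED",
                "UNKNOWN")
  for (p in patterns) {
    for (cls in c("HOMOZYGOUS", "HETEROZYGOUS")) {
      txt <- breeding_advice(p, cls)
      expect_true(is.character(txt) && length(txt) == 1 && nzchar(txt))
    }
  }
  expect_match(breeding_advice("AUTOSOMAL_RECESSIVE", "HOMOZYGOUS"),
               "^ONLY combine with wild type animal!")
  expect_equal(breeding_advice("AUTOSOMAL_DOMINANT", "HETEROZYGOUS"),
               "Animal can NOT be used for breeding purposes")
  expect_equal(breeding_advice("UNKNOWN", "HETEROZYGOUS"),
               paste("Not able to provide breeding advice because",
                     "inheritance pattern was not included in the input file"))
  # Y-linked homozygous-class advice reuses the only printed Y-linked text
  expect_equal(breeding_advice("Y_LINKED", "HOMOZYGOUS"),
               breeding_advice("Y_LINKED", "HETEROZYGOUS"))
})

test_that("filter_variants partitions every VOI locus exactly once and
           never hides a no-call", {
  v <- make_vcf(chrom = rep("chr1", 4), pos = c(10, 20, 30, 40),
                ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
                gt = matrix(c("0/1", "0/0", "./.", "1/1"), 4, 1),
                samples = "dog1")
  voi <- make_voi(chrom = rep("chr1", 5), pos = c(10, 20, 30, 40, 99),
                  gene = paste0("G", 1:5),
                  breeds = c("Labrador retriever", "Labrador retriever",
                             "Beagle", "Beagle", "Labrador retriever"))
  res <- filter_variants(v, voi, breed = "Labrador retriever")
  expect_equal(nrow(res$priority) + nrow(res$other_breed) + nrow(res$hom_ref),
               nrow(voi))
  # locus absent from the VCF surfaces as a no-call, never dropped
  absent <- res$priority[res$priority$pos == 99, ]
  expect_equal(absent$locus_status, "ABSENT_FROM_VCF")
  expect_equal(absent$allele_1, no_call_text())
  missing_gt <- res$other_breed[res$other_breed$pos == 30, ]
  expect_equal(missing_gt$locus_status, "MISSING_GT")
  expect_equal(missing_gt$zygosity, "NO_CALL")
  expect_equal(missing_gt$allele_2, no_call_text())
  # hom-ref goes to the hom_ref table regardless of breed
  expect_equal(res$hom_ref$pos, 20L)
  expect_equal(res$priority$pos, c(10L, 99L))
  expect_equal(res$other_breed$pos, c(30L, 40L))
})

test_that("breed routing is case-insensitive and moves rows without
           changing zygosity or totals", {
  v <- make_vcf(rep("chr1", 3), c(10, 20, 30), c("A", "C", "G"),
                c("G", "T", "A"), matrix(c("0/1", "1/1", "0/1"), 3, 1),
                samples = "dog1")
  voi <- make_voi(rep("chr1", 3), c(10, 20, 30), paste0("G", 1:3),
                  breeds = "  labrador   RETRIEVER ")
  a <- filter_variants(v, voi, breed = "Labrador retriever")
  b <- filter_variants(v, voi, breed = "Poodle")
  expect_equal(nrow(a$priority), 3L)
  expect_equal(nrow(b$priority), 0L)
  expect_equal(nrow(b$other_breed), 3L)
  expect_equal(sort(a$priority$zygosity), sort(b$other_breed$zygosity))
  total_a <- nrow(a$priority) + nrow(a$other_breed) + nrow(a$hom_ref)
  total_b <- nrow(b$priority) + nrow(b$other_breed) + nrow(b$hom_ref)
  expect_equal(total_a, total_b)
})

test_that("blank breed warns and routes non-reference rows to other_breed;
           empty VOI and nomenclature mismatches are errors", {
  v <- make_vcf("chr1", 10, "A", "G", matrix("0/1", 1, 1), samples = "dog1")
  voi <- make_voi("chr1", 10, "G1")
  expect_warning(res <- filter_variants(v, voi, breed = ""), "no breed")
  expect_equal(nrow(res$other_breed), 1L)
  expect_error(filter_variants(v, voi[0, ], breed = "x"), "empty")
  voi_chr <- make_voi("1", 10, "G1")
  expect_error(filter_variants(v, voi_chr, breed = "x"), "nomenclature")
})

test_that("advice tables cover exactly the non-reference rows, with the
           homozygous class for hemizygous calls", {
  v <- make_vcf(rep("chr1", 4), c(10, 20, 30, 40), c("A", "C", "G", "T"),
                c("G", "T", "A", "C"),
                matrix(c("0/1", "1/1", "1", "0/0"), 4, 1), samples = "dog1")
  voi <- make_voi(rep("chr1", 4), c(10, 20, 30, 40), paste0("G", 1:4),
                  inheritance = c("AUTOSOMAL_RECESSIVE", "AUTOSOMAL_DOMINANT",
                                  "Y_LINKED", "AUTOSOMAL_RECESSIVE"))
  res <- filter_variants(v, voi, breed = "Labrador retriever")
  expect_equal(sort(res$advice_hom$pos), c(20L, 30L))   # hom + hemi non-ref
  expect_equal(res$advice_het$pos, 10L)
  expect_equal(res$advice_hom$advice[res$advice_hom$pos == 20],
               breeding_advice("AUTOSOMAL_DOMINANT", "HOMOZYGOUS"))
  expect_equal(res$advice_het$advice,
               breeding_advice("AUTOSOMAL_RECESSIVE", "HETEROZYGOUS"))
})

test_that("a VOI reference allele disagreeing with the VCF REF is flagged
           but does not change routing", {
  v <- make_vcf("chr1", 10, "A", "G", matrix("0/1", 1, 1), samples = "dog1")
  voi <- make_voi("chr1", 10, "G1", ref_allele = "C")
  res <- filter_variants(v, voi, breed = "Labrador retriever")
  expect_true(res$priority$allele_mismatch)
  expect_equal(res$priority$zygosity, "HET")
})

test_that("extra_filter collects non-VOI variants inside VOI gene spans", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t230\tG1.t1\t0\t+\t100\t230\t0\t2\t50,30\t0,100", bed)
  gm <- withr::local_tempfile(fileext = ".tsv")
  writeLines("G1.t1\tG1", gm)
  ann <- build_annotation(bed, gene_map = gm)
  v <- make_vcf(rep("chr1", 3), c(120, 150, 500), c("A", "C", "G"),
                c("G", "T", "A"), matrix(c("0/1", "1/1", "0/1"), 3, 1),
                samples = "dog1")
  voi <- make_voi("chr1", 150, "G1")
  ex <- extra_filter(v, voi, ann)
  expect_equal(ex$pos, 120L)  # VOI locus 150 excluded, 500 outside the span
  expect_equal(ex$zygosity, "HET")
  expect_match(ex$annotation, "exon 1")
  # genes without annotation are reported as skipped
  voi2 <- make_voi(c("chr1", "chr1"), c(150, 500), c("G1", "G9"))
  ex2 <- extra_filter(v, voi2, ann)
  expect_equal(attr(ex2, "skipped_genes"), "G9")
  # planted fixture count agrees with generation-time bookkeeping
  for (seed in c(2, 8)) {
    d <- withr::local_tempdir()
    fx <- generate_fixtures(fixture_spec(seed = seed, n_loci = 80,
                                         n_voi = 10), d)
    vcf <- read_vcf(fx$files$vcf, verbose = FALSE)
    voi_fx <- qc_voi(parse_voi(fx$files$voi), assembly = "canFam3")$voi
    ann_fx <- build_annotation(fx$files$bed, gene_map = fx$files$gene_map)
    got <- extra_filter(extract_sample(vcf, "dog1"), voi_fx, ann_fx)
    expect_equal(nrow(got), fx$truth$n_extra)
  }
})
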