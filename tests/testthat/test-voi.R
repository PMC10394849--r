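write_user_voi <- function(path, rows) {
  writeLines(c("chrom\tpos\tgene\tref_allele\tvar_allele\tinheritance\tphenotype\tbreed\tassembly",
               rows), path)
}

test_that("parse_voi reads a user file into the canonical schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_user_voi(path, c(
    "chr1\t100\tGENE1\tA\tG\tAutosomal recessive\tphen A\tLabrador Retriever; Golden Retriever\tcanFam3",
    "chr2\t2,500\tGENE2\tC\tT\t\tphen B\tBeagle\tcanFam3",
    "chr3\t300\tGENE3\tG\tA\tX-linked dominant\tphen C\t\tcanFam3"))
  voi <- parse_voi(path)
  expect_s3_class(voi, "voi_table")
  expect_equal(nrow(voi), 3L)
  expect_equal(voi$pos, c(100L, 2500L, 300L))  # commas stripped
  expect_equal(voi$breeds[[1]], c("Labrador Retriever", "Golden Retriever"))
  expect_equal(voi$breeds[[3]], character(0))
  expect_equal(voi$inheritance,
               c("AUTOSOMAL_RECESSIVE", "UNKNOWN", "X_LINKED_DOMINANT"))
})

test_that("parse_voi errors name the missing fields and wrong dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "1\t2"), path)
  expect_error(parse_voi(path), "chrom.*pos.*gene")
  expect_error(parse_voi(path, source = "OMIA"), "USER.*column_map")
})

test_that("OMIA dialect is adapted via the packaged header preset", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Chr.,Position,Gene,Inheritance,Phenotype(s),Breed(s),Genome assembly,OMIA ID",
               "29,4000000,CLN5,Autosomal recessive,Neuronal ceroid lipofuscinosis,Border Collie,canFam3,001482"),
             path)
  voi <- parse_voi(path, source = "OMIA")
  expect_equal(voi$chrom, "29")
  expect_equal(voi$pos, 4000000L)
  expect_equal(voi$gene, "CLN5")
  expect_equal(voi$inheritance, "AUTOSOMAL_RECESSIVE")
  expect_equal(voi$`extra.OMIA ID`, "001482")  # opaque extras preserved
})

test_that("parse_voi is the identity on an already-canonical file", {
  d <- withr::local_tempdir()
  fx <- generate_fixtures(fixture_spec(seed = 3, n_voi = 5), d)
  a <- parse_voi(fx$files$voi)
  b <- parse_voi(fx$files$voi,
                 column_map = stats::setNames(
                   c("chrom", "pos", "gene", "ref_allele", "var_allele",
                     "inheritance", "phenotype", "breeds", "assembly",
                     "species"),
                   c("chrom", "pos", "gene", "ref_allele", "var_allele",
                     "inheritance", "phenotype", "breeds", "assembly",
                     "species")))
  expect_equal(a, b)
})

test_that("qc_voi drops incomplete rows, excludes other assemblies, flags
           reference mismatches, and is idempotent", {
  for (seed in c(1, 5, 12)) {
    d <- withr::local_tempdir()
    fx <- generate_fixtures(fixture_spec(
      seed = seed, n_voi = 6, n_incomplete = 2, n_wrong_assembly = 3,
      n_ref_mismatch = 2), d)
    voi <- parse_voi(fx$files$voi)
    qc <- qc_voi(voi, assembly = "canFam3", reference = fx$files$fasta)
    expect_length(qc$report$dropped_incomplete, 2L)
    expect_length(qc$report$excluded_assembly, 3L)
    expect_equal(nrow(qc$report$mismatched_reference), 2L)
    expect_equal(qc$report$mismatched_reference$source_row,
                 fx$truth$qc$mismatch_source_rows)
    expect_equal(qc$report$n_retained, 6L)
    # mismatched rows retained and flagged, not dropped
    expect_equal(sum(qc$voi$ref_mismatch), 2L)
    expect_true(all(qc$report$mismatched_reference$source_row %in%
                      qc$voi$source_row))
    # idempotent: second pass drops nothing and returns the same table
    qc2 <- qc_voi(qc$voi, assembly = "canFam3", reference = fx$files$fasta)
    expect_length(qc2$report$dropped_incomplete, 0L)
    expect_length(qc2$report$excluded_assembly, 0L)
    expect_equal(qc2$voi, qc$voi)
  }
})

test_that("qc_voi reports unverifiable rows and assembly comparison folds
           case and whitespace", {
  voi <- make_voi(c("chrUn", "chr1"), c(10, 20), c("G1", "G2"),
                  ref_allele = "A", assembly = c(" CanFam3 ", "canFam4"))
  ref <- Biostrings::DNAStringSet(c(chr1 = "AAAAAAAAAAAAAAAAAAAAAAAAA"))
  qc <- qc_voi(voi, assembly = "canfam3", reference = ref)
  expect_equal(qc$report$excluded_assembly, 2L)  # canFam4 != canfam3
  expect_equal(qc$report$unverifiable, 1L)       # chrUn not in reference
  expect_equal(qc$report$n_retained, 1L)
})
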