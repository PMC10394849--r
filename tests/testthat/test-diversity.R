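test_that("shared loci are those called (diploid) in every sample", {
  gt <- cbind(c("0/1", "0/0", "1/1"), c("0/1", "./.", "0/1"))
  v <- make_vcf(rep("chr1", 3), c(10, 20, 30), rep("A", 3), rep("G", 3), gt)
  shared <- shared_called_loci(v)
  expect_equal(shared$pos, c(10L, 30L))
  # no missingness: every locus is shared
  v2 <- make_vcf(rep("chr1", 3), c(10, 20, 30), rep("A", 3), rep("G", 3),
                 cbind(c("0/1", "0/0", "1/1"), c("0/0", "0/0", "0/1")))
  expect_equal(nrow(shared_called_loci(v2)), 3L)
  # a locus haploid in one sample leaves the shared set
  v3 <- make_vcf(rep("chr1", 2), c(10, 20), rep("A", 2), rep("G", 2),
                 cbind(c("0/1", "0/1"), c("1", "0/0")))
  expect_equal(shared_called_loci(v3)$pos, 20L)
})

test_that("heterozygosity is the exact het fraction over shared loci", {
  gt <- matrix(c("0/1", "0/0", "1/1", "0/1"), 4, 1)
  v <- make_vcf(rep("chr1", 4), 1:4 * 10, rep("A", 4), rep("G", 4), gt,
                samples = "dog1")
  s <- heterozygosity(v)
  expect_equal(s$n_het, 2L)
  expect_equal(s$n_shared, 4L)
  expect_equal(s$he, 0.5)
  expect_equal(s$population, "all")
  # all-homozygous sample sits at the lower bound
  v0 <- make_vcf(rep("chr1", 3), 1:3 * 10, rep("A", 3), rep("G", 3),
                 matrix(c("0/0", "1/1", "0/0"), 3, 1))
  expect_equal(heterozygosity(v0)$he, 0)
  # multi-allelic het (1/2) counts as heterozygous
  v12 <- make_vcf("chr1", 10, "A", "G,T", matrix("1/2", 1, 1))
  expect_equal(heterozygosity(v12)$n_het, 1L)
  # zero shared loci is an explicit error, not a division by zero
  vna <- make_vcf("chr1", 10, "A", "G", matrix("./.", 1, 1))
  expect_error(heterozygosity(vna), "undefined")
})

test_that("per-sample He matches an independent recount of the written VCF
           and is invariant under record reordering", {
  for (seed in c(3, 11)) {
    d <- withr::local_tempdir()
    fx <- generate_fixtures(fixture_spec(seed = seed, n_samples = 4,
                                         n_loci = 60, missing_rate = 0.1), d)
    v <- read_vcf(fx$files$vcf, verbose = FALSE)
    s <- heterozygosity(v)
    oracle <- oracle_diversity(fx$files$vcf)
    expect_equal(s$he, unname(oracle$he))
    expect_equal(unique(s$n_shared), oracle$n_shared)
    expect_equal(s$he, unname(fx$truth$he))
    # reorder records: He unchanged
    perm <- rev(seq_len(nrow(v$fix)))
    v_perm <- v
    v_perm$fix <- v$fix[perm, ]
    v_perm$gt <- v$gt[perm, , drop = FALSE]
    expect_equal(heterozygosity(v_perm)$he, s$he)
  }
})

test_that("dropping a sample never shrinks the shared-locus set", {
  d <- withr::local_tempdir()
  fx <- generate_fixtures(fixture_spec(seed = 5, n_samples = 5, n_loci = 60,
                                       missing_rate = 0.3), d)
  v <- read_vcf(fx$files$vcf, verbose = FALSE)
  full <- nrow(shared_called_loci(v))
  for (drop in v$sample_names) {
    keep <- setdiff(v$sample_names, drop)
    sub <- v
    sub$gt <- v$gt[, keep, drop = FALSE]
    sub$sample_names <- keep
    expect_gte(nrow(shared_called_loci(sub)), full)
  }
})

test_that("uniform heterozygosity gives exactly h/s for every sample", {
  # every sample heterozygous at the same 3 of 5 shared loci
  gt <- matrix(rep(c("0/1", "0/1", "0/1", "0/0", "1/1"), 3), 5, 3)
  v <- make_vcf(rep("chr1", 5), 1:5 * 10, rep("A", 5), rep("G", 5), gt)
  s <- heterozygosity(v)
  expect_true(all(s$he == 3 / 5))
})

test_that("diversity outputs write the population table, four charts and
           per-sample folders", {
  d <- withr::local_tempdir()
  fx <- generate_fixtures(fixture_spec(seed = 9, n_samples = 4, n_loci = 40), d)
  v <- read_vcf(fx$files$vcf, verbose = FALSE)
  pops <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(v$sample_names, "Labrador retriever", sep = "\t"), pops)
  s <- heterozygosity(v, populations = pops)
  expect_equal(unique(s$population), "Labrador retriever")
  out <- file.path(d, "div")
  suppressMessages(diversity_outputs(s, sample_of_interest = "dog2",
                                     out_dir = out))
  expect_true(file.exists(file.path(out, "diversity_population.tsv")))
  charts <- c("he_overview.png", "he_annotated.png",
              "he_sample_of_interest.png", "he_maximum.png")
  expect_true(all(file.exists(file.path(out, charts))))
  for (smp in v$sample_names) {
    expect_true(file.exists(file.path(out, smp, "diversity.tsv")))
    expect_true(all(file.exists(file.path(out, smp, charts))))
  }
  tab <- read.delim(file.path(out, "diversity_population.tsv"),
                    colClasses = "character")
  # He printed with 15 decimals
  expect_true(all(grepl("^0\\.\\d{15}$|^[01]\\.\\d{15}$", tab$Heterozygosity)))
  expect_error(suppressMessages(diversity_outputs(s, "nope", file.path(d, "x"))),
               "unknown sample")
  # single-sample summary still renders
  s1 <- s[1, , drop = FALSE]
  class(s1) <- c("diversity_summary", "data.frame")
  suppressMessages(diversity_outputs(s1, out_dir = file.path(d, "one")))
  expect_true(file.exists(file.path(d, "one", "he_overview.png")))
})
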