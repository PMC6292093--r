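make_catalog_vcf <- function(path) {
  # 6 records: 4 biallelic SNPs, one multiallelic, one indel
  write_test_vcf(
    path,
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    pos = c(10000L, 25000L, 60000L, 5000L, 9000L, 50000L),
    ref = c("A", "C", "G", "T", "AT", "G"),
    alt = c("C", "T,G", "A", "C", "A", "T"),
    ad = rbind(c("3,1", "1,3", "2,2"),
               c("1,1,0", "2,0,1", "0,1,1"),
               c(".", "4,0", "0,4"),
               c("2,2", "0,0", "1,1"),
               c("1,0", "2,1", "3,0"),
               c("5,0", "3,0", "2,0")),
    sample_ids = c("rep1", "rep2", "panelA"))
}

test_that("VCF import keeps biallelic SNPs and maps AD faithfully", {
  path <- withr::local_tempfile(fileext = ".vcf")
  make_catalog_vcf(path)
  cat <- read_allele_depths(path)
  expect_s3_class(cat, "site_catalog")
  expect_identical(cat$n_skipped, 2L) # multiallelic + indel dropped
  expect_identical(cat$pos, c(10000L, 60000L, 5000L, 50000L))
  expect_identical(cat$n_A[1, ], c(3L, 1L, 2L))
  expect_identical(cat$n_B[1, ], c(1L, 3L, 2L))
  # missing AD "." becomes (0, 0)
  expect_identical(unname(cat$n_A[2, 1]), 0L)
  expect_identical(unname(cat$n_B[2, 1]), 0L)
  expect_true(all(is.na(cat$freq_B)))
})

test_that("sample selection and header checks fail loudly", {
  path <- withr::local_tempfile(fileext = ".vcf")
  make_catalog_vcf(path)
  sub <- read_allele_depths(path, c("rep2", "panelA"))
  expect_identical(sub$sample_ids, c("rep2", "panelA"))
  expect_identical(sub$n_A[1, ], c(1L, 2L))
  expect_error(read_allele_depths(path, c("rep1", "ghost")),
               "ghost.*available", ignore.case = TRUE)
  # a VCF whose FORMAT lacks AD
  no_ad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "C", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t")), no_ad)
  expect_error(read_allele_depths(no_ad), "AD")
})

test_that("a VCF with zero usable records warns but returns", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, chrom = "chr1", pos = 100L, ref = "AT", alt = "A",
                 ad = matrix("1,1", 1, 1), sample_ids = "s1")
  expect_warning(cat <- read_allele_depths(path), "no usable")
  expect_length(cat$pos, 0L)
})

test_that("panel frequency estimation pools read counts", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(
    path,
    chrom = rep("chr1", 3), pos = c(1000L, 30000L, 60000L),
    ref = rep("A", 3), alt = rep("G", 3),
    ad = rbind(c("1,1", "3,1", "1,3"),   # panel pools to 4/8
               c("2,0", "0,0", "0,0"),   # zero panel reads -> NA
               c("1,1", "2,0", "3,0")),  # all-REF panel -> 0
    sample_ids = c("rep1", "p1", "p2"))
  cat <- read_allele_depths(path)
  cat <- estimate_allele_frequencies(cat, c("p1", "p2"))
  expect_equal(cat$freq_B, c(0.5, NA, 0))
  expect_error(estimate_allele_frequencies(cat, character(0)), "at least one")
  expect_error(estimate_allele_frequencies(cat, "nope"), "not in catalog")
})

test_that("frequency tables attach by chrom and position", {
  path <- withr::local_tempfile(fileext = ".vcf")
  make_catalog_vcf(path)
  cat <- read_allele_depths(path)
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_freq_table(ft, c("chr1", "chr2"), c(10000L, 50000L), c(0.42, 0.11))
  tab <- read_frequency_table(ft)
  cat <- attach_frequencies(cat, tab)
  expect_equal(cat$freq_B, c(0.42, NA, NA, 0.11))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tposition\n1\t2", bad)
  expect_error(read_frequency_table(bad), "chrom, pos, freq_B")
})

test_that("site sampling honors MAF, distance and coverage filters", {
  L <- 60
  # alternating positions 12 kb apart on one chromosome: the 20 kb rule
  # forbids adjacent picks
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path,
                 chrom = rep("chr1", L), pos = seq_len(L) * 12000L,
                 ref = rep("A", L), alt = rep("C", L),
                 ad = matrix("2,2", L, 2), sample_ids = c("r1", "r2"))
  cat <- read_allele_depths(path)
  freqs <- rep(c(0.45, 0.25, 0.05), length.out = L) # only 0.45 in (0.4, 0.5]
  cat <- attach_frequencies(cat, data.frame(chrom = cat$chrom, pos = cat$pos,
                                            freq_B = freqs))
  cfg <- sampling_config(L = 10, maf_min = 0.4, maf_max = 0.5,
                         min_distance = 20000, seed = 8)
  data <- sample_sites(cat, cfg, c("r1", "r2"))
  expect_identical(dim(data), c(10L, 2L))
  maf <- pmin(data$freq_B, 1 - data$freq_B)
  expect_true(all(maf > 0.4 & maf <= 0.5))
  expect_true(all(diff(sort(data$pos)) >= 20000))
  # bit-reproducible under the same seed
  again <- sample_sites(cat, cfg, c("r1", "r2"))
  expect_identical(again$pos, data$pos)
  expect_identical(again$n_A, data$n_A)
})

test_that("two candidates inside the minimum distance yield one site", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, chrom = rep("chr1", 2), pos = c(10000L, 25000L),
                 ref = rep("A", 2), alt = rep("C", 2),
                 ad = matrix("1,1", 2, 2), sample_ids = c("r1", "r2"))
  cat <- read_allele_depths(path)
  cat <- attach_frequencies(cat, data.frame(chrom = cat$chrom, pos = cat$pos,
                                            freq_B = c(0.45, 0.45)))
  cfg <- sampling_config(L = 2, maf_min = 0.4, maf_max = 0.5,
                         min_distance = 20000, seed = 1)
  expect_warning(data <- sample_sites(cat, cfg, c("r1", "r2")), "only 1 of")
  expect_identical(dim(data)[1], 1L)
})

test_that("coverage filter excludes zero-depth replicates and can be lifted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, chrom = rep("chr1", 2), pos = c(10000L, 40000L),
                 ref = rep("A", 2), alt = rep("C", 2),
                 ad = rbind(c("1,1", "0,0"), c("1,1", "2,0")),
                 sample_ids = c("r1", "r2"))
  cat <- read_allele_depths(path)
  cat <- attach_frequencies(cat, data.frame(chrom = cat$chrom, pos = cat$pos,
                                            freq_B = c(0.45, 0.45)))
  cfg <- sampling_config(L = 2, maf_min = 0.4, maf_max = 0.5,
                         min_distance = 0, seed = 1)
  expect_warning(data <- sample_sites(cat, cfg, c("r1", "r2")))
  expect_identical(data$pos, 40000L) # site with r2 at (0,0) excluded
  relaxed <- sampling_config(L = 2, maf_min = 0.4, maf_max = 0.5,
                             min_distance = 0, seed = 1,
                             require_read_each = FALSE)
  expect_identical(dim(sample_sites(cat, relaxed, c("r1", "r2")))[1], 2L)
  # no site at all in a too-narrow window
  tight <- sampling_config(L = 1, maf_min = 0.0, maf_max = 0.1, seed = 1)
  expect_error(sample_sites(cat, tight, c("r1", "r2")), "widen the MAF")
})
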