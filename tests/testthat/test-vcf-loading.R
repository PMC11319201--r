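# VCF round trips built on the in-package simulator plus hand-written edge
# cases.

write_mini_vcf <- function(records, samples, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrX>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

mini_panel <- function(samples, sexes) {
  tibble::tibble(sample = samples, sex = sexes, population = "TST")
}

test_that("ploidy arithmetic: one het female plus one hemizygous male", {
  vcf <- write_mini_vcf(
    "chrX\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1",
    c("fem", "mal"), withr::local_tempfile(fileext = ".vcf"))
  hm <- read_phased_haplotypes(vcf, mini_panel(c("fem", "mal"),
                                               c("female", "male")))
  expect_equal(nrow(hm$geno), 3)
  expect_equal(hm$sites$alt_count, 2L)
  expect_equal(hm$sites$freq, 2 / 3)
})

test_that("unphased female genotypes fail naming sample and position", {
  vcf <- write_mini_vcf(
    "chrX\t555\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "fem", withr::local_tempfile(fileext = ".vcf"))
  expect_error(
    read_phased_haplotypes(vcf, mini_panel("fem", "female")),
    "fem.*555")
  # non-strict mode still rejects unphased heterozygotes but takes 1/1
  vcf2 <- write_mini_vcf(
    "chrX\t7\t.\tA\tG\t.\tPASS\t.\tGT\t1/1",
    "fem", withr::local_tempfile(fileext = ".vcf"))
  hm <- read_phased_haplotypes(vcf2, mini_panel("fem", "female"),
                               strict = FALSE)
  expect_equal(as.vector(hm$geno), c(1L, 1L))
})

test_that("male genotype dialects: haploid and homozygous diploid accepted", {
  vcf <- write_mini_vcf(
    c("chrX\t10\t.\tA\tG\t.\tPASS\t.\tGT\t1\t1|1\t1/1",
      "chrX\t20\t.\tC\tT\t.\tPASS\t.\tGT\t0\t0|0\t0/0"),
    c("m1", "m2", "m3"), withr::local_tempfile(fileext = ".vcf"))
  hm <- read_phased_haplotypes(vcf, mini_panel(c("m1", "m2", "m3"),
                                               rep("male", 3)))
  expect_equal(dim(hm$geno), c(3L, 2L))
  expect_equal(hm$sites$alt_count, c(3L, 0L))

  # heterozygous male is an error
  bad <- write_mini_vcf(
    "chrX\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "m1", withr::local_tempfile(fileext = ".vcf"))
  expect_error(read_phased_haplotypes(bad, mini_panel("m1", "male")),
               "m1")
})

test_that("multiallelic and non-SNV records are skipped with a message", {
  vcf <- write_mini_vcf(
    c("chrX\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
      "chrX\t20\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1",
      "chrX\t30\t.\tAT\tA\t.\tPASS\t.\tGT\t0|1"),
    "fem", withr::local_tempfile(fileext = ".vcf"))
  expect_message(
    hm <- read_phased_haplotypes(vcf, mini_panel("fem", "female")),
    "2 multiallelic or non-SNV")
  expect_equal(nrow(hm$sites), 1)
})

test_that("samples missing from the panel are an error", {
  vcf <- write_mini_vcf(
    "chrX\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1",
    c("fem", "ghost"), withr::local_tempfile(fileext = ".vcf"))
  expect_error(read_phased_haplotypes(vcf, mini_panel("fem", "female")),
               "ghost")
})

test_that("region and PAR-mask restriction work on coordinates", {
  vcf <- write_mini_vcf(
    c("chrX\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
      "chrX\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|0",
      "chrX\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1|1"),
    "fem", withr::local_tempfile(fileext = ".vcf"))
  pan <- mini_panel("fem", "female")

  hm <- read_phased_haplotypes(vcf, pan, region = "chrX:150-350")
  expect_equal(hm$sites$pos, c(200L, 300L))
  expect_error(read_phased_haplotypes(vcf, pan, region = "chrX:400-500"),
               "no records")

  par_bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrX\t250\t400\tPAR1", par_bed)  # 0-based half-open: 251..400
  expect_message(
    hm2 <- read_phased_haplotypes(vcf, pan, par_mask = par_bed),
    "pseudoautosomal")
  expect_equal(hm2$sites$pos, c(100L, 200L))
})

test_that("missing genotypes drop the site cohort-wide by default", {
  vcf <- write_mini_vcf(
    c("chrX\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1",
      "chrX\t20\t.\tC\tT\t.\tPASS\t.\tGT\t.\t0"),
    c("fem", "mal"), withr::local_tempfile(fileext = ".vcf"))
  pan <- mini_panel(c("fem", "mal"), c("female", "male"))
  expect_message(hm <- read_phased_haplotypes(vcf, pan), "missing")
  expect_equal(hm$sites$pos, 10L)
  expect_error(read_phased_haplotypes(vcf, pan, missing_policy = "error"),
               "missing")
})

test_that("simulated cohorts reload to the exact generating truth", {
  cfg <- cohort_sim_config(n_females = 6, n_males = 5, n_sites = 80,
                           n_genes = 8, seed = 13)
  co <- simulate_cohort(cfg, withr::local_tempdir())
  hm <- read_phased_haplotypes(co$vcf, co$panel, annotation = co$annotation)
  expect_equal(unname(hm$geno), unname(co$truth$haplotypes))
  expect_equal(hm$sites$consequence, co$truth$sites$consequence)
  # escape BED masks exactly the escape-flagged genes
  kept <- filter_sites(hm, keep_consequences = c("missense", "synonymous"),
                       escape = co$escape_bed)
  expect_setequal(unique(kept$sites$gene),
                  unique(co$truth$sites$gene[!co$truth$sites$escape]))
})
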