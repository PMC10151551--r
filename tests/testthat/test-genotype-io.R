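vcf_fixture <- function() {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:10\t1/1:7",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT:DP\t./.:0\t0/0:9",
    "chr1\t300\t.\tA\tT,G\t.\tPASS\t.\tGT:DP\t0/1:5\t0/0:5",  # multiallelic
    "chr1\t400\t.\tAT\tA\t.\tPASS\t.\tGT:DP\t0/1:5\t0/0:5",   # indel
    "chr1\t500\t.\tC\tG\t.\tPASS\t.\tGT:DP\t1/0:4\t0/1:12"
  )
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

test_that("read_vcf loads dosages, depth and skips non-biallelic-SNP records", {
  G <- suppressMessages(read_vcf(vcf_fixture()))
  expect_equal(n_loci(G), 3)  # multiallelic + indel skipped
  expect_equal(n_samples(G), 2)
  expect_equal(unname(genotypes_of(G, "S1")), c(1L, NA, 1L))
  expect_equal(unname(genotypes_of(G, "S2")), c(2L, 0L, 1L))
  expect_equal(unname(G$depth[1, ]), c(10L, 0L, 4L))
  expect_null(G$hap1)  # "/" calls are unphased
  expect_message(read_vcf(vcf_fixture()), "2 multiallelic/non-SNP")
})

test_that("phased VCF round-trips dosage, missingness, phase and depth", {
  G <- family_panel(n_loci = 120)
  D <- degrade(G, sim_config(n_loci = 120, error_rate = 0,
                             missing_rate = 0.25, seed = 13))
  path <- tempfile(fileext = ".vcf")
  write_vcf(D, path)
  txt <- readLines(path)
  expect_true(any(grepl("^##fileformat", txt)))
  R <- read_vcf(path)
  expect_identical(unname(R$gt), unname(D$gt))
  expect_identical(unname(R$hap1), unname(D$hap1))
  expect_identical(unname(R$hap2), unname(D$hap2))
  expect_identical(unname(R$depth), unname(D$depth))
  expect_equal(R$samples$sample_id, D$samples$sample_id)
  expect_equal(R$loci$pos, D$loci$pos)
})

test_that("apply_filters removes loci and samples in the documented order", {
  # 4 samples x 4 loci; locus 2 called in only 2/4 samples
  gt <- rbind(c(0, 1, 2, 1),
              c(1, NA, 0, 0),
              c(2, NA, 1, 1),
              c(0, 1, 0, NA))
  G <- toy_geno(gt)
  spec <- filter_spec(min_locus_callrate = 0.75, min_sample_callrate = 0,
                      min_depth = 0, min_maf = 0)
  out <- apply_filters(G, spec)
  expect_equal(n_loci(out), 3)
  rep <- attr(out, "filter_report")
  expect_equal(rep$loci_removed_callrate, 1)

  # depth mask with all depths 10 removes nothing
  Gd <- toy_geno(gt, depth = matrix(10L, 4, 4))
  out2 <- apply_filters(Gd, filter_spec(min_locus_callrate = 0.75,
                                        min_sample_callrate = 0,
                                        min_depth = 5, min_maf = 0))
  expect_equal(attr(out2, "filter_report")$calls_masked_by_depth, 0)
  expect_equal(n_loci(out2), 3)

  # depth mask sets low-depth calls missing before the call-rate stages
  dp <- matrix(10L, 4, 4); dp[1:2, 1] <- 1L
  out3 <- apply_filters(toy_geno(gt, depth = dp),
                        filter_spec(min_locus_callrate = 0.75,
                                    min_sample_callrate = 0,
                                    min_depth = 5, min_maf = 0))
  expect_equal(attr(out3, "filter_report")$calls_masked_by_depth, 2)
  expect_equal(n_loci(out3), 2)  # locus 1 drops to 2/4 call rate
})

test_that("the MAF stage drops rare-allele loci computed on called alleles", {
  # locus 1: alt freq 1/40 = 0.025 < 0.03; locus 2: common
  gt <- cbind(c(1L, rep(0L, 19)), rep(1L, 20))
  G <- toy_geno(gt)
  out <- apply_filters(G, filter_spec(min_locus_callrate = 0,
                                      min_sample_callrate = 0, min_depth = 0,
                                      min_maf = 0.03, maf_callrate = 0))
  expect_equal(n_loci(out), 1)
  expect_equal(attr(out, "filter_report")$loci_removed_maf, 1)
  # MAF is the minor allele: freq 0.975 alt is equally filtered
  gt2 <- cbind(2L - gt[, 1], rep(1L, 20))
  out2 <- apply_filters(toy_geno(gt2),
                        filter_spec(min_locus_callrate = 0,
                                    min_sample_callrate = 0, min_depth = 0,
                                    min_maf = 0.03, maf_callrate = 0))
  expect_equal(n_loci(out2), 1)
})

test_that("filters are idempotent and can empty out with a clear error", {
  G <- degrade(family_panel(n_loci = 400),
               sim_config(n_loci = 400, error_rate = 0, missing_rate = 0.2,
                          seed = 3))
  spec <- filter_spec()
  once <- apply_filters(G, spec)
  twice <- apply_filters(once, spec)
  expect_identical(unname(once$gt), unname(twice$gt))
  rep2 <- attr(twice, "filter_report")
  expect_equal(rep2$loci_removed_callrate + rep2$samples_removed_callrate +
                 rep2$loci_removed_maf, 0)
  # every locus has a missing call somewhere: a 100% call-rate bar empties it
  gt <- rbind(c(NA, 0L, 1L), c(1L, NA, 2L), c(2L, 1L, NA))
  expect_error(
    apply_filters(toy_geno(gt), filter_spec(min_locus_callrate = 1,
                                            min_maf = 0)),
    "no data survive")
})

test_that("dual datasets trade loci against focal samples", {
  set.seed(31)
  G <- family_panel(n_loci = 600, n_founders = 12)
  # one very sparse focal sample, one decently covered
  D <- degrade(G, sim_config(n_loci = 600, error_rate = 0,
                             missing_rate = c(self1 = 0.9, clone1 = 0.1),
                             seed = 5))
  focal <- c("self1", "clone1")
  spec <- filter_spec(min_depth = 0, min_maf = 0)
  dual <- build_dual_datasets(D, focal, spec)
  expect_false("self1" %in% dual$wide$samples$sample_id)
  expect_true(all(focal %in% dual$deep$samples$sample_id))
  expect_gt(n_loci(dual$wide), n_loci(dual$deep))
  expect_gte(n_loci(dual$wide), n_loci(dual$deep))

  # with complete data the two datasets coincide
  dual2 <- build_dual_datasets(G, focal, spec)
  expect_identical(unname(dual2$wide$gt), unname(dual2$deep$gt))
})

test_that("wide dataset never has fewer loci than deep across random panels", {
  for (s in 1:5) {
    G <- family_panel(n_loci = 300, n_founders = 8, seed = 100 + s)
    D <- degrade(G, sim_config(n_loci = 300, error_rate = 0,
                               missing_rate = c(self1 = 0.7, cross1 = 0.3),
                               seed = 200 + s))
    dual <- build_dual_datasets(D, c("self1", "cross1"),
                                filter_spec(min_depth = 0, min_maf = 0))
    expect_gte(n_loci(dual$wide), n_loci(dual$deep))
    expect_true(all(c("self1", "cross1") %in% dual$deep$samples$sample_id))
  }
})
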