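test_that("founders are drawn in Hardy-Weinberg proportions", {
  # freq 0.5 everywhere: expected heterozygosity 2pq = 0.5
  cfg <- sim_config(n_founders = 300, n_loci = 50, freq = 0.5, seed = 42)
  F <- simulate_founders(cfg)
  het <- colMeans(F$gt == 1L)
  se <- sqrt(0.5 * 0.5 / 300)
  expect_true(all(abs(het - 0.5) < 3 * se + 0.05))
  expect_lt(abs(mean(het) - 0.5), 3 * se / sqrt(50) * 10)

  # freq 1: everything homozygous alternate
  F1 <- simulate_founders(sim_config(n_founders = 10, n_loci = 20, freq = 1,
                                     seed = 1))
  expect_true(all(F1$gt == 2L))
  expect_equal(sum(F1$gt == 1L), 0)
})

test_that("founder sample allele frequencies recover the generating frequencies", {
  cfg <- sim_config(n_founders = 500, n_loci = 40, seed = 9)
  F <- simulate_founders(cfg)
  # regenerate the frequency draws the constructor used
  set.seed(cfg$seed)
  p <- runif(cfg$n_loci, cfg$freq_range[1], cfg$freq_range[2])
  obs <- alt_freq(F)
  se <- sqrt(p * (1 - p) / (2 * 500))
  expect_true(mean(abs(obs - p) <= 3 * se) > 0.95)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_founders = 8, n_loci = 300, seed = 5)
  A <- simulate_founders(cfg)
  B <- simulate_founders(cfg)
  expect_identical(A$gt, B$gt)
  expect_identical(A$hap1, B$hap1)
  ped <- pedigree_spec(data.frame(child = "c", kind = "self",
                                  parent1 = "F1", parent2 = NA))
  expect_identical(breed(A, ped, seed = 2)$gt, breed(B, ped, seed = 2)$gt)
  dcfg <- sim_config(n_loci = 300, error_rate = 0.01, missing_rate = 0.2, seed = 3)
  expect_identical(degrade(A, dcfg)$gt, degrade(A, dcfg)$gt)
})

test_that("Mendelian transmission is exact for fixed parents", {
  # AA x aa -> always Aa
  h0 <- matrix(0L, 1, 50); h1 <- matrix(1L, 1, 50)
  F <- toy_geno(rbind(h0 + h0, h1 + h1), ids = c("P1", "P2"),
                hap1 = rbind(h0, h1), hap2 = rbind(h0, h1))
  F$anc1 <- matrix(rep(c(1L, 3L), 50), 2)
  F$anc2 <- matrix(rep(c(2L, 4L), 50), 2)
  ped <- pedigree_spec(data.frame(child = "c", kind = "cross",
                                  parent1 = "P1", parent2 = "P2"))
  G <- breed(F, ped, seed = 1)
  expect_true(all(genotypes_of(G, "c") == 1L))

  # self(Aa) segregates 1:2:1
  P <- het_parent(9000)
  P$anc1 <- matrix(1L, 1, 9000); P$anc2 <- matrix(2L, 1, 9000)
  ped <- pedigree_spec(data.frame(child = "s", kind = "self",
                                  parent1 = "P", parent2 = NA))
  S <- genotypes_of(breed(P, ped, seed = 7), "s")
  counts <- tabulate(S + 1L, 3)
  expect_gt(suppressWarnings(
    chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value), 1e-4)
})

test_that("a selfing chain halves heterozygosity each generation", {
  F <- simulate_founders(sim_config(n_founders = 1, n_loci = 10000, seed = 21))
  g <- 3
  ped <- pedigree_spec(data.frame(
    child = paste0("s", 1:g), kind = "self",
    parent1 = c("F1", paste0("s", seq_len(g - 1))), parent2 = NA))
  G <- breed(F, ped, seed = 22)
  h0 <- het_counts(G)[["F1"]]
  for (k in 1:g) {
    hk <- het_counts(G)[[paste0("s", k)]]
    expected <- h0 * 0.5^k
    se <- sqrt(h0 * 0.5^k * (1 - 0.5^k))
    expect_lt(abs(hk - expected), 3 * se)
  }
})

test_that("clones are genotype-identical before degradation", {
  G <- family_panel()
  expect_identical(genotypes_of(G, "F1"), genotypes_of(G, "clone1"))
  expect_identical(G$hap1[match("F1", G$samples$sample_id), ],
                   G$hap1[match("clone1", G$samples$sample_id), ])
})

test_that("offspring ancestry traces to the declared parents", {
  G <- family_panel(n_loci = 500)
  f1 <- match("F1", G$samples$sample_id); f2 <- match("F2", G$samples$sample_id)
  ch <- match("cross1", G$samples$sample_id)
  p1_haps <- c(G$anc1[f1, 1], G$anc2[f1, 1])
  p2_haps <- c(G$anc1[f2, 1], G$anc2[f2, 1])
  # exactly one allele per parent per locus
  expect_true(all(G$anc1[ch, ] %in% p1_haps))
  expect_true(all(G$anc2[ch, ] %in% p2_haps))
})

test_that("pedigree validation rejects malformed specs", {
  expect_error(pedigree_spec(data.frame(child = "c", kind = "cross",
                                        parent1 = "A", parent2 = NA)),
               "two parents")
  expect_error(pedigree_spec(data.frame(child = "c", kind = "fuse",
                                        parent1 = "A", parent2 = "B")),
               "unknown event kind")
  F <- simulate_founders(sim_config(n_founders = 2, n_loci = 10, seed = 1))
  bad <- pedigree_spec(data.frame(child = "c", kind = "self",
                                  parent1 = "nope", parent2 = NA))
  expect_error(breed(F, bad), "unknown parent")
})

test_that("degrade applies error, missingness and depth as configured", {
  G <- family_panel(n_loci = 1000)
  # identity when error and missingness are off
  clean <- degrade(G, sim_config(n_loci = 1000, error_rate = 0,
                                 missing_rate = 0, seed = 4))
  expect_identical(clean$gt, G$gt)
  expect_false(is.null(clean$depth))
  # full missingness for one sample only
  D <- degrade(G, sim_config(n_loci = 1000, error_rate = 0,
                             missing_rate = c(self1 = 1), seed = 4))
  expect_true(all(is.na(genotypes_of(D, "self1"))))
  expect_true(all(!is.na(genotypes_of(D, "F1"))))
  # the input object is untouched
  expect_false(anyNA(G$gt))
})

test_that("per-allele flip count matches its binomial expectation", {
  n_loci <- 6896
  G <- family_panel(n_loci = n_loci)
  e <- 0.0033
  D <- degrade(G, sim_config(n_loci = n_loci, error_rate = e,
                             missing_rate = 0, seed = 8))
  i <- match("F1", G$samples$sample_id)
  flips <- sum(G$hap1[i, ] != D$hap1[i, ]) + sum(G$hap2[i, ] != D$hap2[i, ])
  expected <- 2 * n_loci * e  # ~45 alleles for a diploid at 6,896 sites
  expect_lt(abs(flips - expected), 3 * sqrt(expected) + 1)
})

test_that("color phenotype follows the additive model and grade clipping", {
  G <- family_panel(n_loci = 100)
  zero <- effect_table("chr1", c(1000, 2000), "alt", c(0, 0))
  col <- simulate_color(G, zero, noise_sd = 0, seed = 1)
  expect_true(all(col$grade == 0))
  expect_true(all(col$category == "white"))

  # a sample homozygous alt at one locus of effect 2 lands on grade 4 (black)
  P <- toy_geno(matrix(2L, 1, 3), ids = "x")
  tb <- effect_table("chr1", 1000, "alt", 2.0)
  col <- simulate_color(P, tb, noise_sd = 0, seed = 1)
  expect_equal(col$grade, 4)
  expect_equal(col$category, "black")

  # with zero noise the category is a deterministic function of dosages
  a <- simulate_color(G, effect_table("chr1", 1000, "alt", 1.3), 0, seed = 1)
  b <- simulate_color(G, effect_table("chr1", 1000, "alt", 1.3), 0, seed = 99)
  expect_identical(a$category, b$category)
  expect_error(simulate_color(G, effect_table("chr9", 5, "alt", 1), 0, 1),
               "absent")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(error_rate = 1.5), "error_rate")
  expect_error(sim_config(missing_rate = -0.1), "missing_rate")
  expect_error(sim_config(freq = c(2)), "frequencies")
  expect_error(sim_config(n_loci = 0))
})
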