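test_that("containment counts violating allele copies per site", {
  p <- dos(c("Aa", "AA", "aa"))
  o <- dos(c("aa", "AA", "aa"))
  res <- containment_test(p, o)
  expect_equal(res$n_violating_alleles, 0)  # het parent can't be violated
  expect_true(res$contained)

  o2 <- dos(c("aa", "aa", "aa"))
  res2 <- containment_test(p, o2, max_violations = 0)
  expect_equal(res2$n_violating_alleles, 2)  # offspring aa vs parent AA
  expect_false(res2$contained)

  # one alt copy against a hom-ref parent is a single violation
  res3 <- containment_test(dos(c("AA")), dos(c("Aa")), max_violations = 0)
  expect_equal(res3$n_violating_alleles, 1)

  # missing calls on either side are skipped
  res4 <- containment_test(dos(c("AA", ".")), dos(c(".", "aa")))
  expect_equal(res4$n_sites_compared, 0)
  expect_error(containment_test(p, o[-1]), "length")
})

test_that("the error-rate arithmetic matches violations over allele copies", {
  # 45 violating alleles over 6,896 diploid sites is a 0.33% per-allele rate
  n <- 6896
  parent <- rep(0L, n)
  offspring <- c(rep(1L, 45), rep(0L, n - 45))
  res <- containment_test(parent, offspring, max_violations = 45)
  expect_equal(res$n_sites_compared, 6896)
  expect_equal(res$n_violating_alleles, 45)
  expect_equal(res$error_rate, 45 / (2 * 6896))
  expect_equal(round(100 * res$error_rate, 2), 0.33)
  expect_true(res$contained)
})

test_that("containment is reflexive", {
  G <- family_panel(n_loci = 1000, seed = 3)
  for (id in c("F1", "self1")) {
    g <- genotypes_of(G, id)
    res <- containment_test(g, g, max_violations = 0)
    expect_equal(res$n_violating_alleles, 0)
    expect_true(res$contained)
  }
})

test_that("directionality separates descent, cloning and unrelatedness", {
  G <- family_panel(n_loci = 5000, seed = 13)
  p <- genotypes_of(G, "F1")
  s <- genotypes_of(G, "self1")
  # error-free selfed offspring: contained in parent but not conversely
  d <- directionality(p, s, max_violations = 0)
  expect_equal(d$verdict, "a_contains_b")
  expect_equal(d$ab$n_violating_alleles, 0)
  expect_gt(d$ba$n_violating_alleles, 0)
  # clones contain each other
  expect_equal(directionality(p, genotypes_of(G, "clone1"))$verdict, "mutual")
  # unrelated founders violate massively in both directions
  d3 <- directionality(genotypes_of(G, "F3"), genotypes_of(G, "F4"))
  expect_equal(d3$verdict, "neither")
  expect_gt(d3$ab$error_rate, 0.05)
})

test_that("error-free selfed pairs keep zero violations and zero IBS0", {
  for (s in 1:3) {
    G <- family_panel(n_loci = 2000, seed = 300 + s)
    p <- genotypes_of(G, "F1"); o <- genotypes_of(G, "self1")
    expect_equal(containment_test(p, o)$n_violating_alleles, 0)
    expect_equal(ibs0(pair_counts(p, o)), 0)
  }
})

test_that("genotyping error produces violation counts of the expected order", {
  # an otherwise-contained clone pair at the aDNA error rate should show
  # on the order of tens of violating alleles at 6,896 sites
  G <- family_panel(n_loci = 6896, seed = 29)
  D <- degrade(G, sim_config(n_loci = 6896, error_rate = 0.0033,
                             missing_rate = 0, seed = 30))
  res <- containment_test(genotypes_of(D, "F1"), genotypes_of(D, "clone1"),
                          max_rate = 0.005)
  expect_gte(res$n_violating_alleles, 10)
  expect_lte(res$n_violating_alleles, 120)
  expect_true(res$contained)
})

test_that("heterozygosity ratio estimates selfing generations", {
  # the observed 1,976 vs 913 heterozygous sites give a ~1:2 ratio, one
  # selfing generation
  parent <- c(rep(1L, 1976), rep(0L, 3000))
  offspring <- c(rep(1L, 913), rep(0L, 1976 - 913), rep(0L, 3000))
  est <- selfing_generations(parent, offspring)
  expect_equal(est$het_parent, 1976)
  expect_equal(est$het_offspring, 913)
  expect_equal(round(est$ratio, 3), 0.462)
  expect_equal(est$g_hat, 1L)
  expect_true(est$compatible)

  # equal heterozygosity: clone-compatible, zero generations
  expect_equal(selfing_generations(parent, parent)$g_hat, 0L)
  # 400 vs 100 het: two generations
  est2 <- selfing_generations(c(rep(1L, 400), rep(0L, 100)),
                              c(rep(1L, 100), rep(0L, 400)))
  expect_equal(est2$g_hat, 2L)
  expect_equal(est2$ratio, 0.25)
  # no parental heterozygosity: flagged undefined
  und <- selfing_generations(rep(0L, 10), rep(1L, 10))
  expect_true(is.na(und$g_hat))
})

test_that("haplotype matching is exact without recombination and noisy otherwise", {
  # selfing with whole-haplotype gametes: each offspring haplotype is a
  # verbatim copy of a parent haplotype
  G <- family_panel(n_loci = 2000, seed = 41, recomb_rate = 0)
  hm <- haplotype_containment(G, "F1", "self1")
  expect_equal(hm$mismatch, c(0, 0))
  # clone: both haplotypes match their own template
  hm2 <- haplotype_containment(G, "F1", "clone1")
  expect_equal(hm2$mismatch, c(0, 0))
  expect_equal(hm2$best_parent_hap, c(1, 2))
  # an unrelated sample mismatches well above zero
  hm3 <- haplotype_containment(G, "F3", "F4")
  expect_true(all(hm3$mismatch > 0.05))
  unphased <- toy_geno(matrix(1L, 2, 4), ids = c("a", "b"))
  expect_error(haplotype_containment(unphased, "a", "b"), "phased")
})

test_that("selfing-generation recovery is reliable over replicate chains", {
  # moderate-scale version of the recovery property: g in 0..3, 10 chains
  # each, at 4,000 loci
  hits <- 0; total <- 0
  for (g in 0:3) for (r in 1:10) {
    F <- simulate_founders(sim_config(n_founders = 1, n_loci = 4000,
                                      seed = 1000 + 40 * g + r))
    G <- if (g == 0) {
      ped <- pedigree_spec(data.frame(child = "end", kind = "clone",
                                      parent1 = "F1", parent2 = NA))
      breed(F, ped, seed = r)
    } else {
      kids <- c(if (g > 1) paste0("s", seq_len(g - 1)), "end")
      ped <- pedigree_spec(data.frame(
        child = kids, kind = "self",
        parent1 = c("F1", kids[-length(kids)]), parent2 = NA))
      breed(F, ped, seed = r)
    }
    est <- selfing_generations(genotypes_of(G, "F1"), genotypes_of(G, "end"))
    total <- total + 1
    if (!is.na(est$g_hat) && est$g_hat == g) hits <- hits + 1
  }
  expect_gte(hits / total, 0.9)
})

test_that("descent_report bundles every line of evidence coherently", {
  G <- family_panel(n_loci = 3000, seed = 47)
  rep <- descent_report(G, "F1", "self1", max_rate = 0.005)
  expect_equal(rep$directionality, "a_contains_b")
  expect_equal(rep$ibs0, 0)
  expect_lt(abs(rep$phi - 1 / 3), 0.05)
  expect_equal(rep$selfing$g_hat, 1L)
  expect_equal(rep$n_loci_panel, 3000)
  expect_equal(rep$n_sites_compared, 3000)
  expect_s3_class(rep$haplotype_match, "data.frame")
})
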