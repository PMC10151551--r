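# Build a geno_matrix directly from a dosage matrix (samples x loci),
# with default single-chromosome loci 1000 bp apart.
toy_geno <- function(gt, ids = paste0("S", seq_len(nrow(gt))),
                     depth = NULL, hap1 = NULL, hap2 = NULL,
                     pos = seq_len(ncol(gt)) * 1000L, groups = NULL) {
  gt <- matrix(as.integer(gt), nrow = nrow(gt))
  loci <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (!is.null(groups)) samples$group <- groups
  geno_matrix(gt, loci, samples, depth = depth, hap1 = hap1, hap2 = hap2)
}

# A fully heterozygous phased parent: hap1 all ref, hap2 all alt.
het_parent <- function(n_loci, id = "P") {
  h1 <- matrix(0L, 1, n_loci)
  h2 <- matrix(1L, 1, n_loci)
  toy_geno(h1 + h2, ids = id, hap1 = h1, hap2 = h2)
}

# Standard family panel: founders plus cross child, selfed child, clone.
family_panel <- function(n_loci = 2000, n_founders = 4, seed = 11,
                         recomb_rate = 0.5) {
  F <- simulate_founders(sim_config(n_founders = n_founders, n_loci = n_loci,
                                    seed = seed))
  ped <- pedigree_spec(data.frame(
    child = c("cross1", "self1", "clone1"),
    kind = c("cross", "self", "clone"),
    parent1 = c("F1", "F1", "F1"),
    parent2 = c("F2", NA, NA)))
  breed(F, ped, seed = seed + 1, recomb_rate = recomb_rate)
}

# Dosage vectors written as genotype strings, e.g. c("AA","Aa","aa") -> 0,1,2
dos <- function(x) {
  v <- c(AA = 0L, Aa = 1L, aA = 1L, aa = 2L)[x]
  v[x == "."] <- NA_integer_
  unname(v)
}
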