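#!/usr/bin/env Rscript
# Stage 1: build the synthetic study panel.
#
# The panel emulates the structure of the grape relatedness study: a few
# dozen modern cultivated accessions, a handful of wild ones, a modern clone
# pair, and two "archaeological" samples -- one descended from a modern
# founder by one selfing generation (the descent case of interest) and one
# an outcross of two other founders. Genotypes are then degraded with
# aDNA-style sparsity: per-allele error 0.33% and heavy missingness on the
# ancient samples. Berry color is an additive polygenic trait over 19 loci.
#
# Outputs under scratch/sim/: degraded VCF + metadata (the analysis input),
# the clean phased VCF (standing in for the imputed/phased dataset), the
# planted effect table and the true pedigree.

suppressPackageStartupMessages(library(vinekin))

seed <- 42
out <- "scratch/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_founders = 40, n_loci = 6896, error_rate = 0.0033,
                  missing_rate = c(AncientA = 0.35, AncientB = 0.55),
                  depth_mean = 30, seed = seed)
founders <- simulate_founders(cfg)
founders$samples$group[39:40] <- "wild"

ped <- pedigree_spec(data.frame(
  child   = c("CloneOfF5", "AncientA", "AncientB"),
  kind    = c("clone",     "self",     "cross"),
  parent1 = c("F5",        "F1",       "F2"),
  parent2 = c(NA,          NA,         "F3")))
# blocky gametes (switch probability 0.02 between adjacent loci) so IBD
# segments are long enough to be interesting
panel <- breed(founders, ped, seed = seed + 1, recomb_rate = 0.02)
panel$samples$group[panel$samples$sample_id %in% c("AncientA", "AncientB")] <-
  "archaeological"

# polygenic berry color: 19 loci, effects spanning the 0-4 grade scale
# one MybA-like major locus plus 18 modifiers; effect sum 2.0 centres the
# panel mid-scale so all five categories are populated
eff_idx <- seq(5, by = 360, length.out = 19)
effects <- effect_table("chr1", panel$loci$pos[eff_idx], "alt",
                        c(1.2, 0.3, 0.25, 0.2, 0.15, 0.12, 0.1, 0.08, 0.06,
                          0.05, 0.1, 0.05, -0.2, -0.15, -0.12, -0.1, -0.08,
                          -0.06, -0.05))
col <- simulate_color(panel, effects, noise_sd = 0.35, seed = seed + 2)
panel$samples$color <- ifelse(panel$samples$group == "archaeological",
                              NA, col$category)

degraded <- degrade(panel, cfg, seed = seed + 3)

paths <- write_sim_bundle(degraded, out, pedigree = ped, prefix = "panel")
write_sim_bundle(panel, out, prefix = "panel_phased_clean")
write_effect_table(effects, file.path(out, "effects.tsv"))

cat("panel:", n_samples(degraded), "samples x", n_loci(degraded), "loci\n")
cat("mean call rate by group:\n")
print(round(tapply(sample_callrate(degraded), degraded$samples$group, mean), 3))
cat("color categories in the modern panel:\n")
print(table(panel$samples$color, useNA = "ifany"))
cat("written:", paths$vcf, "\n")
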