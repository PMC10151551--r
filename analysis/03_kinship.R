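#!/usr/bin/env Rscript
# Stage 3: pairwise kinship.
#
# Runs the KING-robust estimator over every sample pair of both datasets,
# classifies pairs into the powers-of-two relatedness categories with the
# IBS0 gate for parent-offspring, and lists every close relationship found.
# The planted truth is one clone pair (F5 / CloneOfF5) and two
# parent-offspring constellations (F1-AncientA by selfing; F2/F3-AncientB
# by outcrossing).

suppressPackageStartupMessages(library(vinekin))

dir.create("results/kinship", showWarnings = FALSE, recursive = TRUE)
meta <- "scratch/sim/panel_samples.tsv"

for (ds in c("wide", "deep")) {
  G <- read_vcf(sprintf("scratch/datasets/%s.vcf", ds), meta)
  km <- kinship_matrix(G)
  out <- sprintf("results/kinship/king_%s.tsv", ds)
  write.table(km, out, sep = "\t", quote = FALSE, row.names = FALSE)
  # third-degree calls are noise-prone at a few thousand SNPs; report from
  # second degree up
  close <- km[km$category %in% c("duplicate/clone", "parent-offspring",
                                 "first-degree-other", "second-degree"), ]
  cat(sprintf("[%s] %d samples, %d loci, %d pairs; close pairs:\n",
              ds, n_samples(G), n_loci(G), nrow(km)))
  print(close[order(-close$phi),
              c("id1", "id2", "n_compared", "phi", "ibs0", "category")],
        row.names = FALSE, digits = 3)
}
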