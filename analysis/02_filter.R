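#!/usr/bin/env Rscript
# Stage 2: dataset construction.
#
# Applies the quality filters (per-call depth >= 5 on the sequenced samples,
# locus call rate >= 75%, sample call rate >= 60%, then MAF >= 3% at >= 80%
# call rate) and builds the two SNP datasets: a "wide" one that maximises
# locus count by dropping focal samples too sparse to pass the sample
# call-rate bar, and a "deep" one that keeps every archaeological sample at
# the cost of restricting to loci called in all of them.

suppressPackageStartupMessages(library(vinekin))

G <- read_vcf("scratch/sim/panel.vcf", "scratch/sim/panel_samples.tsv")
focal <- G$samples$sample_id[G$samples$group == "archaeological"]
spec <- filter_spec(min_locus_callrate = 0.75, min_sample_callrate = 0.60,
                    min_depth = 5, depth_samples = focal,
                    min_maf = 0.03, maf_callrate = 0.80)

dual <- build_dual_datasets(G, focal, spec)

cat("input:", n_samples(G), "samples x", n_loci(G), "loci;",
    length(focal), "archaeological\n")
print(dual$summary)
cat("wide retains focal:",
    paste(intersect(focal, dual$wide$samples$sample_id), collapse = ", "), "\n")
cat("filter funnel (wide):\n")
str(attr(dual$wide, "filter_report"))

dir.create("scratch/datasets", showWarnings = FALSE, recursive = TRUE)
dir.create("results/datasets", showWarnings = FALSE, recursive = TRUE)
write_vcf(dual$wide, "scratch/datasets/wide.vcf")
write_vcf(dual$deep, "scratch/datasets/deep.vcf")
write.table(dual$summary, "results/datasets/summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
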