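#!/usr/bin/env Rscript
# Stage 6: polygenic berry-color scores.
#
# Scores every sample over the 19 color loci (skipping missing calls),
# places the archaeological samples within each color category of the
# modern panel's score distribution, and draws the white-vs-black score
# histogram with the ancient samples marked.

suppressPackageStartupMessages(library(vinekin))

cfg <- run_config(vcf = "scratch/sim/panel.vcf",
                  metadata = "scratch/sim/panel_samples.tsv",
                  effects = "scratch/sim/effects.tsv",
                  color_min_loci = 10,
                  out_dir = "results/color", seed = 42)
res <- run_color_report(cfg)

cat("panel score range:", round(range(res$scores$score, na.rm = TRUE), 2), "\n")
undef <- res$scores[res$scores$group == "archaeological" & !res$scores$defined, ]
if (nrow(undef) > 0)
  cat("excluded (fewer than", cfg$color_min_loci, "called effect loci):",
      paste0(undef$sample_id, " (", undef$n_loci_used, ")", collapse = ", "),
      "\n")
for (id in names(res$placement)) {
  pl <- res$placement[[id]]
  cat(id, "scored higher than:\n")
  for (catg in names(pl))
    cat(sprintf("  %5.1f%% of %s cultivars\n", 100 * pl[[catg]], catg))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  sc <- res$scores[!is.na(res$scores$color) &
                     res$scores$color %in% c("white", "black"), ]
  foc <- res$scores[res$scores$group == "archaeological" &
                      !is.na(res$scores$score), ]
  p <- ggplot(sc, aes(score, fill = color)) +
    geom_histogram(alpha = 0.6, position = "identity", bins = 25) +
    geom_vline(data = foc, aes(xintercept = score), linetype = 2) +
    geom_text(data = foc, aes(x = score, y = Inf, label = sample_id),
              vjust = 1.2, angle = 90, size = 3, inherit.aes = FALSE) +
    scale_fill_manual(values = c(white = "grey70", black = "grey20")) +
    labs(x = "polygenic color score", y = "accessions",
         title = "White vs black cultivar scores with archaeological samples") +
    theme_minimal()
  ggsave("results/color/score_histogram.png", p, width = 7, height = 4, dpi = 150)
  cat("figure written to results/color/score_histogram.png\n")
}
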