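# vinekin

Kinship, descent and berry-color inference for sparse grapevine genotype
panels.

Connecting archaeological grape pips to living cultivars is a relatedness
problem under severe sparsity: ancient samples yield genotype calls at only
a fraction of a SNP panel, at modest depth and with a per-allele error rate
around 0.3%, while the modern reference accessions are densely genotyped.
vinekin implements the full chain such a comparison needs, for population
geneticists and archaeobotanists working with diploid biallelic SNP data:

* **Dataset construction** — call-rate / depth / MAF filters with an
  auditable funnel, and the dual-dataset strategy that trades SNP count
  against low-coverage sample count (`apply_filters()`,
  `build_dual_datasets()`).
* **Kinship** — the KING-robust heterozygote-concordance estimator with
  IBS0 and relatedness classification (`king_robust()`, `kinship_matrix()`):

  φ = (N_het,het − 2·N_opp,hom) / (N_het(i) + N_het(j))

  Expected values: 1/2 for clones, 1/4 for outcross parent–offspring, 1/3
  for a parent versus its one-generation selfed offspring, 0 for unrelated
  pairs; IBS0 (opposite-homozygote fraction) is exactly 0 for error-free
  parent–offspring and clone pairs.
* **IBD sharing** — refined-IBD-style segment files summed into per-pair
  shared-bp matrices with heatmap orderings, plus a naive exact-match scan
  as a desk-scale oracle (`parse_ibd()`, `sharing_matrix()`,
  `order_samples()`, `naive_segments()`).
* **Descent** — directional genotype containment with a per-allele error
  allowance, the heterozygosity-ratio selfing-generation estimator
  ĝ = round(log2(H_parent / H_offspring)), and haplotype matching
  (`containment_test()`, `directionality()`, `selfing_generations()`,
  `haplotype_containment()`, `descent_report()`).
* **Berry color** — additive polygenic scores over an allele-effect table
  (grades white = 0 … black = 4) with reference-panel percentile placement
  (`polygenic_score()`, `percentile_placement()`).
* **Simulation** — a pedigree simulator (outcrossing, selfing, cloning,
  genotyping error, missingness, per-call depth, phased haplotypes with
  founder-ancestry tracking) that provides ground truth for every stage
  (`simulate_founders()`, `breed()`, `degrade()`, `simulate_color()`).

## Worked example

The `analysis/` scripts run the whole workflow on a synthetic panel of 40
modern accessions plus a planted clone pair and two "archaeological"
samples — one produced by selfing founder F1, one an outcross of F2 × F3 —
degraded with 0.33% per-allele error and 35–55% missingness on the ancient
samples:

```sh
Rscript analysis/01_simulate.R   # build the 43 x 6,896 panel
Rscript analysis/02_filter.R     # dual datasets (wide vs deep)
Rscript analysis/03_kinship.R    # KING-robust tables
Rscript analysis/04_ibd.R        # sharing matrix + orderings
Rscript analysis/05_descent.R    # containment / selfing evidence
Rscript analysis/06_colorscore.R # polygenic color placement
```

Stage 2 shows the dataset trade-off — the sparser ancient sample survives
only in the deep dataset:

```
  dataset n_samples n_loci
1    wide        42   6860
2    deep        43   2030
```

Stage 3 recovers the planted relationships (second degree and closer):

```
[wide] 42 samples, 6860 loci, 861 pairs; close pairs:
       id1 id2 n_compared   phi     ibs0         category
 CloneOfF5  F5       6860 0.489 0.000146  duplicate/clone
  AncientA  F1       4453 0.325 0.000449 parent-offspring
[deep] 43 samples, 2030 loci, 903 pairs; close pairs:
 CloneOfF5  F5       2030 0.488 0.000000  duplicate/clone
  AncientA  F1       2030 0.321 0.000493 parent-offspring
  AncientB  F3       2030 0.252 0.001478 parent-offspring
  AncientB  F2       2030 0.240 0.002956 parent-offspring
```

φ ≈ 0.49 with IBS0 ≈ 0 is the clone signature; AncientA–F1 sits near the
1/3 expected for a selfed offspring, and AncientB shows the 1/4 of an
outcross child to each of its two parents. Stage 5 adds the descent
direction and the selfing estimate:

```
F1 -> AncientA [parent-offspring]: a_contains_b; violations 20/4453 sites
  (rate 0.22%), reverse 829; het 1615:806 (ratio 0.499, g_hat 1)
CloneOfF5 -> F5 [duplicate/clone]: mutual; violations 49/6860 sites
  (rate 0.36%), reverse 60; het 2513:2502 (ratio 0.996, g_hat 0)
```

AncientA's genotypes are contained in F1 within the error allowance while
the reverse direction fails by ~40×, and the ~1:2 heterozygosity ratio
estimates one selfing generation — the signature of descent from that plant
alone. Stage 6 places the scoreable ancient sample against the modern color
categories (the sparser one is excluded for having too few called effect
loci):

```
excluded (fewer than 10 called effect loci): AncientB (7)
AncientA scored higher than:
    0.0% of black cultivars
   25.0% of white cultivars
```

i.e. AncientA sits at the light extreme of the panel, below every black,
red and rosé cultivar and most whites.

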