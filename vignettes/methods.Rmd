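---
title: "Kinship, descent and berry-color inference for sparse grapevine genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship, descent and berry-color inference for sparse grapevine genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinekin)
```

## The problem

Connecting archaeological plant remains to living cultivars is a relatedness
problem under severe data sparsity. Genotypes called from ancient grape pips
cover only a fraction of a SNP panel, at modest read depth and with a
non-negligible per-allele error rate, while the modern reference accessions
are densely genotyped. vinekin implements the chain of analyses that such a
comparison needs — dataset construction, pairwise kinship, IBD-segment
sharing, directional descent tests and polygenic berry-color scoring — with
a pedigree simulator that supplies ground truth for every stage.

## Dataset construction

Genotypes are held in a `geno_matrix`: alt-allele dosages (0/1/2/NA) for
samples × loci, with optional per-call depth, phased haplotypes and (for
simulated data) founder ancestry per allele copy. `apply_filters()` runs the
quality stages in a fixed, auditable order:

1. depth mask — calls below `min_depth` (default 5) in the named sequenced
   samples are set missing; array-derived panel genotypes are exempt;
2. locus call rate ≥ `min_locus_callrate` (default 0.75);
3. sample call rate ≥ `min_sample_callrate` (default 0.60);
4. minor-allele frequency ≥ `min_maf` (default 0.03) on called alleles,
   together with a stricter locus call rate (default 0.80).

MAF is computed after missingness masking, on called alleles only, and the
depth filter masks individual calls rather than dropping loci. Each stage
reports what it removed, so the dataset funnel is reconstructible for any
input.

`build_dual_datasets()` encodes the trade-off between SNP count and
low-coverage sample count. The *wide* dataset drops any focal
(archaeological) sample that fails the sample call-rate bar on the filtered
matrix, maximising loci for the remaining samples; the *deep* dataset keeps
every focal sample and restricts to loci called in all of them. The rule for
wide membership — a focal sample enters iff it passes `min_sample_callrate`
on the locus-filtered matrix — is the simplest mechanism that produces the
observed behaviour without an optimisation step; it is a package decision,
as no published algorithm exists for the split.

## Kinship

`king_robust()` implements the heterozygote-concordance estimator

$$\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N^{(i)}_{Aa} + N^{(j)}_{Aa}}$$

over sites called in both samples, where $N_{Aa,Aa}$ counts shared
heterozygotes, $N_{AA,aa}$ opposite homozygotes, and the denominator sums
the two samples' heterozygote counts. Because no population allele
frequencies enter, the estimator is robust to structure — the reason the
KING-robust variant is preferred for a panel mixing wild, feral and
cultivated material. Pedigree expectations: duplicates/clones $\phi = 1/2$
exactly (and it is exact in the estimator, not just in expectation, for
identical genotypes); outcross parent–offspring and full siblings $1/4$; a
parent versus its one-generation selfed offspring $1/3$, because at the
parent's $H$ heterozygous sites the offspring is heterozygous with
probability $1/2$ and opposite homozygosity is impossible, giving
$(H/2)/(H + H/2)$.

IBS0 — the fraction of compared sites with opposite homozygotes — is exactly
zero for error-free parent–offspring and clone pairs, which makes it the
natural gate on the first-degree category: `classify_relationship()` uses
the standard powers-of-two $\phi$ ranges
($>2^{-1.5}$ duplicate; $(2^{-2.5}, 2^{-1.5}]$ first degree, split into
parent–offspring iff IBS0 ≤ 0.01; then second and third degree) with every
threshold exposed in `kinship_thresholds()`. The published criteria
referenced for grapes are not reproduced verbatim here (they are in
supplementary material not distributed with the package); the defaults are
the widely used KING ranges and are documented as such. Pairs with fewer
than `min_compared` (default 200) jointly called sites are classified
"undetermined" rather than risking a call from noise — the relevant guard
for sparse ancient samples. Third-degree calls remain noise-prone at a few
thousand SNPs; the analysis drivers report from second degree up.

## IBD sharing

Haplotype-level IBD segments are consumed from refined-IBD-style files
(`parse_ibd()`, eight whitespace-delimited columns, LOD > 3 by default,
inclusive bp coordinates); detection itself — phasing, imputation,
probabilistic segment calling — is out of scope. `sharing_matrix()` sums
segment lengths over all four haplotype pairings of each sample pair, the
"summed lengths of shared haplotypes" relatedness measure; whether to merge
haplotype pairings per sample pair is not standardised, and summing all
pairings is the declared default. Heatmap orderings: average-linkage
hierarchical clustering on the distance $1 - s_{ij}/\max(s)$ (the metric is
a package choice — the transform is monotone in shared length and bounded —
and is configurable), or descending mean sharing with a focal sample set.

`naive_segments()` is a desk-scale oracle, not a detector: on error-free
phased data it emits maximal identical-allele runs above a span floor. For
whole-haplotype-copy relationships (clones) these runs coincide exactly with
the simulator's ancestry ground truth at any span floor large enough to
exclude chance runs; for mosaic gametes identity-by-state runs can extend
beyond identity-by-descent blocks, so the general guarantee is containment
of every true block, and the tests check exactly that.

## Descent arguments

Three bespoke pieces of evidence distinguish "descended from this plant and
it alone" from mere first-degree relatedness:

* **Directional containment** (`containment_test()`, `directionality()`):
  under Mendelian transmission every offspring allele copy must be present
  in the parent's genotype at that site. Violations are counted per allele
  copy — parent hom-ref vs offspring het is one violation, vs offspring
  hom-alt two, and a heterozygous parent cannot be violated — so the error
  rate is violations over $2 \times$ sites, matching per-allele error-rate
  arithmetic. A selfed offspring is contained in its parent but not
  conversely (it can be homozygous where the parent is heterozygous); clones
  are mutually contained; unrelated pairs fail both directions by orders of
  magnitude. The default allowance is a 0.5% per-allele rate, converted to a
  count; an observed violation count on real data is evidence about the
  error rate, not a threshold.
* **Heterozygosity ratio** (`selfing_generations()`): each selfing or
  clonal-breeding generation halves expected heterozygosity, so
  $\hat g = \mathrm{round}(\log_2 (H_\text{parent}/H_\text{offspring}))$.
  Counts are restricted to sites called in both samples, so differential
  missingness cannot masquerade as selfing — the conservative choice, made
  explicit here because the source analyses do not state one. The
  `compatible` flag tests the ratio against $(1/2)^{\hat g}$ within a ±25%
  multiplicative tolerance.
* **Haplotype matching** (`haplotype_containment()`): each offspring
  haplotype is compared against both parent haplotypes per chromosome,
  whole-chromosome best match, no recombination modelling. Exact matches
  arise for clones and for selfing without recombination; recombinant
  gametes produce intermediate mismatch fractions, which is why this is
  corroborating rather than primary evidence.

The descent report prints both the panel locus count and the
pairwise-complete site count, since which of the two a published "compared
sites" figure refers to is often ambiguous.

## Polygenic berry color

Berry color is graded white = 0, gray = 1, rosé = 2, red = 3, black = 4.
`polygenic_score()` sums effect-allele dosage × effect over the loci with a
genotype call; loci with missing calls are skipped, never imputed, and a
sample falling below `min_loci` called effect loci is flagged undefined
rather than scored. Dosage is the count of the effect allele; relabelling
the effect allele with a sign-flipped effect shifts every score by a
constant and preserves ranking, so the coding convention is immaterial.
`percentile_placement()` reports the fraction of a reference category's
scores strictly below the focal score, ties counted half — the half-tie rule
is declared, not inferred from the source, and avoids order dependence.

`fit_allele_effects()` exists for synthetic validation only: a per-locus
least-squares slope of grade on dosage with a Bonferroni-corrected t-test,
computed in closed form across loci (the tests cross-check it against
`stats::lm` locus by locus). It makes no claim to reproduce any published
GWAS loci.

## The simulator and what it does and does not emulate

`simulate_founders()` draws founders in Hardy–Weinberg proportions with
per-locus allele frequencies uniform on [0.05, 0.95] by default.
`breed()` extends the panel along a `pedigree_spec` of cross, self and
clone events; gametes follow a Markov walk between the parent's two
haplotypes with switch probability `recomb_rate` between adjacent loci
(0.5 = independent assortment, the default; 0 = whole-haplotype
transmission; the analysis drivers use 0.02 so transmitted tracts average
~50 loci and IBD segment logic is exercised on realistic block lengths).
Founder ancestry is tracked per allele copy, providing exact IBD ground
truth. `degrade()` applies the observation model: symmetric per-allele
flips (default rate 0.0033, i.e. 0.33%, the minimal per-allele error level
plausible for ancient-DNA genotype calls — at 6,896 diploid sites this
yields ≈45 flipped alleles in expectation), then per-sample missingness,
then Poisson per-call depth. Errors precede missingness because an
unobserved call cannot carry an error.

The simulator deliberately omits: linkage disequilibrium among founders,
genetic maps in cM, sequence reads, cytosine-deamination damage profiles,
reference bias and imputation artefacts. Passing tests therefore
demonstrate correctness of the estimators under their own model
assumptions, not robustness to every pathology of real ancient DNA.

`simulate_color()` adds Gaussian noise (default sd 0.35–0.5 grade units in
the drivers and tests) to the additive genetic value and clips to [0, 4];
the category is the nearest grade, ties rounding half up — a mapping the
package defines, since grading real berries needs no such rule. Clipping
matters for effect estimation: a planted slope of 2.0 spans the full grade
range across dosages 0–2, so the clipped grade attenuates the fitted slope
near the boundaries (to ≈1.8 at noise sd 0.5). The effect-recovery
validation therefore fits on the latent (unclipped) grade, where the
planted slope is identifiable; both values are returned so users can choose.

## Numerical and design choices

* One seed per generation step, all draws from R's default generator in a
  documented order; identical configurations are bit-identical.
* `king_robust()` returns `NA` (category "undetermined") when both samples
  lack heterozygous calls, rather than dividing by zero.
* `selfing_generations()` clamps $\hat g$ at 0 and flags the estimate when
  the parent has no heterozygous calls; a zero offspring heterozygote count
  is guarded with a one-count floor inside the logarithm.
* Loci are identified by (chrom, pos), 1-based as in VCF; alleles are taken
  as written and never strand-flipped.
* Monomorphic loci are skipped (with a logged count) by the effect
  estimator; a zero-residual fit with zero slope (constant grades) is
  assigned p = 1, not p = 0.
* Percentile ties take half weight; containment allowances given as rates
  are floored to whole allele counts.

## Validation scale

The test suite validates estimator identities at 10,000 loci (clone
$\phi = 1/2$ exact, outcross parent–offspring $1/4 \pm 0.02$, selfed
offspring $1/3 \pm 0.02$ against an independent Monte-Carlo oracle), the
one-generation heterozygosity ratio $0.5 \pm 0.03$, selfing-generation
recovery over 200 replicate chains across $g \in \{0,1,2,3\}$ (≥95%
exact), effect recovery at panel size 500, and an end-to-end run on a
simulated bundle with a planted clone pair and selfed descendant. The
analysis drivers use a 43-sample × 6,896-locus panel — the scale of the
motivating study's larger SNP dataset — and run in seconds.

## Known limitations

* The containment test assumes biallelic sites and diploid calls; it does
  not model genotype-calling asymmetries (e.g. allelic dropout toward
  reference) that could bias violations directionally in real aDNA.
* IBD detection is consumed, not performed; the naive scan is valid only on
  error-free phased data.
* The relatedness categories beyond first degree are noisy below ~5,000
  SNPs; the package reports them but the drivers treat third degree as
  unreliable.
* The color score is additive; dominance at the major color locus (as known
  for MybA) is not modelled, which is one reason the effect estimator is
  for synthetic validation only.
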