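#' Simulation configuration
#'
#' Describes a synthetic genotype panel: founder count, locus count, the
#' allele-frequency distribution of the founding population, the per-allele
#' genotyping error rate, per-sample missingness, and a mean per-call read
#' depth. Defaults emulate the structure of a targeted-enrichment grape panel:
#' thousands of biallelic SNPs, Hardy-Weinberg founders with intermediate
#' allele frequencies, a per-allele error rate of 0.33% and heavy per-sample
#' missingness for low-coverage (ancient) samples.
#'
#' @param n_founders number of unrelated founders drawn from the population.
#' @param n_loci number of independent biallelic loci (>= 1).
#' @param freq_range length-2 numeric; per-locus alt-allele frequencies are
#'   drawn uniformly from this interval. Alternatively pass `freq` to fix them.
#' @param freq optional numeric vector of per-locus alt-allele frequencies
#'   (length 1 or `n_loci`); overrides `freq_range`.
#' @param error_rate per-allele flip probability in `[0, 1]` applied by
#'   [degrade()]. Default 0.0033 (0.33%), the minimal per-allele error rate
#'   consistent with aDNA genotype calls at the depths modelled here.
#' @param missing_rate per-sample probability that a call is masked missing;
#'   a single number applied to all samples, or a named vector
#'   (sample id -> probability) so low-coverage samples can be sparser.
#' @param depth_mean mean read depth per call; depths are Poisson around this.
#' @param locus_spacing_bp fixed distance between consecutive loci, used to
#'   assign positions so segment lengths are expressible in base pairs.
#' @param seed integer seed; identical configs yield bit-identical panels.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 20, n_loci = 1000,
                       freq_range = c(0.05, 0.95), freq = NULL,
                       error_rate = 0.0033, missing_rate = 0,
                       depth_mean = 30, locus_spacing_bp = 1000L,
                       seed = 1L) {
  stopifnot(n_founders >= 1, n_loci >= 1, depth_mean >= 0, locus_spacing_bp >= 1)
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (any(missing_rate < 0 | missing_rate > 1)) stop("missing_rate must be in [0, 1]")
  if (!is.null(freq)) {
    if (any(freq < 0 | freq > 1)) stop("allele frequencies must be in [0, 1]")
    if (!length(freq) %in% c(1L, n_loci)) stop("freq must have length 1 or n_loci")
  } else {
    stopifnot(length(freq_range) == 2, all(freq_range >= 0 & freq_range <= 1),
              freq_range[1] <= freq_range[2])
  }
  structure(list(n_founders = as.integer(n_founders), n_loci = as.integer(n_loci),
                 freq_range = freq_range, freq = freq, error_rate = error_rate,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 locus_spacing_bp = as.integer(locus_spacing_bp),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_locus_table <- function(config) {
  data.frame(chrom = "chr1",
             pos = seq_len(config$n_loci) * config$locus_spacing_bp,
             ref = "A", alt = "T", stringsAsFactors = FALSE)
}

#' Simulate unrelated Hardy-Weinberg founders
#'
#' Each founder receives two haplotypes; at locus l each haplotype carries the
#' alt allele independently with that locus's frequency, so genotypes are in
#' Hardy-Weinberg proportions. Founder haplotypes get globally unique ancestry
#' ids (founder i's haplotypes are `2i-1` and `2i`) so descent of every allele
#' copy in a pedigree can be traced back here.
#'
#' @param config a [sim_config()]
#' @return A phased [geno_matrix()] with ancestry tracking; samples are named
#'   `F1, F2, ...` with group "cultivated".
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$freq
  if (is.null(p)) p <- stats::runif(config$n_loci, config$freq_range[1], config$freq_range[2])
  p <- rep_len(p, config$n_loci)
  n <- config$n_founders
  L <- config$n_loci
  # one Bernoulli draw per haplotype per locus, row-major by sample
  hap1 <- matrix(stats::rbinom(n * L, 1L, rep(p, each = n)), nrow = n)
  hap2 <- matrix(stats::rbinom(n * L, 1L, rep(p, each = n)), nrow = n)
  anc1 <- matrix(rep(2L * seq_len(n) - 1L, L), nrow = n)
  anc2 <- matrix(rep(2L * seq_len(n), L), nrow = n)
  ids <- paste0("F", seq_len(n))
  samples <- data.frame(sample_id = ids, group = "cultivated",
                        region = "simulated", color = NA_character_,
                        stringsAsFactors = FALSE)
  geno_matrix(gt = hap1 + hap2, loci = .sim_locus_table(config),
              samples = samples, hap1 = hap1, hap2 = hap2,
              anc1 = anc1, anc2 = anc2)
}

#' Pedigree specification
#'
#' An ordered list of breeding events. `cross` takes two parents and one
#' uniformly chosen allele per parent per locus; `self` takes two independent
#' gametes from a single parent (self-fertilisation); `clone` copies the
#' parent's genotype exactly (vegetative propagation). Parents must be
#' declared (as founders or earlier children) before use.
#'
#' @param events data.frame with columns `child`, `kind` (cross/self/clone),
#'   `parent1`, `parent2` (`parent2` is `NA` for self and clone).
#' @return data.frame of class `pedigree_spec`
#' @export
pedigree_spec <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("child", "kind", "parent1") %in% names(events)))
  if (!"parent2" %in% names(events)) events$parent2 <- NA_character_
  bad <- !events$kind %in% c("cross", "self", "clone")
  if (any(bad)) stop("unknown event kind: ", paste(unique(events$kind[bad]), collapse = ", "))
  two <- events$kind == "cross"
  if (any(is.na(events$parent2[two]))) stop("cross events need two parents")
  if (any(!is.na(events$parent2[!two]))) stop("self/clone events take one parent")
  if (anyDuplicated(events$child)) stop("duplicate child id")
  structure(events, class = c("pedigree_spec", "data.frame"))
}

# one gamete: Markov walk along the locus order between the parent's two
# haplotypes; switch probability r between adjacent loci. r = 0.5 makes loci
# assort independently, r = 0 transmits one whole haplotype.
.gamete <- function(h1, h2, a1, a2, r = 0.5) {
  n <- length(h1)
  switches <- c(stats::runif(1) < 0.5, stats::runif(n - 1) < r)
  pick <- cumsum(switches) %% 2 == 0
  list(hap = ifelse(pick, h1, h2), anc = ifelse(pick, a1, a2))
}

#' Breed offspring along a pedigree
#'
#' Extends a founder panel with the children described in `pedigree`, in
#' order. A cross child receives one gamete per parent, a selfed child two
#' independent gametes from its single parent, and a clone an exact copy.
#' By default loci assort independently (`recomb_rate = 0.5`: each gamete
#' allele is a fresh uniform pick between the parent's two haplotypes);
#' `recomb_rate = 0` transmits whole haplotypes without recombination, and
#' intermediate values give blocky gametes with geometric tract lengths.
#' Haplotype ancestry is propagated, so ground-truth IBD of any pair is
#' recoverable with [true_ibd_segments()].
#'
#' @param founders phased [geno_matrix()] from [simulate_founders()]
#' @param pedigree a [pedigree_spec()]
#' @param seed integer seed for the gamete draws
#' @param recomb_rate probability of switching source haplotype between
#'   adjacent loci, in `[0, 0.5]`
#' @return A phased [geno_matrix()] containing founders followed by children.
#' @export
breed <- function(founders, pedigree, seed = 1L, recomb_rate = 0.5) {
  stopifnot(inherits(founders, "geno_matrix"), inherits(pedigree, "pedigree_spec"),
            recomb_rate >= 0, recomb_rate <= 0.5)
  if (is.null(founders$hap1)) stop("founders must be phased (use simulate_founders)")
  set.seed(as.integer(seed))
  hap1 <- founders$hap1; hap2 <- founders$hap2
  anc1 <- founders$anc1; anc2 <- founders$anc2
  ids <- founders$samples$sample_id
  rows <- list()
  for (k in seq_len(nrow(pedigree))) {
    ev <- pedigree[k, ]
    i1 <- match(ev$parent1, ids)
    if (is.na(i1)) stop("unknown parent id: ", ev$parent1)
    if (ev$kind == "cross") {
      i2 <- match(ev$parent2, ids)
      if (is.na(i2)) stop("unknown parent id: ", ev$parent2)
      g1 <- .gamete(hap1[i1, ], hap2[i1, ], anc1[i1, ], anc2[i1, ], recomb_rate)
      g2 <- .gamete(hap1[i2, ], hap2[i2, ], anc1[i2, ], anc2[i2, ], recomb_rate)
    } else if (ev$kind == "self") {
      g1 <- .gamete(hap1[i1, ], hap2[i1, ], anc1[i1, ], anc2[i1, ], recomb_rate)
      g2 <- .gamete(hap1[i1, ], hap2[i1, ], anc1[i1, ], anc2[i1, ], recomb_rate)
    } else { # clone
      g1 <- list(hap = hap1[i1, ], anc = anc1[i1, ])
      g2 <- list(hap = hap2[i1, ], anc = anc2[i1, ])
    }
    hap1 <- rbind(hap1, g1$hap); hap2 <- rbind(hap2, g2$hap)
    anc1 <- rbind(anc1, g1$anc); anc2 <- rbind(anc2, g2$anc)
    ids <- c(ids, ev$child)
  }
  child_meta <- data.frame(sample_id = pedigree$child, stringsAsFactors = FALSE)
  for (cn in setdiff(names(founders$samples), "sample_id"))
    child_meta[[cn]] <- if (cn == "group") "cultivated" else
      founders$samples[[cn]][0][NA_integer_]
  samples <- rbind(founders$samples, child_meta[names(founders$samples)])
  geno_matrix(gt = hap1 + hap2, loci = founders$loci, samples = samples,
              hap1 = hap1, hap2 = hap2, anc1 = anc1, anc2 = anc2)
}

#' Degrade a panel with genotyping error, missingness and finite depth
#'
#' Emulates the observational process: each allele copy flips (ref<->alt)
#' independently with `config$error_rate`; each call is then masked missing
#' with the sample's missing rate; per-call depths are drawn Poisson around
#' `config$depth_mean`. Errors are applied on the phased haplotypes before
#' missingness, matching a per-allele (not per-genotype) error model. The
#' input matrix is not modified. Ancestry is dropped: after error the allele
#' no longer faithfully reports its founder copy.
#'
#' @param G a phased [geno_matrix()]
#' @param config a [sim_config()] supplying `error_rate`, `missing_rate`,
#'   `depth_mean`
#' @param seed integer seed (separate from the panel-generation seed so
#'   degradation can be re-rolled on a fixed panel)
#' @return A new phased [geno_matrix()] with depth and without ancestry.
#' @export
degrade <- function(G, config, seed = config$seed) {
  stopifnot(inherits(G, "geno_matrix"), inherits(config, "sim_config"))
  if (is.null(G$hap1)) stop("degrade() needs phased input")
  set.seed(as.integer(seed))
  n <- n_samples(G); L <- n_loci(G)
  hap1 <- G$hap1; hap2 <- G$hap2
  if (config$error_rate > 0) {
    f1 <- matrix(stats::runif(n * L) < config$error_rate, n, L)
    f2 <- matrix(stats::runif(n * L) < config$error_rate, n, L)
    hap1 <- ifelse(f1, 1L - hap1, hap1)
    hap2 <- ifelse(f2, 1L - hap2, hap2)
  }
  mr <- config$missing_rate
  if (length(mr) > 1 || !is.null(names(mr))) {
    rate <- rep(0, n)
    idx <- match(names(mr), G$samples$sample_id)
    if (anyNA(idx)) stop("missing_rate names must be sample ids")
    rate[idx] <- mr
  } else {
    rate <- rep(mr, n)
  }
  miss <- matrix(stats::runif(n * L) < rate, n, L)  # rate recycles down columns
  depth <- matrix(stats::rpois(n * L, config$depth_mean), n, L)
  hap1[miss] <- NA_integer_
  hap2[miss] <- NA_integer_
  depth[miss] <- 0L
  geno_matrix(gt = hap1 + hap2, loci = G$loci, samples = G$samples,
              depth = depth, hap1 = hap1, hap2 = hap2)
}

.color_names <- c("white", "gray", "rose", "red", "black")

#' Simulate an ordinal berry-color phenotype
#'
#' The latent color grade of a sample is the additive genetic value
#' `sum(dosage x effect)` over the effect loci plus Gaussian noise. The
#' observed grade clips the latent value to the ordinal range `[0, 4]`
#' (white = 0 ... black = 4) and the category is the nearest grade, ties
#' rounding half up.
#'
#' @param G a [geno_matrix()]
#' @param effects an [effect_table()] whose loci are all present in `G`
#' @param noise_sd standard deviation of the environmental noise, in
#'   color-grade units
#' @param seed integer seed
#' @return data.frame with `sample_id`, `latent` (unclipped genetic value +
#'   noise), `grade` (clipped to `[0, 4]`), `category` (white/gray/rose/red/
#'   black).
#' @export
simulate_color <- function(G, effects, noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(G, "geno_matrix"), inherits(effects, "effect_table"))
  idx <- match_effect_loci(G, effects)
  if (anyNA(idx)) stop("effect loci absent from genotype matrix")
  set.seed(as.integer(seed))
  dos <- effect_dosage(G, effects, idx)
  genetic <- as.numeric(dos %*% effects$effect)
  latent <- genetic + stats::rnorm(n_samples(G), 0, noise_sd)
  grade <- pmin(pmax(latent, 0), 4)
  cat_idx <- floor(grade + 0.5) + 1L  # nearest grade, ties round half up
  data.frame(sample_id = G$samples$sample_id, latent = latent, grade = grade,
             category = .color_names[cat_idx], stringsAsFactors = FALSE)
}

#' Write a simulated bundle to disk
#'
#' Emits the standard file set downstream stages read: a VCF (phased GT and
#' per-call DP when available), a sample-metadata TSV (sample_id, group,
#' color) and, when a pedigree is given, a ground-truth pedigree TSV.
#'
#' @param G a [geno_matrix()]
#' @param dir output directory (created if needed)
#' @param pedigree optional [pedigree_spec()] written as truth
#' @param prefix file-name prefix
#' @return Invisibly, a named list of the paths written.
#' @export
write_sim_bundle <- function(G, dir, pedigree = NULL, prefix = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, paste0(prefix, ".vcf")),
                metadata = file.path(dir, paste0(prefix, "_samples.tsv")))
  write_vcf(G, paths$vcf)
  meta <- G$samples
  utils::write.table(meta, paths$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pedigree)) {
    paths$pedigree <- file.path(dir, paste0(prefix, "_pedigree.tsv"))
    utils::write.table(as.data.frame(pedigree), paths$pedigree, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
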