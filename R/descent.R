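#' Directional genotype-containment test
#'
#' Tests whether an offspring's genotypes are "contained" in a putative
#' parent: under Mendelian transmission (including selfing and cloning),
#' every offspring allele copy must exist in the parent's genotype at that
#' site. A violating allele is an offspring allele copy absent from the
#' parent: parent hom-ref vs offspring het = 1 violation, vs offspring
#' hom-alt = 2; a heterozygous parent can never be violated. Sites missing
#' in either sample are skipped. The pair is declared contained when the
#' violating-allele count stays within an allowance for genotyping error,
#' expressed either as a maximum count (`max_violations`) or as a maximum
#' per-allele rate (`max_rate`, violations over `2 * n_sites_compared`).
#'
#' @param parent,offspring integer dosage vectors of equal length
#' @param max_rate maximum tolerated per-allele violation rate (default
#'   0.005, i.e. 0.5%); ignored when `max_violations` is given
#' @param max_violations optional absolute allowance in allele copies
#' @return list of class `containment_result`: `n_sites_compared`,
#'   `n_violating_alleles`, `error_rate` (violations / (2 * sites)),
#'   `allowance` (the count actually applied), `contained`.
#' @export
containment_test <- function(parent, offspring, max_rate = 0.005,
                             max_violations = NULL) {
  if (length(parent) != length(offspring))
    stop("genotype vectors differ in length")
  ok <- !is.na(parent) & !is.na(offspring)
  p <- parent[ok]; o <- offspring[ok]
  viol <- ifelse(p == 1L, 0L, ifelse(p == 0L, o, 2L - o))
  n_viol <- sum(viol)
  n_sites <- length(p)
  allowance <- if (!is.null(max_violations)) max_violations
               else floor(max_rate * 2 * n_sites)
  structure(list(
    n_sites_compared = n_sites,
    n_violating_alleles = n_viol,
    error_rate = if (n_sites > 0) n_viol / (2 * n_sites) else NA_real_,
    allowance = allowance,
    contained = n_viol <= allowance
  ), class = "containment_result")
}

#' Containment directionality verdict
#'
#' Runs [containment_test()] in both directions and reports which sample's
#' genotypes contain the other's. `a_contains_b` alone is the signature of b
#' descending from a (and a alone): selfed offspring can be homozygous where
#' the parent is heterozygous, but never carry an allele the parent lacks,
#' so containment fails in the reverse direction. Clones are `mutual`;
#' unrelated pairs are `neither`.
#'
#' @param a,b integer dosage vectors
#' @inheritParams containment_test
#' @return list with `verdict` (a_contains_b / b_contains_a / mutual /
#'   neither) and the two `containment_result`s (`ab`, `ba`).
#' @export
directionality <- function(a, b, max_rate = 0.005, max_violations = NULL) {
  ab <- containment_test(a, b, max_rate, max_violations)
  ba <- containment_test(b, a, max_rate, max_violations)
  verdict <- if (ab$contained && ba$contained) "mutual"
             else if (ab$contained) "a_contains_b"
             else if (ba$contained) "b_contains_a"
             else "neither"
  list(verdict = verdict, ab = ab, ba = ba)
}

#' Selfing-generation estimate from the heterozygosity ratio
#'
#' Each selfing (or clonal-breeding) generation halves expected
#' heterozygosity, so the offspring/parent ratio of heterozygous-site counts
#' estimates the number of selfing generations as
#' `g_hat = round(log2(parent_het / offspring_het))`. Counts are restricted
#' to sites called in both samples so differential missingness cannot drive
#' the ratio. `compatible` reports whether the observed ratio lies within a
#' multiplicative tolerance of the ideal `(1/2)^g_hat`.
#'
#' @param parent,offspring integer dosage vectors of equal length
#' @param tol multiplicative tolerance on the ratio (default 0.25, i.e.
#'   within 25% of the ideal halving)
#' @return list of class `selfing_estimate`: `het_parent`, `het_offspring`,
#'   `ratio`, `g_hat`, `compatible`. `g_hat` is `NA` (flagged) when the
#'   parent has no heterozygous calls.
#' @export
selfing_generations <- function(parent, offspring, tol = 0.25) {
  if (length(parent) != length(offspring))
    stop("genotype vectors differ in length")
  ok <- !is.na(parent) & !is.na(offspring)
  het_p <- sum(parent[ok] == 1L)
  het_o <- sum(offspring[ok] == 1L)
  if (het_p == 0) {
    return(structure(list(het_parent = 0L, het_offspring = het_o,
                          ratio = NA_real_, g_hat = NA_integer_,
                          compatible = NA), class = "selfing_estimate"))
  }
  ratio <- het_o / het_p
  g_hat <- max(0L, as.integer(round(log2(het_p / max(het_o, 1L)))))
  compatible <- is.finite(ratio) && ratio > 0 &&
    abs(ratio / 0.5^g_hat - 1) <= tol
  structure(list(het_parent = het_p, het_offspring = het_o, ratio = ratio,
                 g_hat = g_hat, compatible = compatible),
            class = "selfing_estimate")
}

#' Match offspring haplotypes to parent haplotypes
#'
#' For each offspring haplotype and chromosome, compares against both parent
#' haplotypes over the sites phased and called in both samples, and reports
#' the best-matching parent haplotype with its mismatch fraction. For a
#' selfed or cloned offspring without recombination the best matches are
#' exact (mismatch 0); unrelated samples mismatch at roughly the
#' heterozygosity-driven background rate.
#'
#' @param G a phased [geno_matrix()]
#' @param parent_id,offspring_id sample ids
#' @return data.frame with `chrom`, `offspring_hap`, `best_parent_hap`,
#'   `mismatch` (fraction), `n_sites`.
#' @export
haplotype_containment <- function(G, parent_id, offspring_id) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.null(G$hap1) || is.null(G$hap2)) stop("phased genotypes required")
  i <- match(parent_id, G$samples$sample_id)
  j <- match(offspring_id, G$samples$sample_id)
  if (is.na(i) || is.na(j)) stop("unknown sample id")
  out <- list()
  for (ch in unique(G$loci$chrom)) {
    sel <- G$loci$chrom == ch
    p_h <- list(G$hap1[i, sel], G$hap2[i, sel])
    o_h <- list(G$hap1[j, sel], G$hap2[j, sel])
    for (oh in 1:2) {
      mm <- vapply(1:2, function(ph) {
        ok <- !is.na(o_h[[oh]]) & !is.na(p_h[[ph]])
        if (!any(ok)) return(NA_real_)
        mean(o_h[[oh]][ok] != p_h[[ph]][ok])
      }, numeric(1))
      best <- which.min(mm)
      ok_n <- sum(!is.na(o_h[[oh]]) & !is.na(p_h[[best]]))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, offspring_hap = oh, best_parent_hap = best,
        mismatch = mm[best], n_sites = ok_n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Full descent report for a putative parent-offspring pair
#'
#' Bundles both containment directions, the selfing-generation estimate and
#' (when phase is available) the haplotype match table, alongside the
#' kinship coefficient and IBS0 of the pair -- the complete evidence set for
#' a descent claim. Reports both the panel-wide locus count and the
#' pairwise-complete site count so the comparison base is explicit.
#'
#' @param G a [geno_matrix()]
#' @param parent_id,offspring_id sample ids
#' @inheritParams containment_test
#' @return list of class `descent_report`.
#' @export
descent_report <- function(G, parent_id, offspring_id, max_rate = 0.005,
                           max_violations = NULL) {
  p <- genotypes_of(G, parent_id)
  o <- genotypes_of(G, offspring_id)
  dir <- directionality(p, o, max_rate, max_violations)
  cnt <- pair_counts(p, o)
  hap <- if (!is.null(G$hap1)) haplotype_containment(G, parent_id, offspring_id)
         else NULL
  structure(list(
    parent_id = parent_id, offspring_id = offspring_id,
    n_loci_panel = n_loci(G),
    n_sites_compared = cnt$n_compared,
    directionality = dir$verdict,
    containment_parent_to_offspring = dir$ab,
    containment_offspring_to_parent = dir$ba,
    selfing = selfing_generations(p, o),
    phi = king_robust(cnt), ibs0 = ibs0(cnt),
    haplotype_match = hap
  ), class = "descent_report")
}
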