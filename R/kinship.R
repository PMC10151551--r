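#' Pairwise genotype-concordance counts
#'
#' Counts, over the sites called in both samples, the quantities the
#' KING-robust kinship estimator needs: shared heterozygotes, opposite
#' homozygotes (dosage 0 vs 2 -- the IBS0 events), and each sample's
#' heterozygote count. Sites missing in either sample are excluded from every
#' count.
#'
#' @param gi,gj integer dosage vectors of equal length (0/1/2/NA)
#' @return A list of class `pair_counts`: `n_compared`, `n_het_het`,
#'   `n_opp_hom`, `n_het_i`, `n_het_j`.
#' @export
pair_counts <- function(gi, gj) {
  if (length(gi) != length(gj)) stop("genotype vectors differ in length")
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  structure(list(
    n_compared = length(gi),
    n_het_het = sum(gi == 1L & gj == 1L),
    n_opp_hom = sum(abs(gi - gj) == 2L),
    n_het_i = sum(gi == 1L),
    n_het_j = sum(gj == 1L)
  ), class = "pair_counts")
}

#' KING-robust kinship coefficient
#'
#' The heterozygote-concordance estimator
#' `phi = (n_het_het - 2 * n_opp_hom) / (n_het_i + n_het_j)`,
#' robust to population structure because it never uses population allele
#' frequencies. Expected values: 0.5 for duplicates/clones, 0.25 for outcross
#' parent-offspring or full siblings, 1/3 for a parent versus its
#' one-generation selfed offspring, 0 for unrelated pairs.
#'
#' @param counts a [pair_counts()]
#' @return The kinship coefficient, or `NA` when both samples have zero
#'   heterozygous calls (undefined denominator).
#' @export
king_robust <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  den <- counts$n_het_i + counts$n_het_j
  if (den == 0) return(NA_real_)
  (counts$n_het_het - 2 * counts$n_opp_hom) / den
}

#' IBS0 proportion
#'
#' Fraction of compared sites at which the two samples are opposite
#' homozygotes; zero is diagnostic of parent-offspring and duplicate pairs
#' because Mendelian transmission guarantees one shared allele per site.
#'
#' @param counts a [pair_counts()]
#' @return proportion in `[0, 1]`, `NA` when no sites compared
#' @export
ibs0 <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  if (counts$n_compared == 0) return(NA_real_)
  counts$n_opp_hom / counts$n_compared
}

#' Relatedness-classification thresholds
#'
#' The standard powers-of-two kinship ranges: phi above `2^-1.5` (~0.354)
#' duplicate/clone; `(2^-2.5, 2^-1.5]` first degree, split into
#' parent-offspring (IBS0 at or below `ibs0_po_max`) versus other first
#' degree; `(2^-3.5, 2^-2.5]` second degree; `(2^-4.5, 2^-3.5]` third
#' degree; below that, unrelated. Pairs with fewer than `min_compared`
#' jointly called sites are left undetermined -- the relevant guard for
#' sparse ancient samples.
#'
#' @param duplicate,first,second,third lower phi bounds of each category
#' @param ibs0_po_max maximum IBS0 for the parent-offspring call
#' @param min_compared minimum jointly called sites for any call
#' @return list of class `kinship_thresholds`
#' @export
kinship_thresholds <- function(duplicate = 2^-1.5, first = 2^-2.5,
                               second = 2^-3.5, third = 2^-4.5,
                               ibs0_po_max = 0.01, min_compared = 200L) {
  stopifnot(duplicate > first, first > second, second > third, third > 0)
  structure(list(duplicate = duplicate, first = first, second = second,
                 third = third, ibs0_po_max = ibs0_po_max,
                 min_compared = as.integer(min_compared)),
            class = "kinship_thresholds")
}

#' Classify a pair's relatedness from phi and IBS0
#'
#' @param phi kinship coefficient (possibly `NA`)
#' @param ibs0 IBS0 proportion
#' @param thresholds a [kinship_thresholds()]
#' @param n_compared jointly called sites (optional; triggers
#'   "undetermined" below the threshold minimum)
#' @return One of "duplicate/clone", "parent-offspring", "first-degree-other",
#'   "second-degree", "third-degree", "unrelated", "undetermined".
#' @export
classify_relationship <- function(phi, ibs0, thresholds = kinship_thresholds(),
                                  n_compared = Inf) {
  t <- thresholds
  if (is.na(phi) || is.na(ibs0) || n_compared < t$min_compared)
    return("undetermined")
  if (phi > t$duplicate) return("duplicate/clone")
  if (phi > t$first) {
    if (ibs0 <= t$ibs0_po_max) return("parent-offspring")
    return("first-degree-other")
  }
  if (phi > t$second) return("second-degree")
  if (phi > t$third) return("third-degree")
  "unrelated"
}

#' All-pairs kinship table
#'
#' Computes [pair_counts()], [king_robust()], [ibs0()] and
#' [classify_relationship()] for every unordered sample pair. The result is
#' symmetric by construction (each pair reported once) and invariant to the
#' sample order of the input.
#'
#' @param G a [geno_matrix()] with at least two samples
#' @param thresholds a [kinship_thresholds()]
#' @return data.frame with `id1`, `id2`, `n_compared`, `n_het_het`,
#'   `n_opp_hom`, `phi`, `ibs0`, `category`.
#' @export
kinship_matrix <- function(G, thresholds = kinship_thresholds()) {
  stopifnot(inherits(G, "geno_matrix"))
  n <- n_samples(G)
  if (n < 2) stop("need at least two samples")
  ids <- G$samples$sample_id
  ord <- order(ids)  # canonical order: output independent of input order
  gt <- G$gt[ord, , drop = FALSE]
  ids <- ids[ord]
  pairs <- utils::combn(n, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cnt <- pair_counts(gt[i, ], gt[j, ])
    phi <- king_robust(cnt)
    ib <- ibs0(cnt)
    data.frame(id1 = ids[i], id2 = ids[j],
               n_compared = cnt$n_compared, n_het_het = cnt$n_het_het,
               n_opp_hom = cnt$n_opp_hom,
               phi = phi, ibs0 = ib,
               category = classify_relationship(phi, ib, thresholds,
                                                cnt$n_compared),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
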