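#' Per-locus allele-effect table for berry color
#'
#' Holds the loci of a color GWAS with the estimated effect of each effect
#' allele, in color-grade units per allele copy (grades 0 = white ... 4 =
#' black). In the real analysis this table is consumed as published; for
#' synthetic validation it can be estimated with [fit_allele_effects()].
#'
#' @param chrom,pos locus coordinates (1-based); loci must be unique
#' @param effect_allele the allele whose dosage is weighted ("ref" or "alt",
#'   or a literal base matching one of the locus alleles when attached to a
#'   genotype matrix)
#' @param effect numeric effect size per allele copy; must be finite
#' @param pvalue optional association p-value
#' @return data.frame of class `effect_table`
#' @export
effect_table <- function(chrom, pos, effect_allele, effect, pvalue = NA_real_) {
  if (length(chrom) == 0) stop("empty effect table")
  tab <- data.frame(chrom = chrom, pos = pos, effect_allele = effect_allele,
                    effect = effect, pvalue = rep_len(pvalue, length(chrom)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab[c("chrom", "pos")])) stop("duplicate effect loci")
  if (any(!is.finite(tab$effect))) stop("effect sizes must be finite")
  structure(tab, class = c("effect_table", "data.frame"))
}

#' Read / write an effect table as TSV
#' @param path file path; columns chrom, pos, effect_allele, effect, pvalue
#' @return an [effect_table()]
#' @export
read_effect_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  effect_table(tab$chrom, tab$pos, tab$effect_allele, tab$effect,
               if ("pvalue" %in% names(tab)) tab$pvalue else NA_real_)
}

#' @rdname read_effect_table
#' @param effects an [effect_table()]
#' @export
write_effect_table <- function(effects, path) {
  utils::write.table(as.data.frame(effects), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @keywords internal
match_effect_loci <- function(G, effects) {
  match(paste(effects$chrom, effects$pos),
        paste(G$loci$chrom, G$loci$pos))
}

# dosage of the effect allele (columns follow the effect table); NA where
# the genotype call is missing
#' @keywords internal
effect_dosage <- function(G, effects, idx = match_effect_loci(G, effects)) {
  ok <- !is.na(idx)
  dos <- matrix(NA_real_, n_samples(G), nrow(effects))
  dos[, ok] <- G$gt[, idx[ok], drop = FALSE]
  # alt dosage is stored; effect allele "ref" (or the ref base) counts 2 - dosage
  ea <- effects$effect_allele
  flip <- ea == "ref"
  lit <- !ea %in% c("ref", "alt")
  flip[lit] <- ea[lit] == G$loci$ref[idx[lit]]
  flip[is.na(flip)] <- FALSE
  dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  dos
}

#' Additive polygenic color score
#'
#' For each sample, sums effect-allele dosage times effect size over the loci
#' with a genotype call; loci with a missing call are skipped (no
#' imputation). A sample whose usable locus count falls below `min_loci` is
#' flagged undefined (`NA` score) rather than scored on too few loci.
#'
#' @param G a [geno_matrix()]
#' @param effects an [effect_table()]
#' @param min_loci minimum called effect loci for a defined score
#' @return data.frame with `sample_id`, `score`, `n_loci_used`, `defined`.
#' @export
polygenic_score <- function(G, effects, min_loci = 1L) {
  stopifnot(inherits(G, "geno_matrix"), inherits(effects, "effect_table"))
  dos <- effect_dosage(G, effects)
  used <- !is.na(dos)
  score <- as.numeric((ifelse(used, dos, 0)) %*% effects$effect)
  n_used <- rowSums(used)
  defined <- n_used >= min_loci
  score[!defined] <- NA_real_
  data.frame(sample_id = G$samples$sample_id, score = score,
             n_loci_used = n_used, defined = defined,
             stringsAsFactors = FALSE)
}

#' Percentile placement of a score within reference categories
#'
#' Places a score within each reference category's score distribution,
#' reporting the fraction of reference scores strictly below it, with ties
#' counted half (so a score equal to every reference value sits at 0.5).
#'
#' @param score a single numeric score
#' @param reference_scores numeric vector of reference scores
#' @param reference_category category label per reference score (optional; a
#'   single category is assumed when omitted)
#' @return named numeric vector of percentile-below values in `[0, 1]`, one
#'   per category.
#' @export
percentile_placement <- function(score, reference_scores, reference_category = NULL) {
  stopifnot(length(score) == 1, is.finite(score))
  if (is.null(reference_category))
    reference_category <- rep("all", length(reference_scores))
  if (length(reference_scores) == 0) stop("empty reference")
  keep <- !is.na(reference_scores)
  reference_scores <- reference_scores[keep]
  reference_category <- reference_category[keep]
  out <- vapply(split(reference_scores, reference_category), function(ref) {
    if (length(ref) == 0) stop("empty reference category")
    (sum(ref < score) + 0.5 * sum(ref == score)) / length(ref)
  }, numeric(1))
  out
}

#' Estimate per-locus allele effects from ordinal color grades
#'
#' Fits, at every locus, the least-squares slope of grade (0-4) on alt-allele
#' dosage, with the usual t-test p-value, and keeps loci significant after
#' Bonferroni correction. This is a deliberately simple single-locus
#' estimator for validating the scoring machinery on synthetic panels; it is
#' not a substitute for a proper GWAS on real data.
#'
#' Monomorphic loci (zero dosage variance among graded samples) cannot be
#' fit and are skipped; their count is reported as an attribute.
#'
#' @param G a [geno_matrix()] of the reference panel
#' @param grades numeric color grades, one per sample
#' @param alpha per-test significance level before correction
#' @param n_tests number of tests for the Bonferroni correction (defaults to
#'   the number of testable loci)
#' @return An [effect_table()] of the retained loci (effect allele "alt"),
#'   with attributes `n_skipped` (monomorphic) and `n_tests`.
#' @export
fit_allele_effects <- function(G, grades, alpha = 5e-6, n_tests = NULL) {
  stopifnot(inherits(G, "geno_matrix"), length(grades) == n_samples(G))
  if (anyNA(grades)) stop("grades required for all panel samples")
  gt <- G$gt
  y <- grades
  n <- colSums(!is.na(gt))
  # closed-form simple regression per locus over non-missing calls
  sum_x <- colSums(gt, na.rm = TRUE)
  sum_y <- colSums(ifelse(is.na(gt), 0, y))        # y recycles down columns
  sum_xy <- colSums(gt * y, na.rm = TRUE)
  sum_x2 <- colSums(gt * gt, na.rm = TRUE)
  sum_y2 <- colSums(ifelse(is.na(gt), 0, y * y))
  sxx <- sum_x2 - sum_x^2 / n
  sxy <- sum_xy - sum_x * sum_y / n
  syy <- sum_y2 - sum_y^2 / n
  mono <- !is.na(sxx) & sxx <= 0 | n < 3
  slope <- ifelse(mono, NA_real_, sxy / sxx)
  rss <- pmax(syy - slope * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- slope / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  # zero residual variance: a non-zero slope is a perfect fit, a zero slope
  # (constant grades) carries no evidence at all
  pval[which(se == 0 & slope != 0)] <- 0
  pval[which(se == 0 & slope == 0)] <- 1
  n_skipped <- sum(mono)
  if (n_skipped > 0)
    message(n_skipped, " monomorphic loci skipped")
  if (is.null(n_tests)) n_tests <- sum(!mono)
  keep <- !mono & pval < alpha / n_tests
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no locus passes the significance threshold")
  out <- effect_table(G$loci$chrom[keep], G$loci$pos[keep], "alt",
                      slope[keep], pval[keep])
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_tests") <- n_tests
  out
}
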