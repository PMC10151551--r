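#' Diploid genotype matrix with optional depth, phase and ancestry
#'
#' The central container consumed by every stage of the analysis. Genotypes
#' are stored as alt-allele dosages (0, 1, 2, or `NA` for a missing call) in a
#' samples x loci integer matrix. Optional slots carry per-call read depth,
#' phased haplotypes (two 0/1 allele matrices whose sum equals the dosage
#' wherever both are called), and -- for simulated data -- the founder
#' haplotype id each allele copy descends from, which supplies IBD ground
#' truth.
#'
#' @param gt integer matrix, samples in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`;
#'   one row per column of `gt`; loci must be unique by (chrom, pos).
#' @param samples data.frame with column `sample_id` plus optional metadata
#'   (`group` in archaeological/cultivated/wild, `region`, `color`); one row
#'   per row of `gt`. A character vector of ids is also accepted.
#' @param depth optional non-negative integer matrix of per-call read depth,
#'   same shape as `gt`.
#' @param hap1,hap2 optional 0/1 matrices of phased alleles, same shape as
#'   `gt`; where both are non-missing their sum must equal the dosage.
#' @param anc1,anc2 optional integer matrices of founder haplotype ids
#'   (ancestry of the allele in `hap1` / `hap2`).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(gt, loci, samples, depth = NULL,
                        hap1 = NULL, hap2 = NULL,
                        anc1 = NULL, anc2 = NULL) {
  if (is.character(samples)) samples <- data.frame(sample_id = samples)
  stopifnot(is.matrix(gt), is.data.frame(loci), is.data.frame(samples))
  if (nrow(samples) != nrow(gt))
    stop("sample table has ", nrow(samples), " rows but gt has ", nrow(gt))
  if (nrow(loci) != ncol(gt))
    stop("locus table has ", nrow(loci), " rows but gt has ", ncol(gt), " columns")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci)))
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(loci[c("chrom", "pos")]))
    stop("loci must be unique by (chrom, pos)")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  bad <- !(gt %in% c(0L, 1L, 2L)) & !is.na(gt)
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  storage.mode(gt) <- "integer"
  rownames(gt) <- samples$sample_id
  for (m in list(depth, hap1, hap2, anc1, anc2)) {
    if (!is.null(m) && !identical(dim(m), dim(gt)))
      stop("auxiliary matrix dimensions must match gt")
  }
  if (!is.null(hap1) && !is.null(hap2)) {
    both <- !is.na(hap1) & !is.na(hap2) & !is.na(gt)
    if (any((hap1 + hap2)[both] != gt[both]))
      stop("phased haplotype pair must sum to the dosage")
  }
  structure(
    list(gt = gt, loci = loci, samples = samples, depth = depth,
         hap1 = hap1, hap2 = hap2, anc1 = anc1, anc2 = anc2),
    class = "geno_matrix"
  )
}

#' @export
dim.geno_matrix <- function(x) dim(x$gt)

#' Number of samples / loci
#' @param G a [geno_matrix()]
#' @return integer count
#' @export
n_samples <- function(G) nrow(G$gt)

#' @rdname n_samples
#' @export
n_loci <- function(G) ncol(G$gt)

#' @export
#' @method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", n_samples(x), " samples x ", n_loci(x), " loci\n", sep = "")
  cat("  missing calls: ", sum(is.na(x$gt)),
      sprintf(" (%.1f%%)", 100 * mean(is.na(x$gt))), "\n", sep = "")
  cat("  depth: ", if (is.null(x$depth)) "absent" else "present",
      "; phase: ", if (is.null(x$hap1)) "absent" else "present",
      "; ancestry: ", if (is.null(x$anc1)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or loci
#'
#' @param x a [geno_matrix()]
#' @param i sample selector (ids, logical or integer indices)
#' @param j locus selector (logical or integer indices)
#' @param ... unused
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(i)) {
    i <- match(i, x$samples$sample_id)
    if (anyNA(i)) stop("unknown sample id")
  }
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  geno_matrix(
    gt = x$gt[i, j, drop = FALSE],
    loci = x$loci[j, , drop = FALSE],
    samples = x$samples[i, , drop = FALSE],
    depth = sub(x$depth), hap1 = sub(x$hap1), hap2 = sub(x$hap2),
    anc1 = sub(x$anc1), anc2 = sub(x$anc2)
  )
}

#' Per-sample and per-locus call rates
#' @param G a [geno_matrix()]
#' @return numeric vector of call rates in `[0, 1]`
#' @export
sample_callrate <- function(G) rowMeans(!is.na(G$gt))

#' @rdname sample_callrate
#' @export
locus_callrate <- function(G) colMeans(!is.na(G$gt))

#' Alt-allele and minor-allele frequencies over called alleles
#' @param G a [geno_matrix()]
#' @return numeric vector, one entry per locus (`NaN` where no calls)
#' @export
alt_freq <- function(G) colSums(G$gt, na.rm = TRUE) / (2 * colSums(!is.na(G$gt)))

#' @rdname alt_freq
#' @export
minor_allele_freq <- function(G) pmin(alt_freq(G), 1 - alt_freq(G))

#' Heterozygous-call count per sample
#' @param G a [geno_matrix()]
#' @return named integer vector
#' @export
het_counts <- function(G) rowSums(G$gt == 1L, na.rm = TRUE)

#' Extract one sample's genotype vector
#' @param G a [geno_matrix()]
#' @param id sample id
#' @return integer dosage vector named by locus index
#' @export
genotypes_of <- function(G, id) {
  i <- match(id, G$samples$sample_id)
  if (is.na(i)) stop("unknown sample id: ", id)
  G$gt[i, ]
}
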