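#' Read a VCF into a genotype matrix
#'
#' Loads diploid biallelic SNP records from a VCF (plain or gzipped) via
#' vcfR. Multiallelic and non-SNP (indel) records are skipped and their count
#' reported in a message. Missing GT calls become missing dosages; when every
#' retained call on the phased side uses `|` separators the haplotype pair is
#' kept, and per-call DP is kept when present.
#'
#' @param path VCF file path
#' @param metadata optional path to a sample-metadata TSV with columns
#'   `sample_id`, `group`, and optionally `region`, `color`
#' @return a [geno_matrix()]
#' @export
read_vcf <- function(path, metadata = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  n_skip <- sum(!keep)
  if (n_skip > 0) message(n_skip, " multiallelic/non-SNP records skipped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt_str <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  loci <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                     ref = fix$REF[keep], alt = fix$ALT[keep],
                     stringsAsFactors = FALSE)
  samples <- colnames(gt_str)
  a1 <- substr(gt_str, 1, 1)
  sep <- substr(gt_str, 2, 2)
  a2 <- substr(gt_str, 3, 3)
  to_int <- function(a) {
    v <- suppressWarnings(as.integer(a))
    v[!a %in% c("0", "1")] <- NA_integer_
    v
  }
  h1 <- matrix(to_int(a1), nrow = nrow(gt_str))
  h2 <- matrix(to_int(a2), nrow = nrow(gt_str))
  gt <- t(h1 + h2)  # samples x loci
  phased <- all(sep[!is.na(gt_str) & gt_str != "."] == "|")
  depth <- NULL
  if (any(grepl("(^|:)DP(:|$)", vcf@gt[keep, "FORMAT"]))) {
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    depth <- t(dp)
    storage.mode(depth) <- "integer"
  }
  smp <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    meta <- utils::read.table(metadata, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    smp <- merge(smp, meta, by = "sample_id", all.x = TRUE, sort = FALSE)
    smp <- smp[match(samples, smp$sample_id), , drop = FALSE]
  }
  geno_matrix(gt = gt, loci = loci, samples = smp, depth = depth,
              hap1 = if (phased) t(h1) else NULL,
              hap2 = if (phased) t(h2) else NULL)
}

#' Write a genotype matrix to VCF
#'
#' Emits VCF 4.2 with GT (phased `|` separators when haplotypes are present,
#' `/` otherwise) and DP when depth is present. Writing goes through vcfR;
#' a plain-text `.vcf` is produced unless the path ends in `.gz`.
#'
#' @param G a [geno_matrix()]
#' @param path output path (`.vcf` or `.vcf.gz`)
#' @return `path`, invisibly
#' @importFrom methods new
#' @importClassesFrom vcfR vcfR
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  L <- n_loci(G)
  phased <- !is.null(G$hap1) && !is.null(G$hap2)
  sepc <- if (phased) "|" else "/"
  if (phased) {
    a1 <- t(G$hap1); a2 <- t(G$hap2)  # loci x samples
  } else {
    gt <- t(G$gt)
    a1 <- ifelse(is.na(gt), NA_integer_, as.integer(gt == 2L))
    a2 <- ifelse(is.na(gt), NA_integer_, as.integer(gt >= 1L))
  }
  gt_str <- matrix(paste0(a1, sepc, a2), nrow = L)
  gt_str[is.na(a1) | is.na(a2)] <- paste0(".", sepc, ".")
  fmt <- "GT"
  if (!is.null(G$depth)) {
    fmt <- "GT:DP"
    gt_str <- matrix(paste0(gt_str, ":", t(G$depth)), nrow = L)
  }
  colnames(gt_str) <- G$samples$sample_id
  fix <- cbind(CHROM = G$loci$chrom, POS = as.character(G$loci$pos),
               ID = ".", REF = G$loci$ref, ALT = G$loci$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            if (!is.null(G$depth))
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">")
  vcf <- new("vcfR", meta = meta, fix = fix,
             gt = cbind(FORMAT = fmt, gt_str))
  gz <- grepl("\\.gz$", path)
  tmp <- if (gz) path else paste0(path, ".gz")
  vcfR::write.vcf(vcf, tmp)
  if (!gz) {
    con <- gzfile(tmp); on.exit(close(con))
    writeLines(readLines(con), path)
    unlink(tmp)
  }
  invisible(path)
}

#' Dataset-construction filter thresholds
#'
#' The quality filters used to build the SNP datasets: a per-call minimum
#' read depth (applied only to the named low-coverage/sequenced samples, not
#' to array-derived panel genotypes), a minimum locus call rate of 75%, a
#' minimum sample call rate of 60%, and -- for the kinship-grade variant -- a
#' minor-allele-frequency floor of 3% combined with a stricter 80% locus
#' call rate. Set `min_maf = 0` to skip the MAF stage.
#'
#' @param min_locus_callrate minimum fraction of samples with a call per locus
#' @param min_sample_callrate minimum fraction of loci called per sample
#' @param min_depth calls below this depth are masked missing
#' @param depth_samples sample ids to which the depth mask applies (`NULL` =
#'   all samples that have depth)
#' @param min_maf minor-allele-frequency floor (0 disables)
#' @param maf_callrate stricter locus call rate applied at the MAF stage
#' @return list of class `filter_spec`
#' @export
filter_spec <- function(min_locus_callrate = 0.75, min_sample_callrate = 0.60,
                        min_depth = 5L, depth_samples = NULL,
                        min_maf = 0.03, maf_callrate = 0.80) {
  stopifnot(min_locus_callrate >= 0, min_locus_callrate <= 1,
            min_sample_callrate >= 0, min_sample_callrate <= 1,
            min_depth >= 0, min_maf >= 0, min_maf <= 0.5,
            maf_callrate >= 0, maf_callrate <= 1)
  structure(list(min_locus_callrate = min_locus_callrate,
                 min_sample_callrate = min_sample_callrate,
                 min_depth = as.integer(min_depth),
                 depth_samples = depth_samples,
                 min_maf = min_maf, maf_callrate = maf_callrate),
            class = "filter_spec")
}

#' Apply dataset-construction filters
#'
#' Stages, in order: (1) depth mask -- calls below `min_depth` in the
#' depth-filtered samples are set missing; (2) locus call-rate filter;
#' (3) sample call-rate filter; (4) MAF filter on the surviving calls
#' (minor-allele frequency computed on called alleles only) together with the
#' stricter MAF-stage call rate. The input is not modified; an audit report
#' of what each stage removed is attached as attribute `"filter_report"`.
#'
#' @param G a [geno_matrix()]
#' @param spec a [filter_spec()]
#' @param keep_samples sample ids exempt from the sample call-rate filter
#'   (used by the dual-dataset strategy to force focal samples through)
#' @return The filtered [geno_matrix()]; errors if nothing survives.
#' @export
apply_filters <- function(G, spec = filter_spec(), keep_samples = NULL) {
  stopifnot(inherits(G, "geno_matrix"), inherits(spec, "filter_spec"))
  report <- list()
  # 1: depth mask
  n_masked <- 0L
  if (!is.null(G$depth) && spec$min_depth > 0) {
    rows <- if (is.null(spec$depth_samples)) seq_len(n_samples(G))
            else match(intersect(spec$depth_samples, G$samples$sample_id),
                       G$samples$sample_id)
    low <- G$depth[rows, , drop = FALSE] < spec$min_depth &
      !is.na(G$gt[rows, , drop = FALSE])
    n_masked <- sum(low)
    if (n_masked > 0) {
      G$gt[rows, ][low] <- NA_integer_
      if (!is.null(G$hap1)) { G$hap1[rows, ][low] <- NA_integer_
                              G$hap2[rows, ][low] <- NA_integer_ }
    }
  }
  report$calls_masked_by_depth <- n_masked
  # 2: locus call rate
  keep_loci <- locus_callrate(G) >= spec$min_locus_callrate
  report$loci_removed_callrate <- sum(!keep_loci)
  if (!any(keep_loci)) stop("no data survive filters")
  G <- G[, keep_loci]
  # 3: sample call rate
  keep_smp <- sample_callrate(G) >= spec$min_sample_callrate
  if (!is.null(keep_samples))
    keep_smp[G$samples$sample_id %in% keep_samples] <- TRUE
  report$samples_removed_callrate <- sum(!keep_smp)
  G <- G[keep_smp, ]
  # 4: MAF + stricter call rate
  if (spec$min_maf > 0 && n_loci(G) > 0) {
    maf <- minor_allele_freq(G)
    keep_maf <- !is.na(maf) & maf >= spec$min_maf &
      locus_callrate(G) >= spec$maf_callrate
    report$loci_removed_maf <- sum(!keep_maf)
    G <- G[, keep_maf]
  } else {
    report$loci_removed_maf <- 0L
  }
  if (n_samples(G) == 0 || n_loci(G) == 0)
    stop("no data survive filters")
  report$n_samples <- n_samples(G)
  report$n_loci <- n_loci(G)
  attr(G, "filter_report") <- report
  G
}

#' Build the dual SNP datasets (wide vs deep)
#'
#' Reproduces the two-dataset strategy that trades SNP count against
#' low-coverage sample count. The *wide* dataset maximises loci: focal
#' (e.g. archaeological) samples that individually fail the sample call-rate
#' threshold on the locus-filtered matrix are dropped before filtering, so
#' their sparsity does not constrain the locus set. The *deep* dataset keeps
#' every focal sample: loci are additionally required to be called in all
#' focal samples, so fewer loci survive but all focal samples are usable.
#'
#' @param G a [geno_matrix()]
#' @param focal_samples character vector of focal sample ids, a subset of the
#'   matrix's samples
#' @param spec a [filter_spec()]
#' @return list with elements `wide` and `deep` (each a filtered
#'   [geno_matrix()] carrying its `"filter_report"`), plus a `summary`
#'   data.frame of (dataset, n_samples, n_loci).
#' @export
build_dual_datasets <- function(G, focal_samples, spec = filter_spec()) {
  stopifnot(all(focal_samples %in% G$samples$sample_id))
  # wide: drop focal samples failing sample call rate after the locus filter
  base <- apply_filters(G, spec, keep_samples = focal_samples)
  cr <- sample_callrate(base)[match(focal_samples, base$samples$sample_id)]
  wide_focal <- focal_samples[!is.na(cr) & cr >= spec$min_sample_callrate]
  drop <- setdiff(focal_samples, wide_focal)
  wide <- apply_filters(G[setdiff(G$samples$sample_id, drop), ], spec,
                        keep_samples = wide_focal)
  # deep: all focal samples retained; loci must be called in every focal sample
  focal_called <- colSums(is.na(G$gt[match(focal_samples, G$samples$sample_id),
                                     , drop = FALSE])) == 0
  deepG <- G[, focal_called]
  deep <- apply_filters(deepG, spec, keep_samples = focal_samples)
  summary <- data.frame(
    dataset = c("wide", "deep"),
    n_samples = c(n_samples(wide), n_samples(deep)),
    n_loci = c(n_loci(wide), n_loci(deep))
  )
  list(wide = wide, deep = deep, summary = summary)
}
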