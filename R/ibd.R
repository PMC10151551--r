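#' Parse a refined-IBD-style segment file
#'
#' Reads whitespace/tab-delimited haplotype IBD segment calls with columns
#' id1, hap1, id2, hap2, chrom, start, end, lod (the refined-IBD output
#' dialect; ends inclusive, coordinates 1-based bp). Rows with LOD at or
#' below `min_lod` are dropped; malformed rows (wrong field count,
#' non-numeric coordinates, start > end) are skipped with a logged count.
#'
#' @param path segment file path
#' @param min_lod minimum LOD score; segments must exceed it (LOD > 3 is the
#'   conventional reporting threshold)
#' @param col_map optional integer vector naming which columns hold
#'   id1, hap1, id2, hap2, chrom, start, end, lod, for dialect drift
#' @return data.frame of class `ibd_segments` with those eight columns plus
#'   `length` (bp, end - start + 1).
#' @export
parse_ibd <- function(path, min_lod = 3, col_map = 1:8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(.empty_segments())
  fields <- strsplit(trimws(lines), "[ \t]+")
  ok_len <- lengths(fields) >= max(col_map)
  parsed <- lapply(fields[ok_len], function(f) f[col_map])
  m <- do.call(rbind, parsed)
  seg <- data.frame(id1 = m[, 1], hap1 = suppressWarnings(as.integer(m[, 2])),
                    id2 = m[, 3], hap2 = suppressWarnings(as.integer(m[, 4])),
                    chrom = m[, 5],
                    start = suppressWarnings(as.numeric(m[, 6])),
                    end = suppressWarnings(as.numeric(m[, 7])),
                    lod = suppressWarnings(as.numeric(m[, 8])),
                    stringsAsFactors = FALSE)
  good <- !is.na(seg$start) & !is.na(seg$end) & !is.na(seg$lod) &
    seg$hap1 %in% c(1L, 2L) & seg$hap2 %in% c(1L, 2L) & seg$start <= seg$end
  good[is.na(good)] <- FALSE
  n_bad <- sum(!ok_len) + sum(!good)
  if (n_bad > 0) message(n_bad, " malformed segment rows skipped")
  seg <- seg[good & seg$lod > min_lod, , drop = FALSE]
  seg$length <- seg$end - seg$start + 1
  class(seg) <- c("ibd_segments", "data.frame")
  rownames(seg) <- NULL
  seg
}

.empty_segments <- function() {
  seg <- data.frame(id1 = character(), hap1 = integer(), id2 = character(),
                    hap2 = integer(), chrom = character(), start = numeric(),
                    end = numeric(), lod = numeric(), length = numeric(),
                    stringsAsFactors = FALSE)
  class(seg) <- c("ibd_segments", "data.frame")
  seg
}

#' Per-pair IBD sharing matrix
#'
#' Sums shared segment lengths (bp) over all four haplotype pairings of each
#' sample pair -- the "summed lengths of shared haplotypes" relatedness
#' measure. Samples without segments get zero rows; the matrix is symmetric
#' with a zero diagonal. A parallel segment-count matrix is attached as
#' attribute `"n_segments"`.
#'
#' @param segments an `ibd_segments` data.frame from [parse_ibd()] or
#'   [naive_segments()]
#' @param sample_ids samples to include (rows/columns, in this order)
#' @return numeric matrix of summed shared bp.
#' @export
sharing_matrix <- function(segments, sample_ids) {
  n <- length(sample_ids)
  M <- matrix(0, n, n, dimnames = list(sample_ids, sample_ids))
  K <- matrix(0L, n, n, dimnames = list(sample_ids, sample_ids))
  i <- match(segments$id1, sample_ids)
  j <- match(segments$id2, sample_ids)
  keep <- !is.na(i) & !is.na(j) & i != j
  for (k in which(keep)) {
    M[i[k], j[k]] <- M[i[k], j[k]] + segments$length[k]
    M[j[k], i[k]] <- M[j[k], i[k]] + segments$length[k]
    K[i[k], j[k]] <- K[i[k], j[k]] + 1L
    K[j[k], i[k]] <- K[j[k], i[k]] + 1L
  }
  attr(M, "n_segments") <- K
  M
}

#' Order samples for a sharing heatmap
#'
#' Two orderings of the relatedness heatmap: `"hclust"` performs
#' average-linkage hierarchical clustering on the distance
#' `1 - shared / max(shared)` and returns the dendrogram leaf order;
#' `"closeness"` ranks samples by descending mean shared length with a focal
#' set (e.g. the archaeological samples).
#'
#' @param M sharing matrix from [sharing_matrix()]
#' @param mode "hclust" or "closeness"
#' @param focal focal sample ids (required for "closeness")
#' @return character vector of sample ids in display order
#' @export
order_samples <- function(M, mode = c("hclust", "closeness"), focal = NULL) {
  mode <- match.arg(mode)
  ids <- rownames(M)
  if (mode == "hclust") {
    mx <- max(M)
    if (mx == 0) return(ids)
    d <- stats::as.dist(1 - M / mx)
    hc <- stats::hclust(d, method = "average")
    return(ids[hc$order])
  }
  if (is.null(focal) || length(focal) == 0)
    stop("closeness ordering needs a non-empty focal set")
  if (!all(focal %in% ids)) stop("focal samples absent from matrix")
  score <- colMeans(M[focal, , drop = FALSE])
  ids[order(-score, ids)]
}

#' Naive exact-match IBD segment scan
#'
#' Desk-scale oracle for error-free phased data: emits the maximal runs of
#' identical alleles between two haplotypes whose spanned length reaches
#' `min_bp`. Positions must be ascending; sites where either haplotype is
#' missing break runs. LOD is set to `Inf` (exact match, no model).
#'
#' @param hapA,hapB 0/1 allele vectors of equal length
#' @param positions ascending 1-based bp positions
#' @param min_bp minimum spanned bp (end - start + 1) to report
#' @param id1,id2,hap1,hap2,chrom labels for the emitted segments
#' @return An `ibd_segments` data.frame.
#' @export
naive_segments <- function(hapA, hapB, positions, min_bp = 1,
                           id1 = "A", id2 = "B", hap1 = 1L, hap2 = 1L,
                           chrom = "chr1") {
  if (length(hapA) != length(hapB)) stop("haplotypes differ in length")
  stopifnot(length(positions) == length(hapA), !is.unsorted(positions))
  same <- !is.na(hapA) & !is.na(hapB) & hapA == hapB
  runs <- rle(same)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- .empty_segments()
  for (r in which(runs$values)) {
    s <- positions[starts[r]]; e <- positions[ends[r]]
    if (e - s + 1 >= min_bp) {
      out <- rbind(out, data.frame(id1 = id1, hap1 = hap1, id2 = id2,
                                   hap2 = hap2, chrom = chrom,
                                   start = s, end = e, lod = Inf,
                                   length = e - s + 1,
                                   stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("ibd_segments", "data.frame")
  out
}

#' All-pairings naive segment scan between two phased samples
#'
#' Runs [naive_segments()] on all four haplotype pairings of two samples in
#' a phased genotype matrix.
#'
#' @param G a phased [geno_matrix()]
#' @param id1,id2 sample ids
#' @param min_bp minimum spanned bp
#' @return An `ibd_segments` data.frame.
#' @export
naive_segments_pair <- function(G, id1, id2, min_bp = 1) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.null(G$hap1)) stop("phased genotypes required")
  i <- match(id1, G$samples$sample_id); j <- match(id2, G$samples$sample_id)
  if (is.na(i) || is.na(j)) stop("unknown sample id")
  haps_i <- list(G$hap1[i, ], G$hap2[i, ])
  haps_j <- list(G$hap1[j, ], G$hap2[j, ])
  out <- list()
  for (a in 1:2) for (b in 1:2) {
    out[[length(out) + 1L]] <- naive_segments(
      haps_i[[a]], haps_j[[b]], G$loci$pos, min_bp,
      id1 = id1, id2 = id2, hap1 = a, hap2 = b,
      chrom = G$loci$chrom[1])
  }
  res <- do.call(rbind, out)
  class(res) <- c("ibd_segments", "data.frame")
  res
}

#' Ground-truth IBD segments from simulator ancestry
#'
#' Emits the maximal runs of shared founder-haplotype ancestry between two
#' simulated samples, for every haplotype pairing -- the truth against which
#' IBD detection is judged. Requires the ancestry matrices the simulator
#' tracks ([simulate_founders()] / [breed()]).
#'
#' @param G a [geno_matrix()] with ancestry
#' @param id1,id2 sample ids
#' @param min_bp minimum spanned bp
#' @return An `ibd_segments` data.frame (lod `Inf`).
#' @export
true_ibd_segments <- function(G, id1, id2, min_bp = 1) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.null(G$anc1)) stop("ancestry tracking required")
  i <- match(id1, G$samples$sample_id); j <- match(id2, G$samples$sample_id)
  if (is.na(i) || is.na(j)) stop("unknown sample id")
  anc_i <- list(G$anc1[i, ], G$anc2[i, ])
  anc_j <- list(G$anc1[j, ], G$anc2[j, ])
  out <- list()
  for (a in 1:2) for (b in 1:2) {
    same <- anc_i[[a]] == anc_j[[b]]
    runs <- rle(same)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      s <- G$loci$pos[starts[r]]; e <- G$loci$pos[ends[r]]
      if (e - s + 1 >= min_bp)
        out[[length(out) + 1L]] <- data.frame(
          id1 = id1, hap1 = a, id2 = id2, hap2 = b,
          chrom = G$loci$chrom[1], start = s, end = e, lod = Inf,
          length = e - s + 1, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_segments()
  class(res) <- c("ibd_segments", "data.frame")
  res
}
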