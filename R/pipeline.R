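#' Run configuration for the end-to-end analysis
#'
#' Collects every input path and threshold the full analysis needs, so a run
#' is reproducible from one declarative object: the VCF and sample metadata,
#' an optional IBD-segment file and allele-effects table, the filter spec,
#' kinship thresholds, the descent error allowance, the minimum locus count
#' for a defined color score, and the output directory.
#'
#' @param vcf path to the genotype VCF
#' @param metadata path to the sample-metadata TSV (sample_id, group, color)
#' @param ibd optional path to a refined-IBD-style segment file
#' @param effects optional path to an allele-effects TSV
#' @param filters a [filter_spec()]
#' @param thresholds a [kinship_thresholds()]
#' @param focal_samples focal (e.g. archaeological) sample ids; defaults to
#'   the metadata samples with group "archaeological"
#' @param descent_max_rate per-allele violation-rate allowance for descent
#' @param color_min_loci minimum called effect loci for a defined score
#' @param min_lod minimum LOD for IBD segments
#' @param out_dir output directory
#' @param seed integer seed
#' @return list of class `run_config`
#' @export
run_config <- function(vcf, metadata, ibd = NULL, effects = NULL,
                       filters = filter_spec(),
                       thresholds = kinship_thresholds(),
                       focal_samples = NULL,
                       descent_max_rate = 0.005, color_min_loci = 1L,
                       min_lod = 3, out_dir = tempfile("vinekin_run_"),
                       seed = 1L) {
  for (p in c(vcf, metadata, ibd, effects))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(vcf = vcf, metadata = metadata, ibd = ibd, effects = effects,
                 filters = filters, thresholds = thresholds,
                 focal_samples = focal_samples,
                 descent_max_rate = descent_max_rate,
                 color_min_loci = color_min_loci, min_lod = min_lod,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.log_stage <- function(log, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  c(log, msg)
}

#' End-to-end kinship, IBD-sharing and descent report
#'
#' Applies the dataset-construction filters, builds the wide/deep dual
#' datasets around the focal samples, computes the all-pairs kinship table
#' for both, builds the IBD sharing matrix with both heatmap orderings when
#' a segment file is supplied, and produces a [descent_report()] for every
#' pair classified parent-offspring or duplicate/clone. All tables are
#' written under `config$out_dir`; stage logs record input and output
#' dimensions so the dataset funnel is auditable.
#'
#' @param config a [run_config()]
#' @return Invisibly, a list with `datasets`, `kinship_wide`, `kinship_deep`,
#'   `sharing` (or NULL), `orderings` (or NULL), `descent` (list of
#'   reports), `log`, `paths`.
#' @export
run_kinship_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  G <- read_vcf(config$vcf, config$metadata)
  log <- .log_stage(log, "loaded ", n_samples(G), " samples x ", n_loci(G), " loci")
  focal <- config$focal_samples
  if (is.null(focal))
    focal <- G$samples$sample_id[G$samples$group %in% "archaeological"]
  dual <- build_dual_datasets(G, focal, config$filters)
  log <- .log_stage(log, "wide dataset: ", n_samples(dual$wide), " samples x ",
                    n_loci(dual$wide), " loci")
  log <- .log_stage(log, "deep dataset: ", n_samples(dual$deep), " samples x ",
                    n_loci(dual$deep), " loci")
  kin_wide <- kinship_matrix(dual$wide, config$thresholds)
  kin_deep <- kinship_matrix(dual$deep, config$thresholds)
  paths <- list(
    kinship_wide = file.path(config$out_dir, "kinship_wide.tsv"),
    kinship_deep = file.path(config$out_dir, "kinship_deep.tsv"),
    datasets = file.path(config$out_dir, "datasets.tsv")
  )
  utils::write.table(kin_wide, paths$kinship_wide, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(kin_deep, paths$kinship_deep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dual$summary, paths$datasets, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sharing <- NULL; orderings <- NULL
  if (!is.null(config$ibd)) {
    seg <- parse_ibd(config$ibd, min_lod = config$min_lod)
    sharing <- sharing_matrix(seg, dual$wide$samples$sample_id)
    ord_h <- order_samples(sharing, "hclust")
    ord_c <- if (length(intersect(focal, rownames(sharing))) > 0)
      order_samples(sharing, "closeness", intersect(focal, rownames(sharing)))
    else NULL
    orderings <- list(hclust = ord_h, closeness = ord_c)
    paths$sharing <- file.path(config$out_dir, "ibd_sharing.tsv")
    utils::write.table(sharing, paths$sharing, sep = "\t", quote = FALSE)
    log <- .log_stage(log, "IBD sharing matrix over ", nrow(sharing),
                      " samples (", nrow(seg), " segments)")
  } else {
    log <- .log_stage(log, "no IBD segment file supplied; sharing step skipped")
  }
  # descent evidence for every close pair found on the wide dataset
  close <- kin_wide[kin_wide$category %in% c("parent-offspring", "duplicate/clone"), ]
  descent <- lapply(seq_len(nrow(close)), function(k) {
    rep <- descent_report(dual$wide, close$id1[k], close$id2[k],
                          max_rate = config$descent_max_rate)
    # orient the report: parent is the sample with more heterozygous sites
    if (rep$directionality == "b_contains_a")
      rep <- descent_report(dual$wide, close$id2[k], close$id1[k],
                            max_rate = config$descent_max_rate)
    rep
  })
  if (length(descent) > 0) {
    paths$descent <- file.path(config$out_dir, "descent.json")
    jsonlite::write_json(
      lapply(descent, function(r) r[setdiff(names(r), "haplotype_match")]),
      paths$descent, auto_unbox = TRUE, force = TRUE, digits = NA)
  }
  log <- .log_stage(log, length(descent), " close pair(s) examined for descent")
  writeLines(log, file.path(config$out_dir, "kinship_report.log"))
  invisible(list(datasets = dual, kinship_wide = kin_wide,
                 kinship_deep = kin_deep, sharing = sharing,
                 orderings = orderings, descent = descent, log = log,
                 paths = paths))
}

#' End-to-end polygenic color-score report
#'
#' Scores every sample with the supplied allele-effects table, then places
#' each focal sample's score within the score distribution of each color
#' category of the reference panel (samples with known color and a defined
#' score).
#'
#' @param config a [run_config()] with `effects` set
#' @return Invisibly, a list with `scores` (per-sample data.frame),
#'   `placement` (per focal sample, percentile-below per category), `paths`.
#' @export
run_color_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$effects)) stop("effects table required for color report")
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  G <- read_vcf(config$vcf, config$metadata)
  effects <- read_effect_table(config$effects)
  scores <- polygenic_score(G, effects, min_loci = config$color_min_loci)
  meta <- G$samples
  scores$color <- meta$color[match(scores$sample_id, meta$sample_id)]
  scores$group <- meta$group[match(scores$sample_id, meta$sample_id)]
  focal <- config$focal_samples
  if (is.null(focal)) focal <- scores$sample_id[scores$group %in% "archaeological"]
  panel <- scores[!scores$sample_id %in% focal & !is.na(scores$color) &
                    scores$defined, ]
  if (nrow(panel) == 0) stop("no reference panel samples with known color")
  placement <- lapply(focal, function(id) {
    s <- scores$score[scores$sample_id == id]
    if (length(s) != 1 || is.na(s)) return(NULL)  # undefined score: excluded
    percentile_placement(s, panel$score, panel$color)
  })
  names(placement) <- focal
  placement <- placement[!vapply(placement, is.null, logical(1))]
  paths <- list(scores = file.path(config$out_dir, "color_scores.tsv"),
                placement = file.path(config$out_dir, "color_placement.json"))
  utils::write.table(scores, paths$scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(placement, paths$placement, auto_unbox = TRUE, digits = NA)
  invisible(list(scores = scores, placement = placement, paths = paths))
}
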