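#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   findOverlaps granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits metadata metadata<- DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' ArrayDesign: promoter tiling-array layout
#'
#' Container for the geometry of a promoter tiling array: probe intervals,
#' strand-aware promoter windows around each transcription start site (TSS),
#' the probe-to-promoter assignment, and per-probe CpG/C/G counts when a
#' genome sequence is available.
#'
#' Coordinates are held as `GRanges` (1-based, closed intervals, the
#' Bioconductor convention). On-disk design files use BED-style 0-based
#' half-open starts; the conversion happens exactly once, in
#' [loadArrayDesign()] / [writeArrayDesign()].
#'
#' @slot probes `GRanges`, one range per unique probe, with metadata columns
#'   `probe_id` and (when counted) `cpg_count`, `c_count`, `g_count`.
#' @slot promoters `GRanges` of promoter windows spanning `upstream` bp
#'   before to `downstream` bp after the TSS in transcription direction,
#'   with metadata columns `promoter_id`, `gene_id`, `tss` (1-based).
#' @slot probeMap `data.frame` with columns `probe_id`, `promoter_id`; a
#'   probe belongs to every promoter window it overlaps by at least 1 bp,
#'   so multi-TSS genes may share probes.
#' @slot upstream,downstream numeric; window extent around the TSS (bp).
#' @slot genomeBuild character label, e.g. `"synthetic"` or `"hg19"`.
#'
#' @seealso [buildArrayDesign()], [loadArrayDesign()]
#' @export
setClass("ArrayDesign",
  representation(
    probes      = "GRanges",
    promoters   = "GRanges",
    probeMap    = "data.frame",
    upstream    = "numeric",
    downstream  = "numeric",
    genomeBuild = "character"
  )
)

setValidity("ArrayDesign", function(object) {
  msg <- character()
  pid <- object@probes$probe_id
  if (is.null(pid)) return("'probes' must carry a 'probe_id' metadata column")
  if (anyDuplicated(pid)) msg <- c(msg, "probe_ids must be unique")
  prid <- object@promoters$promoter_id
  if (is.null(prid)) return("'promoters' must carry a 'promoter_id' column")
  if (anyDuplicated(prid)) msg <- c(msg, "promoter_ids must be unique")
  if (!all(c("probe_id", "promoter_id") %in% colnames(object@probeMap)))
    return("'probeMap' needs columns probe_id, promoter_id")
  if (!all(object@probeMap$probe_id %in% pid))
    msg <- c(msg, "probeMap references unknown probe_id(s)")
  if (!all(object@probeMap$promoter_id %in% prid))
    msg <- c(msg, "probeMap references unknown promoter_id(s)")
  w <- GenomicRanges::width(object@promoters)
  if (length(w) && any(w != object@upstream + object@downstream))
    msg <- c(msg, "promoter windows must span upstream + downstream bp")
  cc <- object@probes$cpg_count
  if (!is.null(cc) && !all(is.na(cc))) {
    ok <- is.na(cc) |
      (cc <= pmin(object@probes$c_count, object@probes$g_count) &
         cc <= GenomicRanges::width(object@probes) - 1L & cc >= 0L)
    if (!all(ok)) msg <- c(msg, "CpG counts inconsistent with C/G counts or probe length")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ArrayDesign-class number of probes
#' @param x,object an `ArrayDesign`.
#' @export
setMethod("length", "ArrayDesign", function(x) length(x@probes))

setMethod("show", "ArrayDesign", function(object) {
  cat(sprintf("ArrayDesign (%s): %d probes, %d promoter windows, %d genes\n",
              object@genomeBuild, length(object@probes),
              length(object@promoters),
              length(unique(object@promoters$gene_id))))
  cat(sprintf("  window: TSS -%d..+%d bp; CpG counts: %s\n",
              object@upstream, object@downstream,
              if (is.null(object@probes$cpg_count) ||
                  all(is.na(object@probes$cpg_count))) "absent" else "present"))
})

#' @rdname ArrayDesign-class
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))
#' @rdname ArrayDesign-class
#' @export
setMethod("probes", "ArrayDesign", function(x) x@probes)

#' @rdname ArrayDesign-class
#' @export
setGeneric("promoterWindows", function(x) standardGeneric("promoterWindows"))

#' @rdname ArrayDesign-class
#' @export
setMethod("promoterWindows", "ArrayDesign", function(x) x@promoters)

#' @rdname ArrayDesign-class
#' @export
setGeneric("probeMap", function(x) standardGeneric("probeMap"))
#' @rdname ArrayDesign-class
#' @export
setMethod("probeMap", "ArrayDesign", function(x) x@probeMap)

#' NormalizedRatios: per-array or per-subject log2(bound/input) matrix
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' probes x samples matrix of normalized log2(bound/input) MeDIP enrichment
#' ratios in assay `"ratio"`. `colData` carries the sample sheet
#' (subject, group, replicate array ids); `metadata(x)$provenance` records
#' the normalization steps applied (background method, offset, quantile
#' step, replicate merge map).
#'
#' @export
setClass("NormalizedRatios", contains = "SummarizedExperiment")

setValidity("NormalizedRatios", function(object) {
  if (!"ratio" %in% SummarizedExperiment::assayNames(object))
    return("assay 'ratio' is required")
  if (!is.numeric(SummarizedExperiment::assay(object, "ratio")))
    return("assay 'ratio' must be numeric")
  TRUE
})

#' @rdname NormalizedRatios-class
#' @param x a `NormalizedRatios`.
#' @export
setGeneric("ratioMatrix", function(x) standardGeneric("ratioMatrix"))
#' @rdname NormalizedRatios-class
#' @export
setMethod("ratioMatrix", "NormalizedRatios", function(x)
  SummarizedExperiment::assay(x, "ratio"))

#' TruthSet: simulator ground truth for a synthetic cohort
#'
#' Ground truth emitted by [simulateTruth()]: per-promoter baseline
#' methylation, effect flags, effect direction and size, cluster membership,
#' and CpG-density class, together with the [ArrayDesign] the truth was
#' drawn on and the synthetic promoter-window sequences.
#'
#' @slot promoterTruth `data.frame` with one row per promoter: columns
#'   `promoter_id`, `gene_id`, `m0` (baseline methylation in [0,1]),
#'   `effect` (logical), `direction` (`"hypo"`/`"hyper"` in the case group,
#'   `NA` for null promoters), `delta` (effect size on the methylation
#'   scale), `cluster_id`, `density_class` (`"low"`/`"mid"`/`"high"`).
#' @slot design the `ArrayDesign` (with CpG counts filled from the
#'   synthetic sequences).
#' @slot sequences `DNAStringSet` of promoter-window sequences (names =
#'   promoter ids), or `NULL`.
#' @slot config the `SimConfig` list used.
#' @export
setClass("TruthSet",
  representation(
    promoterTruth = "data.frame",
    design        = "ArrayDesign",
    sequences     = "DNAStringSetOrNULL",
    config        = "list"
  )
)

setValidity("TruthSet", function(object) {
  tt <- object@promoterTruth
  need <- c("promoter_id", "gene_id", "m0", "effect", "direction",
            "delta", "cluster_id", "density_class")
  if (!all(need %in% colnames(tt)))
    return(paste("promoterTruth needs columns:", paste(need, collapse = ", ")))
  if (any(tt$m0 < 0 | tt$m0 > 1)) return("m0 must lie in [0,1]")
  if (any(!is.na(tt$direction) & !tt$direction %in% c("hypo", "hyper")))
    return("direction must be 'hypo' or 'hyper'")
  TRUE
})

setMethod("show", "TruthSet", function(object) {
  tt <- object@promoterTruth
  cat(sprintf("TruthSet: %d promoters, %d with effects (%d hypo / %d hyper in cases)\n",
              nrow(tt), sum(tt$effect),
              sum(tt$effect & tt$direction == "hypo"),
              sum(tt$effect & tt$direction == "hyper")))
})

#' @rdname TruthSet-class
#' @param x a `TruthSet`.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname TruthSet-class
#' @export
setMethod("truthTable", "TruthSet", function(x) x@promoterTruth)

#' @rdname TruthSet-class
#' @export
setGeneric("truthDesign", function(x) standardGeneric("truthDesign"))
#' @rdname TruthSet-class
#' @export
setMethod("truthDesign", "TruthSet", function(x) x@design)

#' @rdname TruthSet-class
#' @export
setGeneric("truthSequences", function(x) standardGeneric("truthSequences"))
#' @rdname TruthSet-class
#' @export
setMethod("truthSequences", "TruthSet", function(x) x@sequences)

#' SpatialCorrCurve: distance-binned correlation of methylation differences
#'
#' Result of [spatialCorrelationCurve()]: per distance bin, the Pearson
#' correlation of between-group methylation differences over probe pairs
#' separated by that distance, a bootstrap confidence interval, and a
#' coordinate-permutation null band.
#'
#' @slot bins `data.frame` with columns `bin_lo`, `bin_hi` (bp), `n_pairs`,
#'   `r`, `ci_lo`, `ci_hi` (bootstrap 2.5/97.5%), `null_lo`, `null_hi`
#'   (central 95% of permuted correlations).
#' @slot params list: `n_boot`, `n_perm`, `pair_cap`, `min_pairs`, `seed`.
#' @export
setClass("SpatialCorrCurve",
  representation(bins = "data.frame", params = "list"))

setValidity("SpatialCorrCurve", function(object) {
  b <- object@bins
  need <- c("bin_lo", "bin_hi", "n_pairs", "r", "ci_lo", "ci_hi",
            "null_lo", "null_hi")
  if (!all(need %in% colnames(b)))
    return(paste("bins needs columns:", paste(need, collapse = ", ")))
  if (any(diff(b$bin_lo) <= 0)) return("bins must be ascending")
  if (any(b$bin_hi <= b$bin_lo)) return("bin_hi must exceed bin_lo")
  ok <- is.na(b$r) | (b$r >= -1 & b$r <= 1 &
                        (is.na(b$ci_lo) | (b$ci_lo <= b$r & b$r <= b$ci_hi)))
  if (!all(ok)) return("r outside [-1,1] or outside its bootstrap CI")
  TRUE
})

setMethod("show", "SpatialCorrCurve", function(object) {
  b <- object@bins
  cat(sprintf("SpatialCorrCurve: %d bins (%.0f bp .. %.2f Mb), %d with estimates\n",
              nrow(b), min(b$bin_lo), max(b$bin_hi) / 1e6, sum(!is.na(b$r))))
  cat(sprintf("  %d bootstraps, %d permutations, seed %s\n",
              object@params$n_boot, object@params$n_perm,
              format(object@params$seed)))
})

#' @rdname SpatialCorrCurve-class
#' @param x a `SpatialCorrCurve`.
#' @export
setGeneric("curveBins", function(x) standardGeneric("curveBins"))
#' @rdname SpatialCorrCurve-class
#' @export
setMethod("curveBins", "SpatialCorrCurve", function(x) x@bins)
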