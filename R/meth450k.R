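# Pooled beta-value (450K-style) validation arm: probe filters,
# differential test on M-values, and promoter mapping.

#' Filter beta-array probes by detection p-value and SNP proximity
#'
#' Drops any CpG whose detection p-value exceeds `detp_max` in any pool
#' (with only three pools per group a single unreliable value cripples
#' the test, so the whole CpG goes), and any CpG with a SNP within
#' `snp_bp` bp of the CpG site (inclusive boundary; missing SNP distance
#' means no known SNP and is kept). The two filters commute.
#'
#' @param beta CpG x pool matrix of beta values in [0, 1].
#' @param detp matching matrix of detection p-values.
#' @param manifest `data.frame` with `cpg_id` and `snp_distance` covering
#'   all CpGs in `beta`.
#' @param detp_max detection p threshold (0.001).
#' @param snp_bp SNP exclusion distance in bp (10, inclusive).
#' @return list: `beta`, `detp` (filtered), `report` (named counts:
#'   `n_input`, `n_detp_fail`, `n_snp`, `n_kept`).
#' @export
filterProbes450k <- function(beta, detp, manifest, detp_max = 0.001,
                             snp_bp = 10) {
  stopifnot(identical(dim(beta), dim(detp)))
  ids <- rownames(beta)
  if (is.null(ids)) stop("'beta' needs CpG ids as rownames")
  mi <- match(ids, manifest$cpg_id)
  if (anyNA(mi)) stop("manifest does not cover all CpG ids")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  detp_fail <- apply(detp > detp_max, 1L, any)
  snp_near <- !is.na(manifest$snp_distance[mi]) &
    manifest$snp_distance[mi] <= snp_bp
  keep <- !detp_fail & !snp_near
  if (!any(keep)) stop("no CpGs left after filtering")
  list(beta = beta[keep, , drop = FALSE],
       detp = detp[keep, , drop = FALSE],
       report = c(n_input = length(ids),
                  n_detp_fail = sum(detp_fail),
                  n_snp = sum(snp_near),
                  n_kept = sum(keep)))
}

#' Pooled differential methylation on beta values
#'
#' Per CpG: the group beta difference `delta_beta = mean(case pools) -
#' mean(control pools)` and a Welch t-test on M-values
#' `M = log2(beta / (1 - beta))` (betas clipped to
#' `[beta_clip, 1 - beta_clip]` before the logit to avoid infinities),
#' with Benjamini-Hochberg q-values. CpGs with zero variance in both
#' groups get `p = 1` and a flag. This transparent test stands in for
#' proprietary bead-array software output.
#'
#' @param beta filtered CpG x pool matrix.
#' @param groups per-pool group labels (`"CPA"`/`"NPA"`).
#' @param beta_clip clip bound before the M-value transform (0.01).
#' @param q_max significance threshold on q (0.05).
#' @return `data.frame`: `cpg_id`, `delta_beta`, `t`, `df`, `p`, `q`,
#'   `significant`, `zero_variance`.
#' @export
poolDifferential <- function(beta, groups, beta_clip = 0.01, q_max = 0.05) {
  stopifnot(length(groups) == ncol(beta))
  g1 <- groups == "CPA"; g2 <- groups == "NPA"
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop("at least 2 pools per group are required")
  n1 <- sum(g1); n2 <- sum(g2)
  db <- rowMeans(beta[, g1, drop = FALSE]) -
    rowMeans(beta[, g2, drop = FALSE])
  bc <- beta
  bc[bc < beta_clip] <- beta_clip
  bc[bc > 1 - beta_clip] <- 1 - beta_clip
  M <- log2(bc / (1 - bc))
  m1 <- rowMeans(M[, g1, drop = FALSE]); m2 <- rowMeans(M[, g2, drop = FALSE])
  v1 <- apply(M[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(M[, g2, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  zerovar <- se2 == 0
  tstat <- ifelse(zerovar, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(zerovar, NA_real_,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- ifelse(zerovar, 1, 2 * stats::pt(-abs(tstat), df = df))
  q <- bhFdr(p)
  data.frame(cpg_id = rownames(beta), delta_beta = db, t = tstat, df = df,
             p = p, q = q, significant = q < q_max,
             zero_variance = zerovar,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map differentially methylated CpGs to promoter windows
#'
#' A promoter is a hit when at least one significant CpG lies inside its
#' strand-aware TSS window (the array design's windows, for internal
#' consistency with the tiling-array arm). CpGs without coordinates are
#' skipped.
#'
#' @param diffStats `data.frame` from [poolDifferential()].
#' @param manifest `data.frame` with `cpg_id`, `chrom`, `pos`.
#' @param design [ArrayDesign] supplying the promoter windows.
#' @return `data.frame`: `promoter_id`, `gene_id`, `n_cpgs`, `cpg_ids`
#'   (semicolon-joined), `mean_delta_beta`.
#' @export
mapCpgsToPromoters <- function(diffStats, manifest, design) {
  sig <- diffStats[diffStats$significant, , drop = FALSE]
  mi <- match(sig$cpg_id, manifest$cpg_id)
  has_pos <- !is.na(mi) & !is.na(manifest$pos[mi])
  if (any(!has_pos))
    message(sum(!has_pos), " significant CpG(s) without coordinates skipped")
  sig <- sig[has_pos, , drop = FALSE]
  mi <- mi[has_pos]
  if (!nrow(sig))
    return(data.frame(promoter_id = character(), gene_id = character(),
                      n_cpgs = integer(), cpg_ids = character(),
                      mean_delta_beta = numeric(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(manifest$chrom[mi],
                               IRanges::IRanges(manifest$pos[mi], width = 1L))
  prm <- promoterWindows(design)
  ov <- GenomicRanges::findOverlaps(gr, prm, ignore.strand = TRUE)
  if (!length(ov))
    return(data.frame(promoter_id = character(), gene_id = character(),
                      n_cpgs = integer(), cpg_ids = character(),
                      mean_delta_beta = numeric(), stringsAsFactors = FALSE))
  hit <- data.frame(
    promoter_id = prm$promoter_id[S4Vectors::subjectHits(ov)],
    gene_id = prm$gene_id[S4Vectors::subjectHits(ov)],
    cpg_id = sig$cpg_id[S4Vectors::queryHits(ov)],
    delta_beta = sig$delta_beta[S4Vectors::queryHits(ov)],
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(hit, hit$promoter_id), function(h)
    data.frame(promoter_id = h$promoter_id[1L], gene_id = h$gene_id[1L],
               n_cpgs = nrow(h),
               cpg_ids = paste(h$cpg_id, collapse = ";"),
               mean_delta_beta = mean(h$delta_beta),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
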