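# Shared fixtures, built in code and cached for the test session.

.fixtures <- new.env(parent = emptyenv())

## A small TSS table on one chromosome, plus strand unless stated.
toyTssTable <- function(n = 2, chrom = "chr1", start = 100000,
                        spacing = 50000, strand = "+") {
  data.frame(promoter_id = sprintf("P%02d", seq_len(n)),
             gene_id = sprintf("G%02d", seq_len(n)),
             chrom = chrom,
             tss = start + spacing * (seq_len(n) - 1L),
             strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}

toyDesign <- function(n = 2, ...) buildArrayDesign(toyTssTable(n, ...))

## Random genome covering the toy designs.
toyGenome <- function(len = 300000, chrom = "chr1", seed = 99) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    g <- Biostrings::DNAStringSet(s)
    names(g) <- chrom
    g
  })
}

## Full-size signal cohort (study conditions) with the analysis chain run
## once and cached; several files assert different aspects of it.
signalCohort <- function() {
  if (is.null(.fixtures$signal)) {
    cohort <- simulateCohort(simConfig(), seed = 1)
    truth <- cohort$truth
    design <- truthDesign(truth)
    merged <- mergeReplicates(
      normalizeRatios(cohort$arrays, cohort$arrays$samples))
    ps <- probeModeratedT(merged)
    prs <- promoterRankSum(ps, design)
    dmr <- callDmrs(ps, prs, design)
    .fixtures$signal <- list(cohort = cohort, truth = truth,
                             design = design, merged = merged,
                             probe_stats = ps, promoter_stats = prs,
                             dmr = dmr)
  }
  .fixtures$signal
}

## Small cohort for cheaper end-to-end assertions.
smallCohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- simConfig(n_genes = 300)
    cohort <- simulateCohort(cfg, seed = 7)
    merged <- mergeReplicates(
      normalizeRatios(cohort$arrays, cohort$arrays$samples))
    .fixtures$small <- list(config = cfg, cohort = cohort,
                            truth = cohort$truth,
                            design = truthDesign(cohort$truth),
                            merged = merged)
  }
  .fixtures$small
}

## Design whose promoters keep only the first `sizes[i]` probes.
designWithSizes <- function(sizes, chrom = "chr1") {
  tss <- toyTssTable(length(sizes), spacing = 100000)
  d <- buildArrayDesign(tss)
  pm <- probeMap(d)
  keep <- unlist(lapply(seq_along(sizes), function(i) {
    ids <- pm$probe_id[pm$promoter_id == tss$promoter_id[i]]
    ids[seq_len(sizes[i])]
  }))
  methods::initialize(d,
    probes = probes(d)[probes(d)$probe_id %in% keep],
    probeMap = pm[pm$probe_id %in% keep, ])
}

## Probe-stat table with prescribed t values for a design.
statsFor <- function(design, tvals) {
  pr <- probes(design)
  data.frame(probe_id = pr$probe_id, log2fc = tvals / 10, s2 = 1,
             s2_post = 1, df_resid = 17, t = tvals,
             p = 2 * pnorm(-abs(tvals)), boundary = FALSE,
             stringsAsFactors = FALSE)
}

## Design whose probes carry hand-set CpG counts.
designWithCpg <- function(cpg_lists) {
  tss <- toyTssTable(length(cpg_lists), spacing = 100000)
  d <- buildArrayDesign(tss)
  pr <- probes(d)
  pm <- probeMap(d)
  keep <- unlist(lapply(seq_along(cpg_lists), function(i) {
    pm$probe_id[pm$promoter_id == tss$promoter_id[i]][
      seq_along(cpg_lists[[i]])]
  }))
  pr <- pr[match(keep, pr$probe_id)]
  pr$cpg_count <- as.integer(unlist(cpg_lists))
  pr$c_count <- pr$cpg_count + 1L
  pr$g_count <- pr$cpg_count + 1L
  methods::initialize(d, probes = pr,
                      probeMap = pm[pm$probe_id %in% keep, ])
}

## Brute-force one-sided rank-sum tail by subset enumeration (independent
## of the package's implementation).
bruteRanksum <- function(values_in, values_all) {
  ranks <- rank(values_all, ties.method = "average")
  in_idx <- match(values_in, values_all)
  W <- sum(ranks[in_idx])
  sums <- colSums(utils::combn(ranks, length(values_in)))
  c(p_pos = mean(sums >= W - 1e-9), p_neg = mean(sums <= W + 1e-9))
}

## Brute-force BH step-up from the definition.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

## Greedy Ward (ward.D2 Lance-Williams) agglomeration from scratch:
## globally minimal merge at each step.
bruteWard <- function(d, n) {
  D <- as.matrix(d)
  diag(D) <- Inf
  size <- rep(1L, n)
  id <- -seq_len(n)  # hclust convention: negatives are singletons
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    sub <- D[active, active, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- active[min(k)]; j <- active[max(k)]
    height[step] <- D[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))
    ## Lance-Williams update for ward.D2 (distances, not squares)
    for (h in setdiff(active, c(i, j))) {
      ni <- size[i]; nj <- size[j]; nh <- size[h]
      D[h, i] <- D[i, h] <- sqrt(((ni + nh) * D[i, h]^2 +
                                    (nj + nh) * D[j, h]^2 -
                                    nh * D[i, j]^2) / (ni + nj + nh))
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merge, height = height)
}
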