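# Genomic organization of methylation differences: CpG observed/expected
# density asymmetry of calls, and the distance-binned correlation of
# between-group differences with bootstrap CIs against a
# coordinate-permutation null.

#' Normalized (observed/expected) CpG density of regions
#'
#' Per region, `rho = [cpg/(L-1)] / [(c/L) * (g/L)]`: the CpG
#' dinucleotide density divided by the expected density under
#' independence, the product of the C and G mononucleotide densities.
#' `N` bases are excluded from counts and from the effective length `L`.
#' Regions with no C or no G have undefined `rho` (`NA`, excluded from
#' the comparison test). When two groups are supplied, their densities
#' are compared with a two-sided Mann-Whitney U test.
#'
#' @param sequences a `DNAStringSet` (or character vector) of region
#'   sequences, or a `GRanges` plus `genome` to extract them from.
#' @param genome optional genome (`DNAStringSet`/FASTA path) when
#'   `sequences` is a `GRanges`.
#' @param group optional factor/character per region (e.g. `"hyper"`,
#'   `"hypo"`, `"background"`); the test compares `"hyper"` vs `"hypo"`.
#' @return list with `table` (`data.frame`: `region`, `rho`, `group`)
#'   and, when both groups are present, `test` (list `statistic`, `p`).
#' @export
normalizedCpgDensity <- function(sequences, genome = NULL, group = NULL) {
  if (methods::is(sequences, "GRanges")) {
    if (is.null(genome)) stop("supply 'genome' to extract GRanges sequences")
    nm <- sequences$name %||% names(sequences) %||%
      as.character(seq_along(sequences))
    sequences <- regionSequences(sequences, genome)
    names(sequences) <- nm
  }
  cnt <- countCpg(sequences)
  seqs <- if (is.character(sequences))
    Biostrings::DNAStringSet(toupper(sequences)) else sequences
  n_count <- Biostrings::letterFrequency(seqs, letters = "N")[, 1L]
  L <- Biostrings::width(seqs) - n_count  # effective (non-N) length
  obs <- cnt[, "cpg_count"] / pmax(1, L - 1)
  expd <- (cnt[, "c_count"] / L) * (cnt[, "g_count"] / L)
  rho <- ifelse(expd > 0, obs / expd, NA_real_)
  tab <- data.frame(
    region = names(seqs) %||% as.character(seq_along(rho)),
    rho = rho,
    group = if (is.null(group)) NA_character_ else as.character(group),
    stringsAsFactors = FALSE)
  out <- list(table = tab, test = NULL)
  if (!is.null(group)) {
    hyper <- tab$rho[tab$group == "hyper" & !is.na(tab$rho)]
    hypo <- tab$rho[tab$group == "hypo" & !is.na(tab$rho)]
    if (length(hyper) >= 2L && length(hypo) >= 2L) {
      wt <- stats::wilcox.test(hyper, hypo, exact = FALSE)
      out$test <- list(statistic = unname(wt$statistic), p = wt$p.value,
                       median_hyper = stats::median(hyper),
                       median_hypo = stats::median(hypo))
    }
  }
  out
}

## Pearson correlation over pairs with both orientations included;
## algebraically identical to cor(c(x, y), c(y, x)) but allocation-light.
pairCor <- function(x, y) {
  n <- length(x)
  mx <- (sum(x) + sum(y)) / (2 * n)
  vv <- (sum(x * x) + sum(y * y)) / 2 - n * mx * mx
  cv <- sum(x * y) - n * mx * mx
  if (vv <= 0) return(NA_real_)
  cv / vv
}

## Enumerate or uniformly subsample (without replacement) the pairs of
## sorted positions whose separation lies in [lo, hi). Positions must be
## sorted ascending. Returns list(i, j) of index pairs with i < j.
pairsInBin <- function(pos, lo, hi, cap) {
  n <- length(pos)
  ## partner window of each i among j > i
  first <- findInterval(pos + lo, pos, left.open = TRUE) + 1L
  first <- pmax(first, seq_len(n) + 1L)
  last <- findInterval(pos + hi, pos, left.open = TRUE)
  cnt <- pmax(0L, last - first + 1L)
  total <- sum(cnt)
  if (total == 0) return(list(i = integer(0), j = integer(0), total = 0))
  if (total <= cap) {
    i <- rep.int(seq_len(n), cnt)
    j <- sequence(cnt, from = first)
  } else {
    pick <- sort(sample.int(total, cap))  # uniform over all pairs
    cs <- cumsum(cnt)
    i <- findInterval(pick - 1L, c(0L, cs), left.open = FALSE,
                      rightmost.closed = TRUE)
    offset <- pick - c(0L, cs)[i] - 1L
    j <- first[i] + offset
  }
  list(i = i, j = j, total = total)
}

#' Distance-binned spatial correlation of methylation differences
#'
#' For each genomic distance bin, collects same-chromosome probe pairs
#' whose separation falls in the bin (uniformly subsampled down to
#' `pair_cap` pairs when there are more) and computes the Pearson
#' correlation of the between-group methylation differences of the two
#' probes, both pair orientations included. A bootstrap confidence
#' interval (2.5-97.5%) comes from resampling pairs with replacement
#' `n_boot` times, and a null band from `n_perm` random permutations of
#' the probe coordinates within each chromosome (difference values kept
#' fixed), pooling all permuted correlations per bin and taking the
#' central 95%.
#'
#' @param delta numeric per-probe between-group difference
#'   (mean case - mean control of normalized ratios).
#' @param chrom chromosome per probe.
#' @param pos position per probe (bp; probe midpoints).
#' @param bin_edges ascending bin edges in bp; default 0, 50 kb, then
#'   log-spaced up to 4 Mb (14 bins).
#' @param n_boot bootstrap replicates (1000).
#' @param n_perm coordinate permutations (500).
#' @param pair_cap maximum pairs per bin (200,000).
#' @param min_pairs bins with fewer pairs get `r = NA` (30).
#' @param seed integer seed controlling subsampling, bootstrap and
#'   permutations; results are byte-identical given the seed.
#' @return A [SpatialCorrCurve].
#' @export
spatialCorrelationCurve <- function(delta, chrom, pos,
                                    bin_edges = defaultDistanceBins(),
                                    n_boot = 1000, n_perm = 500,
                                    pair_cap = 200000, min_pairs = 30,
                                    seed = 1) {
  stopifnot(length(delta) == length(chrom), length(delta) == length(pos))
  if (stats::sd(delta) == 0) stop("'delta' is constant: correlation undefined")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly ascending")
  nb <- length(bin_edges) - 1L

  ord <- order(chrom, pos)
  delta <- delta[ord]; chrom <- chrom[ord]; pos <- pos[ord]
  by_chr <- split(seq_along(pos), chrom)
  by_chr <- by_chr[lengths(by_chr) >= 2L]

  withSeed(seed, {
    ## fixed pair index sets per bin (global indices)
    pair_i <- vector("list", nb); pair_j <- vector("list", nb)
    n_pairs_total <- numeric(nb)
    for (b in seq_len(nb)) {
      ii <- jj <- integer(0); tot <- 0
      for (k in by_chr) {
        pb <- pairsInBin(pos[k], bin_edges[b], bin_edges[b + 1L], pair_cap)
        ii <- c(ii, k[pb$i]); jj <- c(jj, k[pb$j])
        tot <- tot + pb$total
      }
      ## re-cap across chromosomes so no bin exceeds pair_cap overall
      if (length(ii) > pair_cap) {
        keep <- sort(sample.int(length(ii), pair_cap))
        ii <- ii[keep]; jj <- jj[keep]
      }
      pair_i[[b]] <- ii; pair_j[[b]] <- jj
      n_pairs_total[b] <- tot
    }

    r <- ci_lo <- ci_hi <- null_lo <- null_hi <- rep(NA_real_, nb)
    use <- lengths(pair_i) >= min_pairs

    for (b in which(use)) {
      x <- delta[pair_i[[b]]]; y <- delta[pair_j[[b]]]
      r[b] <- pairCor(x, y)
      bs <- vapply(seq_len(n_boot), function(dummy) {
        k <- sample.int(length(x), replace = TRUE)
        pairCor(x[k], y[k])
      }, numeric(1))
      qs <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      ci_lo[b] <- min(qs[1L], r[b]); ci_hi[b] <- max(qs[2L], r[b])
    }

    ## permuting coordinates within chromosome with delta fixed is
    ## equivalent to permuting delta within chromosome over fixed
    ## coordinates, so the pair index sets can be reused
    perm_r <- matrix(NA_real_, n_perm, nb)
    for (p in seq_len(n_perm)) {
      dp <- delta
      for (k in by_chr) dp[k] <- dp[k[sample.int(length(k))]]
      for (b in which(use))
        perm_r[p, b] <- pairCor(dp[pair_i[[b]]], dp[pair_j[[b]]])
    }
    for (b in which(use)) {
      qs <- stats::quantile(perm_r[, b], c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE)
      null_lo[b] <- qs[1L]; null_hi[b] <- qs[2L]
    }

    bins <- data.frame(
      bin_lo = bin_edges[-length(bin_edges)], bin_hi = bin_edges[-1L],
      n_pairs = lengths(pair_i), r = r, ci_lo = ci_lo, ci_hi = ci_hi,
      null_lo = null_lo, null_hi = null_hi)
    bins$r[!use] <- NA_real_
    methods::new("SpatialCorrCurve", bins = bins,
                 params = list(n_boot = n_boot, n_perm = n_perm,
                               pair_cap = pair_cap, min_pairs = min_pairs,
                               seed = seed))
  })
}

#' Default distance bins: 0, 50 kb, then log-spaced to 4 Mb
#' @param n_log number of log-spaced edges after 50 kb (13 -> 14 bins).
#' @return numeric vector of bin edges (bp).
#' @export
defaultDistanceBins <- function(n_log = 13) {
  c(0, 50e3 * (4e6 / 50e3)^(seq(0, n_log) / n_log))
}

#' Decorrelation length of a spatial correlation curve
#'
#' The upper edge of the largest-distance bin such that every bin at or
#' below it has a bootstrap confidence interval disjoint from the
#' permutation null band; 0 when no bin qualifies. This is the distance
#' out to which between-group methylation differences remain predictive
#' of each other beyond chance.
#'
#' @param curve a [SpatialCorrCurve].
#' @return distance in bp.
#' @export
decorrelationLength <- function(curve) {
  b <- curveBins(curve)
  if (sum(!is.na(b$r)) < 3L)
    stop("need at least 3 bins with estimates")
  sig <- !is.na(b$r) & !is.na(b$null_lo) &
    (b$ci_lo > b$null_hi | b$ci_hi < b$null_lo)
  run <- cumprod(as.numeric(sig))  # leading run of significant bins
  if (!any(run > 0)) return(0)
  b$bin_hi[max(which(run > 0))]
}
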