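# Probe-level moderated t-statistics, promoter-level rank-sum enrichment,
# FDR control, the combined differential-methylation call rule, and the
# heatmap probe selection / clustering.

#' Invert the trigamma function
#'
#' Newton iteration on `trigamma(y) = x`, used when solving for the prior
#' degrees of freedom of the variance model.
#'
#' @param x positive numeric vector.
#' @return y with `trigamma(y) = x`.
#' @keywords internal
trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x  # asymptotic start (trigamma(y) ~ 1/y + 1/(2y^2))
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(-dif / y, na.rm = TRUE) < 1e-8) break
  }
  y
}

#' Fit the empirical-Bayes prior of the probe variance model
#'
#' Method-of-moments fit of the scaled-F model `s_g^2 ~ s0^2 F(d_g, d0)`
#' on the log variances: with `z = log(s_g^2)` and
#' `e = z - digamma(d_g/2) + log(d_g/2)`, solve
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` for the prior degrees
#' of freedom `d0`, and recover `s0^2` from `mean(e)` with the digamma
#' correction. When the spread of `z` does not exceed what sampling alone
#' explains, `d0 = Inf` and `s0^2` is the mean variance.
#'
#' @param s2 positive per-probe residual variances.
#' @param df residual degrees of freedom (scalar or per-probe vector).
#' @return list with `d0` (prior df, possibly `Inf`) and `s02`.
#' @export
fitEbayesPrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("need at least two positive finite variances")
  s2 <- s2[ok]
  df <- rep_len(df, length(ok))[ok]
  if (any(df < 1)) stop("residual df must be >= 1")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = mean(s2)))
  d0 <- 2 * trigammaInverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Probe-level moderated t-statistics
#'
#' Two-sample comparison per probe with empirical-Bayes variance
#' shrinkage: the pooled within-group variance `s_g^2` (df
#' `d_g = n1 + n2 - 2`) is shrunk to
#' `s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and
#' `t~ = log2FC / (s~ sqrt(1/n1 + 1/n2))`, with two-sided p-values from
#' the t distribution on `d0 + d_g` df (standard normal when `d0 = Inf`).
#' `log2FC` is mean(case) - mean(control) of the (replicate-merged)
#' normalized ratios.
#'
#' @param ratios [NormalizedRatios] with one column per subject, or a
#'   plain probes x subjects matrix.
#' @param groups factor/character per subject: `"CPA"` (case) or `"NPA"`
#'   (control); taken from `colData` when `ratios` is a
#'   `NormalizedRatios` and `groups` is missing.
#' @param prior optional list `(d0, s02)`; fitted from the data via
#'   [fitEbayesPrior()] when missing. `d0 = 0` gives the classical
#'   two-sample t.
#' @return `data.frame`: `probe_id`, `log2fc`, `s2` (pooled variance),
#'   `s2_post`, `df_resid`, `t` (moderated), `p`.
#' @export
probeModeratedT <- function(ratios, groups = NULL, prior = NULL) {
  if (methods::is(ratios, "NormalizedRatios")) {
    groups <- groups %||%
      as.data.frame(SummarizedExperiment::colData(ratios))$group
    x <- ratioMatrix(ratios)
  } else x <- ratios
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  g1 <- groups == "CPA"; g2 <- groups == "NPA"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")

  skip <- !stats::complete.cases(x)
  if (any(skip))
    message(sum(skip), " probe(s) with missing values skipped")
  xx <- x[!skip, , drop = FALSE]
  m1 <- rowMeans(xx[, g1, drop = FALSE])
  m2 <- rowMeans(xx[, g2, drop = FALSE])
  v1 <- apply(xx[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(xx[, g2, drop = FALSE], 1L, stats::var)
  dg <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / dg
  if (is.null(prior)) prior <- fitEbayesPrior(s2[s2 > 0], dg)
  d0 <- prior$d0; s02 <- prior$s02
  s2post <- if (is.infinite(d0)) rep(s02, length(s2))
            else (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2post * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  ## zero posterior variance (possible only at d0 = 0 with a constant
  ## probe): p pinned to the exact 0/1 boundary and flagged
  boundary <- se == 0
  tt <- ifelse(!boundary, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d0 + dg  # pt() handles df = Inf as the normal limit
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  p <- pmin(1, pmax(p, 0))
  data.frame(probe_id = rownames(xx) %||% as.character(seq_len(nrow(xx))),
             log2fc = lfc, s2 = s2, s2_post = s2post,
             df_resid = dg, t = tt, p = p, boundary = boundary,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Exact one-sided rank-sum tail probabilities by exhaustive enumeration
## of all C(N, k) probe subsets (used for small promoters; also the
## natural independent check at toy scale).
ranksumExact <- function(ranks_in, ranks_all) {
  k <- length(ranks_in)
  W <- sum(ranks_in)
  comb <- utils::combn(ranks_all, k)
  sums <- colSums(comb)
  c(p_pos = mean(sums >= W - 1e-9), p_neg = mean(sums <= W + 1e-9))
}

#' Promoter-level rank-sum enrichment test
#'
#' For each promoter with at least `min_probes` probes, the Wilcoxon
#' rank-sum statistic of the promoter's probe moderated-t values against
#' all probes outside the promoter. One-sided p-values in both directions
#' come from the normal approximation with tie and continuity correction,
#' or from exhaustive enumeration when the promoter has at most
#' `exact_max_k` probes and the array at most `exact_max_n` probes in
#' total. The reported two-sided p is `min(1, 2 min(p_pos, p_neg))`, the
#' direction is the smaller side, and q-values are Benjamini-Hochberg
#' over tested promoters.
#'
#' @param probeStats `data.frame` from [probeModeratedT()].
#' @param design [ArrayDesign] providing the probe-to-promoter map.
#' @param min_probes minimum probes for a promoter to be tested (3).
#' @param exact_max_k,exact_max_n limits for exact enumeration (8, 25).
#' @return `data.frame`: `promoter_id`, `gene_id`, `n_probes`, `W`,
#'   `p_pos`, `p_neg`, `p`, `q`, `direction` (`"hyper"`/`"hypo"` in the
#'   case group), `tested` plus an `untested_reason`.
#' @export
promoterRankSum <- function(probeStats, design, min_probes = 3,
                            exact_max_k = 8, exact_max_n = 25) {
  map <- probeMap(design)
  prm <- promoterWindows(design)
  idx <- match(map$probe_id, probeStats$probe_id)
  present <- !is.na(idx)
  tvals <- probeStats$t
  N <- nrow(probeStats)
  ranks <- rank(tvals, ties.method = "average")

  ## tie correction term shared by all promoters
  tie_tab <- table(tvals)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))

  prom_f <- factor(map$promoter_id[present], levels = prm$promoter_id)
  k_all <- as.integer(table(prom_f))
  W_full <- as.numeric(tapply(ranks[idx[present]], prom_f, sum))

  tested <- k_all >= min_probes & (N - k_all) >= 1L
  mu <- k_all * (N + 1) / 2
  sigma <- sqrt(k_all * (N - k_all) / 12 * ((N + 1) - tie_term))
  p_pos <- stats::pnorm((W_full - 0.5 - mu) / sigma, lower.tail = FALSE)
  p_neg <- stats::pnorm((W_full + 0.5 - mu) / sigma)

  ## exact enumeration regime: small promoter on a small array
  if (N <= exact_max_n) {
    by_prom <- split(idx[present], map$promoter_id[present])
    for (pid in names(by_prom)) {
      j <- match(pid, prm$promoter_id)
      if (!tested[j] || k_all[j] > exact_max_k) next
      pp <- ranksumExact(ranks[by_prom[[pid]]], ranks)
      p_pos[j] <- pp["p_pos"]; p_neg[j] <- pp["p_neg"]
    }
  }

  p_two <- pmin(1, 2 * pmin(p_pos, p_neg))
  out <- data.frame(
    promoter_id = prm$promoter_id,
    gene_id = prm$gene_id,
    n_probes = k_all,
    W = ifelse(tested, W_full, NA_real_),
    p_pos = ifelse(tested, p_pos, NA_real_),
    p_neg = ifelse(tested, p_neg, NA_real_),
    p = ifelse(tested, p_two, NA_real_),
    q = NA_real_,
    direction = ifelse(tested, ifelse(p_pos < p_neg, "hyper", "hypo"),
                       NA_character_),
    tested = tested,
    untested_reason = ifelse(tested, NA_character_,
                             ifelse(k_all == 0L, "no scored probes",
                                    sprintf("fewer than %d scored probes",
                                            min_probes))),
    stringsAsFactors = FALSE)
  out$q[out$tested] <- bhFdr(out$p[out$tested])
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) m / j`, order-preserving, bounded by
#' `[p, 1]`. Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order; empty input gives empty output.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04, 0.2))
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Combined probe + promoter differential-methylation call rule
#'
#' A promoter is called differentially methylated when its rank-sum
#' q-value is at most `q_max` AND it contains at least one probe with
#' uncorrected t-test p-value at most `probe_p_max`, absolute log2 fold
#' change at least `lfc_min`, and (by default) a fold-change sign
#' consistent with the promoter direction.
#'
#' @param probeStats from [probeModeratedT()].
#' @param promoterStats from [promoterRankSum()].
#' @param design the common [ArrayDesign].
#' @param probe_p_max probe p threshold (0.05).
#' @param lfc_min probe |log2FC| threshold (0.25).
#' @param q_max promoter FDR threshold (0.05).
#' @param sign_consistent require the qualifying probe's log2FC sign to
#'   match the promoter direction (TRUE).
#' @return list with `calls` (`data.frame`: `promoter_id`, `gene_id`,
#'   `direction`, `q`, `n_qualifying`, `qualifying_probes`
#'   (semicolon-joined ids)) and `direction_counts`
#'   (named vector `hyper`/`hypo` in the case group).
#' @export
callDmrs <- function(probeStats, promoterStats, design,
                     probe_p_max = 0.05, lfc_min = 0.25, q_max = 0.05,
                     sign_consistent = TRUE) {
  map <- probeMap(design)
  ps <- probeStats[match(map$probe_id, probeStats$probe_id), ]
  cand <- promoterStats[promoterStats$tested &
                          !is.na(promoterStats$q) &
                          promoterStats$q <= q_max, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    pid <- cand$promoter_id[i]
    dirn <- cand$direction[i]
    sel <- map$promoter_id == pid & !is.na(ps$p)
    qual <- ps$p[sel] <= probe_p_max & abs(ps$log2fc[sel]) >= lfc_min
    if (sign_consistent) {
      want <- if (dirn == "hyper") 1 else -1
      qual <- qual & sign(ps$log2fc[sel]) == want
    }
    if (!any(qual)) return(NULL)
    data.frame(promoter_id = pid, gene_id = cand$gene_id[i],
               direction = dirn, q = cand$q[i],
               n_qualifying = sum(qual),
               qualifying_probes = paste(ps$probe_id[sel][qual],
                                         collapse = ";"),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows) %||%
    data.frame(promoter_id = character(), gene_id = character(),
               direction = character(), q = numeric(),
               n_qualifying = integer(), qualifying_probes = character(),
               stringsAsFactors = FALSE)
  counts <- c(hyper = sum(calls$direction == "hyper"),
              hypo = sum(calls$direction == "hypo"))
  list(calls = calls, direction_counts = counts)
}

#' Select one representative probe per called gene
#'
#' For each gene with a called promoter, picks the probe with the most
#' extreme moderated t-statistic (largest `|t|`); exact ties are broken
#' by the smaller genomic start coordinate. Returns the normalized-ratio
#' rows of the selected probes, for heatmap display.
#'
#' @param calls `data.frame` from `callDmrs()$calls`.
#' @param probeStats from [probeModeratedT()].
#' @param ratios [NormalizedRatios] (per subject) or matrix.
#' @param design the [ArrayDesign].
#' @return matrix (one row per called gene, rownames
#'   `"<gene_id>|<probe_id>"`) of normalized ratios across subjects.
#' @export
representativeProbes <- function(calls, probeStats, ratios, design) {
  if (!nrow(calls)) stop("no calls to select representative probes from")
  x <- if (methods::is(ratios, "NormalizedRatios")) ratioMatrix(ratios)
       else ratios
  map <- probeMap(design)
  pr <- probes(design)
  start_of <- GenomicRanges::start(pr)[match(probeStats$probe_id,
                                             pr$probe_id)]
  genes <- unique(calls$gene_id)
  sel <- vapply(genes, function(g) {
    proms <- calls$promoter_id[calls$gene_id == g]
    pids <- unique(map$probe_id[map$promoter_id %in% proms])
    k <- match(pids, probeStats$probe_id)
    k <- k[!is.na(k)]
    at <- abs(probeStats$t[k])
    best <- k[at == max(at)]
    if (length(best) > 1L) best <- best[which.min(start_of[best])]
    probeStats$probe_id[best]
  }, character(1))
  out <- x[sel, , drop = FALSE]
  rownames(out) <- paste(genes, sel, sep = "|")
  out
}

#' Ward hierarchical clustering with Pearson correlation distance
#'
#' Rows (and columns) are clustered with Ward's minimum-variance linkage
#' (`hclust` method `"ward.D2"`) on the distance `1 - Pearson r`.
#' Constant rows or columns are an error (correlation undefined).
#'
#' @param x numeric matrix (e.g. from [representativeProbes()]).
#' @return list with `hclust` objects `rows` and `cols`.
#' @export
wardCluster <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  const_row <- apply(x, 1L, stats::sd) == 0
  if (any(const_row))
    stop("constant row(s): ", paste(utils::head(
      rownames(x)[const_row] %||% which(const_row), 5), collapse = ", "))
  const_col <- apply(x, 2L, stats::sd) == 0
  if (any(const_col))
    stop("constant column(s): ", paste(utils::head(
      colnames(x)[const_col] %||% which(const_col), 5), collapse = ", "))
  drow <- stats::as.dist(1 - stats::cor(t(x)))
  dcol <- stats::as.dist(1 - stats::cor(x))
  list(rows = stats::hclust(drow, method = "ward.D2"),
       cols = stats::hclust(dcol, method = "ward.D2"))
}
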