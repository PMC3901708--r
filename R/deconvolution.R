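# Simplified Bayesian deconvolution of absolute promoter methylation from
# MeDIP enrichment ratios, and the methylation-vs-expression sanity check.

#' Estimate absolute promoter methylation from cohort-averaged ratios
#'
#' Transparent grid-posterior deconvolution: per promoter, the
#' cohort-averaged probe ratios are modelled as
#' `r_j ~ Normal(a m w_j + b, sigma^2)` with `w_j` the probe CpG coupling
#' weight (CpG count, normalized to the promoter maximum), a uniform
#' prior on `m` over a [0,1] grid, and globally estimated gain/offset.
#' When `a`/`b` are not supplied they are estimated by regressing the
#' array-wide mean ratio on the coupling weight binned by CpG count,
#' dividing the slope by the prior mean methylation `m_ref`; `sigma`
#' defaults to the residual SD of that regression. Promoters whose probes
#' all have zero CpG count are excluded with reason `"no CpG coverage"`.
#'
#' This is deliberately not a dinucleotide-resolution coupling-profile
#' model: the posterior here serves as an interpretable sanity check that
#' enrichment tracks absolute methylation.
#'
#' @param ratios cohort-averaged per-probe ratios: a named numeric vector
#'   (names = probe ids), or a [NormalizedRatios]/matrix averaged across
#'   columns.
#' @param design [ArrayDesign] with CpG counts.
#' @param a,b optional known gain/offset of the methylation-to-log2-ratio
#'   coupling.
#' @param sigma optional known noise SD.
#' @param grid_step methylation grid resolution (0.01).
#' @param m_ref prior mean methylation used to convert the regression
#'   slope into a gain when `a` is estimated (0.5).
#' @return `data.frame`: `promoter_id`, `m_hat` (posterior mean),
#'   `m_sd` (posterior SD), `n_informative` (probes with CpG coverage),
#'   `excluded_reason`.
#' @export
estimatePromoterMethylation <- function(ratios, design, a = NULL, b = NULL,
                                        sigma = NULL, grid_step = 0.01,
                                        m_ref = 0.5) {
  if (methods::is(ratios, "NormalizedRatios"))
    ratios <- rowMeans(ratioMatrix(ratios))
  else if (is.matrix(ratios)) ratios <- rowMeans(ratios)
  pr <- probes(design)
  if (is.null(pr$cpg_count) || all(is.na(pr$cpg_count)))
    stop("design carries no CpG counts; supply a genome when loading it")
  r <- ratios[pr$probe_id]
  if (anyNA(r)) stop("ratios missing for some design probes")

  w <- probeCouplingWeights(design)
  informative <- (pr$coupling_cpg %||% pr$cpg_count) >= 1L

  if (is.null(a) || is.null(b)) {
    ## bin probes by CpG count, regress bin-mean ratio on bin-mean weight
    bins <- split(seq_along(r), pr$cpg_count)
    br <- vapply(bins, function(k) mean(r[k]), numeric(1))
    bw <- vapply(bins, function(k) mean(w[k]), numeric(1))
    bn <- lengths(bins)
    if (length(br) < 2L)
      stop("cannot estimate gain/offset: all probes share one CpG count")
    fit <- stats::lm(br ~ bw, weights = bn)
    slope <- unname(stats::coef(fit)[2L])
    if (is.null(a)) a <- slope / m_ref
    if (is.null(b)) b <- unname(stats::coef(fit)[1L])
  }
  if (is.null(sigma)) {
    sigma <- stats::sd(r - (a * m_ref * w + b))
    sigma <- max(sigma, 1e-3)
  }
  if (a == 0) stop("gain 'a' must be non-zero")

  grid <- seq(0, 1, by = grid_step)
  map <- probeMap(design)[!duplicated(probeMap(design)$probe_id), ]
  pidx <- match(map$probe_id, pr$probe_id)
  keep <- informative[pidx]
  prom_f <- factor(map$promoter_id[keep],
                   levels = promoterWindows(design)$promoter_id)
  rj <- r[pidx][keep]; wj <- w[pidx][keep]
  ## per-promoter sufficient statistics of the Gaussian likelihood
  Sxy <- as.numeric(tapply(wj * (rj - b), prom_f, sum))
  Sxx <- as.numeric(tapply(wj * wj, prom_f, sum))
  n_inf <- as.integer(table(prom_f))

  ## log-likelihood over the grid, up to an m-independent constant
  ll <- (a * outer(Sxy, grid) - 0.5 * a^2 * outer(Sxx, grid^2)) / sigma^2
  ll <- ll - apply(ll, 1L, max)
  post <- exp(ll)
  post <- post / rowSums(post)
  m_hat <- as.numeric(post %*% grid)
  m_sd <- sqrt(pmax(0, as.numeric(post %*% grid^2) - m_hat^2))

  ok <- n_inf >= 1L & !is.na(Sxx)
  data.frame(
    promoter_id = promoterWindows(design)$promoter_id,
    m_hat = ifelse(ok, m_hat, NA_real_),
    m_sd = ifelse(ok, m_sd, NA_real_),
    n_informative = n_inf,
    excluded_reason = ifelse(ok, NA_character_, "no CpG coverage"),
    stringsAsFactors = FALSE)
}

#' Association between estimated promoter methylation and expression
#'
#' Partitions genes into twenty 5%-wide expression-percentile bins,
#' summarizes the methylation-estimate distribution per bin, and reports
#' the global Spearman correlation (with p-value) between expression and
#' estimated methylation. Promoter methylation is expected to
#' anti-correlate with expression.
#'
#' @param estimates `data.frame` from [estimatePromoterMethylation()],
#'   plus a `gene_id` column or promoter ids resolvable via `design`.
#' @param expression named numeric vector (names = gene ids).
#' @param design optional [ArrayDesign] used to map promoters to genes.
#' @param min_shared minimum genes shared between the two tables (100).
#' @return list with `bins` (`data.frame`: `bin`, `n`, `q25`, `median`,
#'   `q75`), `rho`, `p`, `n_genes`.
#' @export
methylationExpressionAssociation <- function(estimates, expression,
                                             design = NULL,
                                             min_shared = 100) {
  if (!"gene_id" %in% colnames(estimates)) {
    if (is.null(design))
      stop("need a 'gene_id' column in estimates or a design to map with")
    prm <- promoterWindows(design)
    estimates$gene_id <- prm$gene_id[match(estimates$promoter_id,
                                           prm$promoter_id)]
  }
  est <- estimates[!is.na(estimates$m_hat), ]
  ## per gene: average m_hat over its promoters
  m_gene <- tapply(est$m_hat, est$gene_id, mean)
  shared <- intersect(names(m_gene), names(expression))
  if (length(shared) < min_shared)
    stop(sprintf("only %d genes shared between methylation and expression (need >= %d)",
                 length(shared), min_shared))
  m <- as.numeric(m_gene[shared])
  e <- as.numeric(expression[shared])
  if (stats::sd(e) == 0)
    stop("expression is constant: correlation undefined")

  pct <- rank(e, ties.method = "average") / length(e)
  bin <- cut(pct, breaks = seq(0, 1, by = 0.05), include.lowest = TRUE,
             labels = sprintf("%d-%d%%", seq(0, 95, 5), seq(5, 100, 5)))
  bins <- do.call(rbind, lapply(levels(bin), function(lv) {
    mm <- m[bin == lv]
    if (!length(mm)) mm <- NA_real_
    data.frame(bin = lv, n = sum(!is.na(mm)),
               q25 = stats::quantile(mm, 0.25, names = FALSE),
               median = stats::median(mm),
               q75 = stats::quantile(mm, 0.75, names = FALSE))
  }))
  ct <- suppressWarnings(stats::cor.test(e, m, method = "spearman"))
  list(bins = bins, rho = unname(ct$estimate), p = ct$p.value,
       n_genes = length(shared))
}
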