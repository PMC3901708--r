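# Cross-signature and cross-platform comparisons, and cohort-table
# statistics: hypergeometric set overlaps, Fisher exact 2x2 tests,
# two-sample t-tests from raw vectors or printed summaries, and
# fold-change concordance.

#' Hypergeometric enrichment test for the overlap of two sets
#'
#' Upper-tail probability `P[X >= |A intersect B|]` for
#' `X ~ Hypergeometric(N, |A|, |B|)`, identical to a one-sided Fisher
#' exact test on the induced 2x2 table. Sets can be given as id vectors
#' (the intersection is computed) or as sizes plus an explicit overlap.
#'
#' @param a,b character id vectors, or single integers (set sizes).
#' @param n_universe universe size N.
#' @param overlap intersection size; required when `a`/`b` are sizes.
#' @return list: `n_a`, `n_b`, `n_overlap`, `n_universe`, `p`
#'   (hypergeometric upper tail), `odds_ratio` (sample OR of the induced
#'   2x2), `expected` (chance expectation `|A||B|/N`).
#' @examples
#' setOverlapTest(448, 430, n_universe = 20318, overlap = 31)
#' @export
setOverlapTest <- function(a, b, n_universe, overlap = NULL) {
  if (is.character(a) || is.character(b)) {
    a <- unique(a); b <- unique(b)
    overlap <- length(intersect(a, b))
    na <- length(a); nb <- length(b)
    union_n <- length(union(a, b))
  } else {
    na <- as.integer(a); nb <- as.integer(b)
    if (is.null(overlap)) stop("supply 'overlap' when passing set sizes")
    union_n <- na + nb - overlap
  }
  if (n_universe < union_n)
    stop("universe smaller than the union of the two sets")
  if (overlap > min(na, nb)) stop("overlap exceeds a set size")
  p <- stats::phyper(overlap - 1L, na, n_universe - na, nb,
                     lower.tail = FALSE)
  tab <- c(a11 = overlap, a12 = na - overlap, a21 = nb - overlap,
           a22 = n_universe - na - nb + overlap)
  or <- if (tab["a12"] * tab["a21"] == 0) Inf
        else unname(tab["a11"] * tab["a22"] / (tab["a12"] * tab["a21"]))
  list(n_a = na, n_b = nb, n_overlap = overlap, n_universe = n_universe,
       p = p, odds_ratio = or, expected = na * nb / n_universe)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test: the two-sided p sums the probabilities of all
#' tables (with the observed margins) no more likely than the observed
#' one, with a small relative tolerance for probability ties — the
#' standard convention, as implemented in `stats::fisher.test()`. The
#' odds ratio reported is the sample OR `ad/bc` (flagged `Inf` at zero
#' cells). A table with an all-zero row or column margin is degenerate:
#' `p = 1` with a flag.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major
#'   `a, b, c, d` for `[[a, b], [c, d]]`) of non-negative counts.
#' @return list: `p`, `odds_ratio`, `degenerate`.
#' @examples
#' fisher2x2(matrix(c(5, 9, 1, 4), nrow = 2, byrow = TRUE))
#' @export
fisher2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- if (tab[1, 2] * tab[2, 1] == 0) {
    if (tab[1, 1] * tab[2, 2] == 0) NaN else Inf
  } else tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  list(p = min(1, p), odds_ratio = or, degenerate = degenerate)
}

#' Two-sample t-test from raw vectors or printed summaries
#'
#' Classical pooled-variance or Welch (Satterthwaite) two-sample t-test,
#' computable either from raw vectors or from printed group summaries
#' (mean, SD, n) such as cohort-characteristics table rows; the two
#' input forms agree exactly when the summaries are exact.
#'
#' @param x,y raw numeric vectors, or lists `list(mean =, sd =, n =)`.
#' @param variant `"pooled"` or `"welch"`.
#' @return list: `t`, `df`, `p`, `mean_diff`, plus a `boundary` flag for
#'   the degenerate zero-variance cases (`p` exactly 0 or 1).
#' @export
twoSampleT <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  summarize <- function(v) {
    if (is.list(v)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(v)))
      v
    } else list(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  s1 <- summarize(x); s2 <- summarize(y)
  if (s1$n < 2 || s2$n < 2) stop("each group needs n >= 2")
  if (s1$sd < 0 || s2$sd < 0) stop("sd must be >= 0")
  d <- s1$mean - s2$mean
  if (s1$sd == 0 && s2$sd == 0) {
    if (d == 0) return(list(t = 0, df = s1$n + s2$n - 2, p = 1,
                            mean_diff = 0, boundary = TRUE))
    return(list(t = sign(d) * Inf, df = s1$n + s2$n - 2, p = 0,
                mean_diff = d, boundary = TRUE))
  }
  if (variant == "pooled") {
    df <- s1$n + s2$n - 2
    sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / df
    se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
  } else {
    a1 <- s1$sd^2 / s1$n; a2 <- s2$sd^2 / s2$n
    se <- sqrt(a1 + a2)
    df <- (a1 + a2)^2 / (a1^2 / (s1$n - 1) + a2^2 / (s2$n - 1))
  }
  tstat <- d / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df = df),
       mean_diff = d, boundary = FALSE)
}

#' Cross-platform fold-change concordance
#'
#' Pearson correlation (with two-sided p) between the fold changes two
#' platforms report for the same regions, e.g. tiling-array log2 fold
#' changes against quantitative-PCR fold differences for the regions
#' selected for validation.
#'
#' @param fc_a,fc_b named numeric vectors of fold changes; matched by
#'   shared names when named, by position otherwise.
#' @return list: `r`, `p`, `n`, `table` (`data.frame` of the paired
#'   values).
#' @export
foldChangeConcordance <- function(fc_a, fc_b) {
  if (!is.null(names(fc_a)) && !is.null(names(fc_b))) {
    shared <- intersect(names(fc_a), names(fc_b))
    fc_a <- fc_a[shared]; fc_b <- fc_b[shared]
    ids <- shared
  } else {
    stopifnot(length(fc_a) == length(fc_b))
    ids <- as.character(seq_along(fc_a))
  }
  if (length(fc_a) < 3L) stop("need at least 3 shared regions")
  if (stats::sd(fc_a) == 0 || stats::sd(fc_b) == 0)
    stop("constant fold-change vector: correlation undefined")
  ct <- stats::cor.test(fc_a, fc_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(fc_a),
       table = data.frame(region = ids, fc_a = as.numeric(fc_a),
                          fc_b = as.numeric(fc_b),
                          stringsAsFactors = FALSE))
}

#' Shared differentially methylated probes/CpGs between two call sets
#'
#' Intersects two call sets by exact id and tests the overlap for
#' enrichment against a shared universe via [setOverlapTest()].
#'
#' @param ids_a,ids_b character vectors of called probe/CpG/promoter ids.
#' @param universe character vector of all testable ids (both call sets
#'   must be subsets of it).
#' @return list: `shared` (character), `overlap` (a [setOverlapTest()]
#'   result).
#' @export
commonProbeOverlap <- function(ids_a, ids_b, universe) {
  ids_a <- unique(ids_a); ids_b <- unique(ids_b)
  if (!all(ids_a %in% universe) || !all(ids_b %in% universe))
    stop("call sets must lie inside the shared universe (disjoint id spaces?)")
  res <- setOverlapTest(ids_a, ids_b, n_universe = length(unique(universe)))
  list(shared = intersect(ids_a, ids_b), overlap = res)
}
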