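# Quality control and normalization of two-channel intensities into
# per-sample log2(bound/input) ratios.

## Background-subtract one channel and floor at eps so ratios stay finite.
## method: "auto" uses the provided background column when present, else
## the per-array 1st-percentile offset; "none" skips subtraction.
subtractBackground <- function(x, bg, method, eps) {
  if (method == "none") return(pmax(x, eps))
  if (!is.null(bg)) x <- x - bg
  else x <- sweep(x, 2L, apply(x, 2L, stats::quantile, probs = 0.01,
                               na.rm = TRUE))
  pmax(x, eps)
}

#' Per-array QC summary for two-channel MeDIP arrays
#'
#' Computes, per array, the median log2 bound/input ratio (M), the median
#' log2 intensity (A), the slope of M against A (dye/intensity bias), the
#' fractions of negative and saturated probes, and the correlation between
#' replicate arrays of the same subject (computed on raw log-ratios;
#' reported `NA` for subjects with a single array, never zero). Arrays are
#' flagged when `|median M|` exceeds `m_threshold` or the replicate
#' correlation falls below `cor_threshold`.
#'
#' @param raw list with `bound`/`input` matrices (probes x arrays), as
#'   from [loadIntensityTable()] or [simulateMedipArrays()].
#' @param samples sample-sheet `data.frame` (one row per array).
#' @param m_threshold flag threshold on `|median M|` (default 1).
#' @param cor_threshold flag threshold on replicate correlation (0.8).
#' @param saturation intensity treated as scanner saturation (65535).
#' @return A `data.frame` with one row per array and a `flagged` column.
#' @export
qcSummary <- function(raw, samples, m_threshold = 1, cor_threshold = 0.8,
                      saturation = 65535) {
  stopifnot(ncol(raw$bound) >= 1L)
  samples <- validateSampleSheet(samples)
  arrays <- colnames(raw$bound)
  b <- pmax(raw$bound, .Machine$double.eps)
  i <- pmax(raw$input, .Machine$double.eps)
  M <- log2(b) - log2(i)
  A <- 0.5 * (log2(b) + log2(i))
  med_m <- apply(M, 2L, stats::median, na.rm = TRUE)
  med_a <- apply(A, 2L, stats::median, na.rm = TRUE)
  slope <- vapply(seq_along(arrays), function(k) {
    ok <- is.finite(M[, k]) & is.finite(A[, k])
    if (sum(ok) < 3L || stats::sd(A[ok, k]) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(M[ok, k] ~ A[ok, k]))[2L])
  }, numeric(1))
  frac_neg <- colMeans(raw$bound <= 0 | raw$input <= 0, na.rm = TRUE)
  frac_sat <- colMeans(raw$bound >= saturation | raw$input >= saturation,
                       na.rm = TRUE)

  subj <- samples$subject_id[match(arrays, samples$array_id)]
  rep_cor <- rep(NA_real_, length(arrays))
  for (s in unique(subj)) {
    k <- which(subj == s)
    if (length(k) >= 2L) {
      cc <- stats::cor(M[, k], use = "pairwise.complete.obs")
      diag(cc) <- NA
      rep_cor[k] <- rowMeans(cc, na.rm = TRUE)
    }
  }
  flagged <- abs(med_m) > m_threshold |
    (!is.na(rep_cor) & rep_cor < cor_threshold)
  data.frame(array_id = arrays, subject_id = subj,
             median_m = med_m, median_a = med_a, ma_slope = slope,
             frac_negative = frac_neg, frac_saturated = frac_sat,
             replicate_cor = rep_cor, flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantile-normalize a matrix of log-ratios across arrays
#'
#' Each array's sorted values are replaced by the across-array mean of
#' order statistics, preserving within-array ranks; tied values receive
#' the mean of the quantile values their ranks span (deterministic tie
#' rule). NAs are not allowed here (they are resolved upstream).
#'
#' @param x numeric matrix, probes x arrays.
#' @return The normalized matrix: all columns share the same value multiset.
#' @export
quantileNormalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("quantileNormalize does not accept missing values")
  if (any(apply(x, 2L, function(col) length(unique(col))) == 1L))
    stop("array with all-constant ratios: ranks undefined everywhere")
  mu <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (mu[lo] + mu[hi]) / 2  # fractional (tied) ranks get the mean quantile
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Normalize raw two-channel intensities into per-array log2 ratios
#'
#' Pipeline: (1) per-channel background subtraction (provided background
#' columns when present, else the per-array 1st-percentile offset),
#' (2) floor at `eps` intensity units, (3) `r = log2(bound/input)` per
#' probe and array, (4) quantile normalization of the ratios across
#' arrays. Probes with a missing value on any array are dropped (and
#' recorded in the provenance) before the quantile step, which requires a
#' complete matrix.
#'
#' @param raw list with `bound`/`input` (and optional `bound_bg`/
#'   `input_bg`) matrices.
#' @param samples sample-sheet `data.frame` (one row per array), stored as
#'   `colData`.
#' @param background `"auto"` (default) or `"none"`.
#' @param eps intensity floor after background subtraction (default 1).
#' @param quantile logical; set `FALSE` to skip the quantile step.
#' @return A [NormalizedRatios] (one column per array).
#' @export
normalizeRatios <- function(raw, samples, background = c("auto", "none"),
                            eps = 1, quantile = TRUE) {
  background <- match.arg(background)
  samples <- validateSampleSheet(samples)
  stopifnot(identical(colnames(raw$bound), colnames(raw$input)))
  b <- subtractBackground(raw$bound, raw$bound_bg, background, eps)
  i <- subtractBackground(raw$input, raw$input_bg, background, eps)
  r <- log2(b) - log2(i)
  complete <- stats::complete.cases(r)
  dropped <- rownames(r)[!complete]
  r <- r[complete, , drop = FALSE]
  if (quantile) r <- quantileNormalize(r)
  cd <- samples[match(colnames(r), samples$array_id), , drop = FALSE]
  rownames(cd) <- cd$array_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = r), colData = S4Vectors::DataFrame(cd))
  obj <- methods::new("NormalizedRatios", se)
  S4Vectors::metadata(obj)$provenance <- list(
    background = background, eps = eps, quantile = quantile,
    dropped_probes = dropped, merged = FALSE)
  obj
}

#' Merge replicate arrays into per-subject ratios
#'
#' Per subject, the probe value is the unweighted mean of its replicate
#' arrays' normalized ratios (a single replicate passes through
#' unchanged). Flagged arrays can be excluded first via `exclude`.
#'
#' @param ratios a [NormalizedRatios] with one column per array.
#' @param exclude optional character vector of array ids to drop (e.g.
#'   QC-flagged arrays under a strict policy).
#' @return A [NormalizedRatios] with one column per subject.
#' @export
mergeReplicates <- function(ratios, exclude = NULL) {
  stopifnot(methods::is(ratios, "NormalizedRatios"))
  x <- ratioMatrix(ratios)
  cd <- as.data.frame(SummarizedExperiment::colData(ratios))
  if (length(exclude)) {
    keep <- !cd$array_id %in% exclude
    x <- x[, keep, drop = FALSE]
    cd <- cd[keep, , drop = FALSE]
  }
  subjects <- unique(cd$subject_id)
  lost <- setdiff(unique(as.data.frame(
    SummarizedExperiment::colData(ratios))$subject_id), subjects)
  if (length(lost))
    stop("subject(s) with zero usable arrays: ", paste(lost, collapse = ", "))
  merged <- vapply(subjects, function(s)
    rowMeans(x[, cd$subject_id == s, drop = FALSE]), numeric(nrow(x)))
  merged <- matrix(merged, nrow = nrow(x),
                   dimnames = list(rownames(x), subjects))
  cd2 <- cd[match(subjects, cd$subject_id),
            setdiff(colnames(cd), "array_id"), drop = FALSE]
  rownames(cd2) <- subjects
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = merged), colData = S4Vectors::DataFrame(cd2))
  obj <- methods::new("NormalizedRatios", se)
  prov <- S4Vectors::metadata(ratios)$provenance %||% list()
  prov$merged <- TRUE
  prov$merge_map <- split(cd$array_id, cd$subject_id)
  S4Vectors::metadata(obj)$provenance <- prov
  obj
}
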