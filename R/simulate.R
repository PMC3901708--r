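# Synthetic cohort generator: ground truth, two-channel MeDIP intensities
# and pooled beta tables with the statistical structure the analysis
# assumes, so every downstream stage is testable without external data.

#' Simulation configuration
#'
#' Builds the configuration for the synthetic-cohort generator. Defaults
#' emulate the study conditions the pipeline targets: 5 case (CPA) vs 14
#' control (NPA) female subjects, two replicate arrays each, a 2,000-gene
#' single-chromosome promoter tiling design (100 bp probe spacing over
#' TSS -1000..+200), a 2% promoter effect fraction with an 82%
#' hypomethylated-in-CPA direction bias, megabase-scale spatial clustering
#' of effects (1.5 Mb), a CpG-density link for hypermethylated effects,
#' and three pools per group for the beta-value validation arm.
#'
#' @param n_genes number of genes (one promoter each at desk scale).
#' @param n_cpa,n_npa subjects per group.
#' @param replicates replicate arrays per subject.
#' @param effect_fraction fraction `pi` of promoters carrying a group effect.
#' @param hypo_bias among effect promoters, the probability the CPA group
#'   is hypomethylated.
#' @param delta effect size on the methylation scale.
#' @param gain,offset coupling of CpG-weighted methylation to log2
#'   enrichment ratio: `r = gain * m * w + offset`.
#' @param probe_sd SD of the fixed per-probe affinity effect (log2 scale).
#' @param array_sd SD of the per-array global shift.
#' @param bio_sd SD of subject-by-probe biological noise (shared by the
#'   subject's replicates). Probe-level noise is independent across probes,
#'   the exchangeability the promoter rank-sum test assumes.
#' @param replicate_sd SD of array-by-probe technical noise.
#' @param input_meanlog,input_sdlog log-normal parameters of the input
#'   channel intensities.
#' @param cluster_scale spatial scale L (bp) of effect clustering.
#' @param cluster_size expected effect promoters per cluster centre
#'   (sets the number of centres as `effect_fraction * n_genes /
#'   cluster_size`).
#' @param spacing_min,spacing_max uniform range of promoter spacing (bp).
#' @param chrom chromosome name of the single synthetic chromosome.
#' @param probe_spacing,upstream,downstream,probe_length array geometry (bp).
#' @param coupling_bp half-width of the CpG coupling window around each
#'   probe: MeDIP enrichment integrates methylation over the
#'   immunoprecipitated fragment, so CpGs within `coupling_bp` of the
#'   probe contribute to its signal.
#' @param inject_cpg named vector: CpG dinucleotides injected per promoter
#'   window for the `low`/`mid`/`high` density classes.
#' @param class_probs probabilities of the three density classes.
#' @param hyper_class_weight,hypo_class_weight density-class tilt applied
#'   to hypermethylated (toward high density) and hypomethylated (toward
#'   low density) effect promoters, linking effect direction to CpG
#'   density.
#' @param pools_per_group 450K-arm pools per group.
#' @param cpgs_per_promoter CpG sites per promoter on the beta array.
#' @param beta_sd SD of beta-value noise per pool.
#' @param detection_fail_rate fraction of CpGs given a failing detection
#'   p-value in one pool.
#' @param snp_frac fraction of CpGs flagged with a SNP within 10 bp.
#' @return A classed list (`SimConfig`).
#' @export
simConfig <- function(n_genes = 2000, n_cpa = 5, n_npa = 14, replicates = 2,
                      effect_fraction = 0.02, hypo_bias = 0.82, delta = 0.3,
                      gain = 2, offset = -0.5,
                      probe_sd = 0.25, array_sd = 0.1, bio_sd = 0.1,
                      replicate_sd = 0.12,
                      input_meanlog = log(500), input_sdlog = 0.3,
                      cluster_scale = 1.5e6, cluster_size = 20,
                      spacing_min = 30e3, spacing_max = 150e3,
                      chrom = "chrS1",
                      probe_spacing = 100, upstream = 1000, downstream = 200,
                      probe_length = 50, coupling_bp = 300,
                      inject_cpg = c(low = 6, mid = 15, high = 45),
                      class_probs = c(low = 0.4, mid = 0.4, high = 0.2),
                      hyper_class_weight = c(low = 1, mid = 3, high = 16),
                      hypo_class_weight = c(low = 8, mid = 2, high = 1),
                      pools_per_group = 3, cpgs_per_promoter = 2,
                      beta_sd = 0.03, detection_fail_rate = 0.02,
                      snp_frac = 0.05) {
  cfg <- as.list(environment())
  assertScalarNumber(cfg$effect_fraction, "effect_fraction", 0, 1)
  assertScalarNumber(cfg$hypo_bias, "hypo_bias", 0, 1)
  for (nm in c("probe_sd", "array_sd", "bio_sd", "replicate_sd", "beta_sd"))
    assertScalarNumber(cfg[[nm]], nm, 0)
  assertScalarNumber(cfg$cluster_scale, "cluster_scale", 1)
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  class(cfg) <- "SimConfig"
  cfg
}

## Generate promoter-window sequences (plus padding for edge probes) as a
## character matrix: CpG-depleted random background with class-dependent
## CpG injection. Returns list(mat, pad).
generatePromoterSequences <- function(n, window_len, pad, inject) {
  len <- window_len + 2L * pad
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, n * len, replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3)),
                nrow = n, ncol = len)
  ## deplete background CpGs (vertebrate genomes are strongly CpG-poor)
  is_cg <- mat[, -len, drop = FALSE] == "C" & mat[, -1L, drop = FALSE] == "G"
  idx <- which(is_cg)
  mut <- idx[stats::runif(length(idx)) < 0.8]
  mat[mut + n] <- "A"  # (i, j) in is_cg maps to (i, j + 1) in mat
  ## inject class-dependent CpGs inside the window proper
  k <- stats::rpois(n, inject)
  if (sum(k)) {
    rows <- rep.int(seq_len(n), k)
    cols <- pad + sample.int(window_len - 1L, sum(k), replace = TRUE)
    mat[cbind(rows, cols)] <- "C"
    mat[cbind(rows, cols + 1L)] <- "G"
  }
  list(mat = mat, pad = pad)
}

#' Simulate ground truth and array design for a synthetic cohort
#'
#' Lays promoters along one synthetic chromosome at uniform random
#' spacing and samples spatially clustered group effects: effect
#' probability decays exponentially with distance to the nearest cluster
#' centre at scale `cluster_scale` and is truncated at one scale length,
#' so effects live in clusters of radius `cluster_scale` and the spatial
#' correlation of group differences dies out by twice that scale. Effect
#' directions are independent draws at the configured hypomethylation
#' bias; each promoter then receives a CpG-density class (hypermethylated
#' effects tilted toward the high-density class, hypomethylated toward
#' the low) and a synthetic window sequence generated at that class's
#' CpG density.
#'
#' @param config a [simConfig()] list.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A [TruthSet] (carrying the [ArrayDesign] with CpG counts and
#'   the synthetic promoter sequences).
#' @export
simulateTruth <- function(config = simConfig(), seed = 1) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(seed, {
    n <- config$n_genes
    if (config$effect_fraction * n < 1)
      warning("effect_fraction * n_genes < 1: simulating a no-signal cohort")
    spacing <- stats::runif(n, config$spacing_min, config$spacing_max)
    tss_pos <- as.integer(round(1e6 + cumsum(spacing)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("PR%05d", seq_len(n))
    genes <- sprintf("G%05d", seq_len(n))

    ## spatially clustered effects: effect probability decays
    ## exponentially with distance to the nearest cluster centre at scale
    ## cluster_scale; the proportionality constant is solved so the
    ## expected effect count equals effect_fraction * n_genes even where
    ## the probability saturates at 1 near centres
    n_target <- config$effect_fraction * n
    ## enough centres that the clusters (radius = cluster_scale) can host
    ## the expected effect count with headroom
    capacity <- 2 * config$cluster_scale /
      ((config$spacing_min + config$spacing_max) / 2)
    n_centers <- max(1L, round(n_target / config$cluster_size),
                     ceiling(1.25 * n_target / capacity))
    centers <- sort(tss_pos[sample.int(n, min(n_centers, n))])
    d <- vapply(tss_pos, function(p) min(abs(p - centers)), numeric(1))
    ## exponential decay at scale cluster_scale, truncated at one scale
    ## length: effects live inside clusters of radius cluster_scale, so
    ## within-cluster pair separations (and hence the spatial correlation
    ## of group differences) cannot exceed twice the cluster scale
    wgt <- ifelse(d <= config$cluster_scale,
                  exp(-d / config$cluster_scale), 0)
    p_eff <- rep(0, n)
    if (n_target > 0) {
      cc <- n_target / sum(wgt)
      for (it in 1:25) {
        p_eff <- pmin(1, cc * wgt)
        excess <- n_target - sum(p_eff)
        if (abs(excess) < 1e-9) break
        free <- sum(wgt[cc * wgt < 1])
        if (free <= 0) break
        cc <- cc * (1 + excess / (cc * free))
      }
    }
    effect <- stats::runif(n) < p_eff
    cluster_id <- ifelse(effect,
                         vapply(tss_pos, function(p) which.min(abs(p - centers)),
                                integer(1)), NA_integer_)

    ## directions independent across effect promoters (binomial around
    ## the configured hypomethylation bias)
    direction <- rep(NA_character_, n)
    eff_idx <- which(effect)
    if (length(eff_idx))
      direction[eff_idx] <- ifelse(stats::runif(length(eff_idx)) <
                                     config$hypo_bias, "hypo", "hyper")

    ## CpG-density classes: null promoters follow the genome-wide class
    ## mix; hypermethylated effects are tilted toward the high-density
    ## class and hypomethylated effects toward the low-density class
    ## (observed/expected density asymmetry by direction)
    drawClass <- function(k, weight = NULL) {
      p <- config$class_probs
      if (!is.null(weight)) p <- p * weight[names(p)]
      sample(names(config$class_probs), k, replace = TRUE, prob = p)
    }
    classes <- drawClass(n)
    is_hyper <- !is.na(direction) & direction == "hyper"
    is_hypo <- !is.na(direction) & direction == "hypo"
    classes[is_hyper] <- drawClass(sum(is_hyper), config$hyper_class_weight)
    classes[is_hypo] <- drawClass(sum(is_hypo), config$hypo_class_weight)

    window_len <- config$upstream + config$downstream
    pad <- as.integer(ceiling(config$probe_length / 2) + config$coupling_bp)
    sq <- generatePromoterSequences(n, window_len, pad,
                                    config$inject_cpg[classes])

    tss_df <- data.frame(promoter_id = ids, gene_id = genes,
                         chrom = config$chrom, tss = tss_pos,
                         strand = strand, stringsAsFactors = FALSE)
    design <- buildArrayDesign(tss_df, spacing = config$probe_spacing,
                               upstream = config$upstream,
                               downstream = config$downstream,
                               probeLength = config$probe_length,
                               genomeBuild = "synthetic")

    ## per-probe CpG counts from the padded window sequences
    pr <- probes(design)
    prm <- promoterWindows(design)
    first_map <- probeMap(design)[!duplicated(probeMap(design)$probe_id), ]
    pi_idx <- match(pr$probe_id, first_map$probe_id)
    prom_idx <- match(first_map$promoter_id[pi_idx], prm$promoter_id)
    pad_start <- GenomicRanges::start(prm)[prom_idx] - pad  # genomic pos of column 1
    rel <- GenomicRanges::start(pr) - pad_start + 1L
    seq_chr <- apply(sq$mat, 1L, paste, collapse = "")
    probe_seq <- substring(seq_chr[prom_idx], rel,
                           rel + config$probe_length - 1L)
    cnt <- countCpg(probe_seq)
    pr$cpg_count <- cnt[, "cpg_count"]
    pr$c_count <- cnt[, "c_count"]
    pr$g_count <- cnt[, "g_count"]
    ## fragment-scale coupling: CpGs within probe +/- coupling_bp
    ext_seq <- substring(seq_chr[prom_idx],
                         pmax(1L, rel - config$coupling_bp),
                         rel + config$probe_length - 1L + config$coupling_bp)
    pr$coupling_cpg <- countCpg(ext_seq)[, "cpg_count"]
    design@probes <- pr

    window_seq <- Biostrings::DNAStringSet(
      substring(seq_chr, pad + 1L, pad + window_len))
    names(window_seq) <- ids

    ## intermediate baselines: +/- delta effects stay inside [0,1], so the
    ## configured effect size is fully expressed on the methylation scale
    m0 <- 0.25 + 0.5 * stats::rbeta(n, 2, 2)
    truth <- data.frame(
      promoter_id = ids, gene_id = genes, chrom = config$chrom,
      tss = tss_pos, m0 = m0, effect = effect, direction = direction,
      delta = ifelse(effect, config$delta, 0),
      cluster_id = cluster_id, density_class = classes,
      stringsAsFactors = FALSE)

    methods::new("TruthSet", promoterTruth = truth, design = design,
                 sequences = window_seq, config = unclass(config))
  })
}

## promoter x subject methylation matrix implied by the truth
subjectMethylation <- function(truth, config) {
  tt <- truthTable(truth)
  n_sub <- config$n_cpa + config$n_npa
  m <- matrix(tt$m0, nrow = nrow(tt), ncol = n_sub)
  shift <- ifelse(tt$effect & tt$direction == "hyper", tt$delta,
                  ifelse(tt$effect, -tt$delta, 0))
  m[, seq_len(config$n_cpa)] <- m[, seq_len(config$n_cpa)] + shift
  m[] <- pmin(1, pmax(0, m))
  rownames(m) <- tt$promoter_id
  m
}

## CpG coupling weight per probe: fragment-scale CpG count (probe +/-
## coupling distance when available, else the probe window) normalized to
## the maximum within the probe's promoter.
probeCouplingWeights <- function(design) {
  pr <- probes(design)
  map <- probeMap(design)[!duplicated(probeMap(design)$probe_id), ]
  counts <- pr$coupling_cpg %||% pr$cpg_count
  cpg <- counts[match(map$probe_id, pr$probe_id)]
  mx <- tapply(cpg, map$promoter_id, max)
  w <- cpg / pmax(1, mx[map$promoter_id])
  names(w) <- map$probe_id
  w[pr$probe_id]
}

#' Simulate two-channel MeDIP array intensities for a cohort
#'
#' Inverts the measurement chain: for probe j of promoter i and subject s,
#' the true log2 enrichment ratio is
#' `r = gain * m[i,s] * w[j] + offset + probe effect + array shift +
#' subject-by-probe noise + replicate noise`, with `w[j]` the probe CpG
#' count normalized to the promoter maximum. The input channel is drawn
#' log-normal per probe and array, and `bound = input * 2^r`.
#'
#' @param truth a [TruthSet] from [simulateTruth()].
#' @param config the [simConfig()] used (defaults to the truth's config).
#' @param seed integer seed.
#' @return A list: `bound` and `input` matrices (probes x arrays), and
#'   `samples`, the sample-sheet `data.frame` (one row per array).
#' @export
simulateMedipArrays <- function(truth, config = NULL, seed = 1) {
  config <- config %||% do.call(simConfig, truthConfigArgs(truth))
  stopifnot(inherits(config, "SimConfig"))
  withSeed(seed, {
    design <- truthDesign(truth)
    pr <- probes(design)
    n_probe <- length(pr)
    subjects <- sprintf("S%02d", seq_len(config$n_cpa + config$n_npa))
    group <- rep(c("CPA", "NPA"), c(config$n_cpa, config$n_npa))
    samples <- data.frame(
      subject_id = rep(subjects, each = config$replicates),
      group = rep(group, each = config$replicates),
      sex = "F",
      array_id = paste0(rep(subjects, each = config$replicates), "_A",
                        seq_len(config$replicates)),
      stringsAsFactors = FALSE)

    m <- subjectMethylation(truth, config)
    w <- probeCouplingWeights(design)
    map <- probeMap(design)[!duplicated(probeMap(design)$probe_id), ]
    prom_of_probe <- map$promoter_id[match(pr$probe_id, map$probe_id)]
    r_true <- config$gain * m[prom_of_probe, , drop = FALSE] * w +
      config$offset
    colnames(r_true) <- subjects

    probe_eff <- stats::rnorm(n_probe, 0, config$probe_sd)
    bio <- matrix(stats::rnorm(n_probe * length(subjects), 0, config$bio_sd),
                  nrow = n_probe)
    n_arr <- nrow(samples)
    array_shift <- stats::rnorm(n_arr, 0, config$array_sd)
    sub_idx <- match(samples$subject_id, subjects)
    r_arr <- r_true[, sub_idx, drop = FALSE] + bio[, sub_idx, drop = FALSE] +
      probe_eff +
      matrix(stats::rnorm(n_probe * n_arr, 0, config$replicate_sd),
             nrow = n_probe) +
      rep(array_shift, each = n_probe)
    input <- matrix(stats::rlnorm(n_probe * n_arr, config$input_meanlog,
                                  config$input_sdlog), nrow = n_probe)
    bound <- input * 2^r_arr
    dimnames(bound) <- dimnames(input) <-
      list(pr$probe_id, samples$array_id)
    list(bound = bound, input = input, samples = samples)
  })
}

truthConfigArgs <- function(truth) {
  cfg <- truth@config
  cfg[names(cfg) %in% names(formals(simConfig))]
}

#' Simulate pooled beta-value (450K-style) tables
#'
#' Builds `pools_per_group` DNA pools per group, places
#' `cpgs_per_promoter` CpG sites inside each promoter window, and draws
#' per-pool beta values as the pool-average methylation plus bounded
#' noise, clipped to [0,1]. A configurable fraction of CpGs receives a
#' failing detection p-value (> 0.001) in one pool and another fraction a
#' SNP within 10 bp, to exercise the probe filters.
#'
#' @param truth a [TruthSet].
#' @param config the [simConfig()] used.
#' @param seed integer seed.
#' @return A list: `beta` (CpG x pool matrix), `detp` (matching detection
#'   p-values), `manifest` (`data.frame`: `cpg_id`, `chrom`, `pos`,
#'   `snp_distance`, `promoter_id`, `gene_id`), and `pools`
#'   (`data.frame`: `pool_id`, `group`).
#' @export
simulate450kPools <- function(truth, config = NULL, seed = 1) {
  config <- config %||% do.call(simConfig, truthConfigArgs(truth))
  stopifnot(inherits(config, "SimConfig"))
  if (config$pools_per_group < 2)
    stop("at least 2 pools per group are required for a differential test")
  withSeed(seed, {
    tt <- truthTable(truth)
    design <- truthDesign(truth)
    prm <- promoterWindows(design)
    k <- config$cpgs_per_promoter
    n <- nrow(tt) * k
    prom_idx <- rep(seq_len(nrow(tt)), each = k)
    pos <- GenomicRanges::start(prm)[prom_idx] +
      sample.int(GenomicRanges::width(prm)[1L], n, replace = TRUE) - 1L
    manifest <- data.frame(
      cpg_id = sprintf("cg%07d", seq_len(n)),
      chrom = as.character(GenomicRanges::seqnames(prm))[prom_idx],
      pos = pos,
      snp_distance = ifelse(stats::runif(n) < config$snp_frac,
                            sample(0:10, n, replace = TRUE),
                            sample(100:10000, n, replace = TRUE)),
      promoter_id = prm$promoter_id[prom_idx],
      gene_id = prm$gene_id[prom_idx],
      stringsAsFactors = FALSE)

    pools <- data.frame(
      pool_id = c(sprintf("CPA_P%d", seq_len(config$pools_per_group)),
                  sprintf("NPA_P%d", seq_len(config$pools_per_group))),
      group = rep(c("CPA", "NPA"), each = config$pools_per_group),
      stringsAsFactors = FALSE)

    shift <- ifelse(tt$effect & tt$direction == "hyper", tt$delta,
                    ifelse(tt$effect, -tt$delta, 0))
    site_off <- stats::rnorm(n, 0, 0.05)
    m_cpg_npa <- pmin(1, pmax(0, tt$m0[prom_idx] + site_off))
    m_cpg_cpa <- pmin(1, pmax(0, tt$m0[prom_idx] + shift[prom_idx] + site_off))
    base <- cbind(matrix(m_cpg_cpa, n, config$pools_per_group),
                  matrix(m_cpg_npa, n, config$pools_per_group))
    beta <- base + matrix(stats::rnorm(length(base), 0, config$beta_sd),
                          nrow = n)
    beta[beta < 0] <- 0
    beta[beta > 1] <- 1
    dimnames(beta) <- list(manifest$cpg_id, pools$pool_id)

    detp <- matrix(stats::runif(length(beta), 0, 1e-4), nrow = n,
                   dimnames = dimnames(beta))
    n_fail <- round(config$detection_fail_rate * n)
    if (n_fail > 0) {
      fail_cpg <- sample.int(n, n_fail)
      fail_pool <- sample.int(ncol(detp), n_fail, replace = TRUE)
      detp[cbind(fail_cpg, fail_pool)] <- stats::runif(n_fail, 0.0015, 0.05)
    }
    list(beta = beta, detp = detp, manifest = manifest, pools = pools)
  })
}

#' Simulate a complete cohort (truth, MeDIP arrays, beta tables)
#'
#' Convenience wrapper chaining [simulateTruth()], [simulateMedipArrays()]
#' and [simulate450kPools()] with sub-seeds derived from `seed`.
#'
#' @param config a [simConfig()].
#' @param seed integer seed.
#' @return A list: `truth`, `arrays`, `betas`.
#' @export
simulateCohort <- function(config = simConfig(), seed = 1) {
  truth <- simulateTruth(config, seed = seed)
  arrays <- simulateMedipArrays(truth, config, seed = seed + 1000L)
  betas <- simulate450kPools(truth, config, seed = seed + 2000L)
  list(truth = truth, arrays = arrays, betas = betas)
}
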