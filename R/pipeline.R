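# End-to-end pipeline driver: configuration validation, stage ordering,
# structured logging and a reproducibility manifest.

#' Run the full differential-methylation pipeline
#'
#' Executes, in order: normalize (QC, background subtraction, quantile
#' normalization, replicate merge), dmr (probe moderated t, promoter
#' rank-sum, FDR, call rule, heatmap matrix + clustering), deconvolve
#' (promoter methylation estimates), organization (spatial correlation
#' curve and, when region sequences are available, CpG-density
#' statistics), optionally beta450k (pooled beta filters + differential
#' test + promoter mapping) and overlap (cross-arm gene overlap). Every
#' stage writes its outputs under `out_dir` and is re-runnable from
#' those files alone; all randomness flows from `seed`.
#'
#' @param config a list (or YAML file path) with elements:
#'   `design` (TSV path), `intensities` (TSV path), `samples` (CSV
#'   path), optional `genome` (FASTA path), optional `betas`, `detp`,
#'   `manifest450k`, `pools` (CSV paths for the beta arm), and optional
#'   `thresholds` overrides (`probe_p`, `lfc`, `promoter_q`, `detp_max`,
#'   `snp_bp`) and `stages` (character subset to run).
#' @param out_dir output directory (created).
#' @param seed integer seed for the organization stage.
#' @return the run manifest (list), invisibly; also written as JSON.
#' @export
runPipeline <- function(config, out_dir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- utils::modifyList(
    list(probe_p = 0.05, lfc = 0.25, promoter_q = 0.05,
         detp_max = 0.001, snp_bp = 10),
    config$thresholds %||% list())
  all_stages <- c("normalize", "dmr", "deconvolve", "organization",
                  "beta450k", "overlap")
  stages <- config$stages %||%
    all_stages[c(TRUE, TRUE, TRUE, TRUE, !is.null(config$betas),
                 !is.null(config$betas))]
  stages <- match.arg(stages, all_stages, several.ok = TRUE)

  ## validate the configuration before any compute
  need <- c("design", "intensities", "samples")
  if ("beta450k" %in% stages)
    need <- c(need, "betas", "detp", "manifest450k", "pools")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("configuration error: missing input(s): ",
         paste(missing, collapse = ", "))
  paths <- unlist(config[intersect(names(config),
                                   c(need, "genome", "sequences"))])
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("configuration error: input file(s) not found: ",
         paste(absent, collapse = ", "))

  logf <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                              append = TRUE)
  cat("", file = logf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("medipDMR")),
    seed = seed, thresholds = thr, stages = stages,
    inputs = lapply(as.list(paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = list())
  emit <- function(name, df, writer = NULL) {
    path <- file.path(out_dir, name)
    if (is.null(writer))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else writer(path)
    manifest$outputs[[name]] <<- list(
      path = path, rows = if (is.data.frame(df)) nrow(df) else NA)
    path
  }

  design <- loadArrayDesign(config$design, genome = config$genome)
  samples <- loadSampleSheet(config$samples)
  raw <- loadIntensityTable(config$intensities, design)

  results <- list(design = design)

  if ("normalize" %in% stages) {
    qc <- qcSummary(raw, samples)
    logmsg("normalize: %d arrays, %d flagged", nrow(qc), sum(qc$flagged))
    ratios <- normalizeRatios(raw, samples)
    merged <- mergeReplicates(ratios)
    logmsg("normalize: %d probes x %d subjects after merge",
           nrow(merged), ncol(merged))
    emit("qc_report.tsv", qc)
    rt <- data.frame(probe_id = rownames(ratioMatrix(merged)),
                     ratioMatrix(merged), check.names = FALSE)
    emit("ratios_subjects.tsv", rt)
    results$qc <- qc; results$ratios <- merged
  }

  if ("dmr" %in% stages) {
    ps <- probeModeratedT(results$ratios)
    prs <- promoterRankSum(ps, design)
    dmr <- callDmrs(ps, prs, design, probe_p_max = thr$probe_p,
                    lfc_min = thr$lfc, q_max = thr$promoter_q)
    logmsg("dmr: %d promoters tested, %d called (%d hypo / %d hyper)",
           sum(prs$tested), nrow(dmr$calls),
           dmr$direction_counts["hypo"], dmr$direction_counts["hyper"])
    emit("probe_stats.tsv", ps)
    emit("promoter_stats.tsv", prs)
    emit("dmr_calls.tsv", dmr$calls)
    prm <- promoterWindows(design)
    hit <- prm[match(dmr$calls$promoter_id, prm$promoter_id)]
    if (length(hit)) hit$name <- dmr$calls$promoter_id
    emit("dmr_calls.bed", dmr$calls, writer = function(p)
      writeDmrBed(hit, dmr$calls$q, p))
    if (nrow(dmr$calls) >= 2L) {
      hm <- representativeProbes(dmr$calls, ps, results$ratios, design)
      emit("heatmap_matrix.tsv",
           data.frame(row = rownames(hm), hm, check.names = FALSE))
      if (nrow(hm) >= 2L &&
          !any(apply(hm, 1L, stats::sd) == 0) &&
          !any(apply(hm, 2L, stats::sd) == 0)) {
        cl <- wardCluster(hm)
        emit("linkage.json", NULL, writer = function(p)
          jsonlite::write_json(list(
            rows = list(merge = cl$rows$merge, height = cl$rows$height,
                        order = cl$rows$order, labels = cl$rows$labels),
            cols = list(merge = cl$cols$merge, height = cl$cols$height,
                        order = cl$cols$order, labels = cl$cols$labels)),
            p, auto_unbox = TRUE, digits = NA))
      }
    }
    results$probe_stats <- ps; results$promoter_stats <- prs
    results$dmr <- dmr
  }

  if ("deconvolve" %in% stages) {
    est <- estimatePromoterMethylation(results$ratios, design)
    logmsg("deconvolve: %d promoters estimated, %d excluded",
           sum(!is.na(est$m_hat)), sum(is.na(est$m_hat)))
    emit("promoter_methylation.tsv", est)
    results$methylation <- est
  }

  if ("organization" %in% stages) {
    pr <- probes(design)
    ps <- results$probe_stats
    mid <- (GenomicRanges::start(pr) + GenomicRanges::end(pr)) / 2
    k <- match(ps$probe_id, pr$probe_id)
    cv <- config$curve %||% list()
    curve <- spatialCorrelationCurve(
      ps$log2fc, as.character(GenomicRanges::seqnames(pr))[k], mid[k],
      bin_edges = unlist(cv$bin_edges) %||% defaultDistanceBins(),
      n_boot = cv$n_boot %||% 1000, n_perm = cv$n_perm %||% 500,
      pair_cap = cv$pair_cap %||% 200000,
      seed = seed)
    dl <- decorrelationLength(curve)
    logmsg("organization: decorrelation length %.0f bp", dl)
    emit("spatial_curve.tsv", curveBins(curve))
    manifest$outputs[["decorrelation_length_bp"]] <- dl
    results$curve <- curve; results$decorrelation_length <- dl
    seq_path <- config$sequences %||% NULL
    if (!is.null(seq_path) && nrow(results$dmr$calls)) {
      seqs <- Biostrings::readDNAStringSet(seq_path)
      calls <- results$dmr$calls
      idx <- calls$promoter_id %in% names(seqs)
      dens <- normalizedCpgDensity(seqs[calls$promoter_id[idx]],
                                   group = calls$direction[idx])
      emit("cpg_density.tsv", dens$table)
      results$density <- dens
      if (!is.null(dens$test))
        logmsg("organization: density asymmetry p = %.3g", dens$test$p)
    }
  }

  if ("beta450k" %in% stages) {
    bt <- utils::read.csv(config$betas, row.names = 1, check.names = FALSE)
    dp <- utils::read.csv(config$detp, row.names = 1, check.names = FALSE)
    mf <- utils::read.csv(config$manifest450k, stringsAsFactors = FALSE)
    pools <- utils::read.csv(config$pools, stringsAsFactors = FALSE)
    flt <- filterProbes450k(as.matrix(bt), as.matrix(dp), mf,
                            detp_max = thr$detp_max, snp_bp = thr$snp_bp)
    logmsg("beta450k: %d/%d CpGs kept (%d detection, %d SNP)",
           flt$report["n_kept"], flt$report["n_input"],
           flt$report["n_detp_fail"], flt$report["n_snp"])
    ds <- poolDifferential(flt$beta,
                           pools$group[match(colnames(flt$beta),
                                             pools$pool_id)])
    hits <- mapCpgsToPromoters(ds, mf, design)
    logmsg("beta450k: %d significant CpGs, %d promoter hits",
           sum(ds$significant), nrow(hits))
    emit("cpg_diff_stats.tsv", ds)
    emit("promoter_hits_450k.tsv", hits)
    results$beta450k <- list(filter = flt$report, stats = ds, hits = hits)
  }

  if ("overlap" %in% stages && !is.null(results$beta450k)) {
    genes_a <- unique(results$dmr$calls$gene_id)
    genes_b <- unique(results$beta450k$hits$gene_id)
    prm <- promoterWindows(design)
    universe <- length(unique(prm$gene_id))
    if (length(genes_a) && length(genes_b)) {
      ov <- setOverlapTest(genes_a, genes_b, n_universe = universe)
      logmsg("overlap: %d/%d genes shared, p = %.3g",
             ov$n_overlap, min(ov$n_a, ov$n_b), ov$p)
      emit("cross_arm_overlap.tsv",
           data.frame(n_medip = ov$n_a, n_450k = ov$n_b,
                      n_overlap = ov$n_overlap, universe = universe,
                      p = ov$p, odds_ratio = ov$odds_ratio))
      results$overlap <- ov
    }
  }

  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}

#' Generate a synthetic cohort on disk and run the whole pipeline on it
#'
#' Writes a simulated cohort (design TSV, intensity TSV, sample sheet
#' CSV, promoter sequences FASTA, beta/detection/manifest/pool CSVs and
#' the ground truth) under `out_dir/inputs`, then runs [runPipeline()]
#' on those files. Small by default so it finishes in well under a
#' minute.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param config a [simConfig()]; default is a 300-gene miniature of the
#'   full study conditions.
#' @return list with the pipeline results and the [TruthSet], invisibly.
#' @export
runDemo <- function(out_dir, seed = 1,
                    config = simConfig(n_genes = 300)) {
  inp <- file.path(out_dir, "inputs")
  dir.create(inp, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulateCohort(config, seed = seed)
  truth <- cohort$truth
  design <- truthDesign(truth)

  writeArrayDesign(design, file.path(inp, "design.tsv"))
  writeIntensityTable(cohort$arrays, file.path(inp, "intensities.tsv"))
  utils::write.csv(cohort$arrays$samples, file.path(inp, "samples.csv"),
                   row.names = FALSE)
  Biostrings::writeXStringSet(truthSequences(truth),
                              file.path(inp, "promoter_sequences.fa"))
  utils::write.csv(data.frame(cpg_id = rownames(cohort$betas$beta),
                              cohort$betas$beta, check.names = FALSE),
                   file.path(inp, "betas.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cpg_id = rownames(cohort$betas$detp),
                              cohort$betas$detp, check.names = FALSE),
                   file.path(inp, "detp.csv"), row.names = FALSE)
  utils::write.csv(cohort$betas$manifest, file.path(inp, "manifest450k.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$betas$pools, file.path(inp, "pools.csv"),
                   row.names = FALSE)
  utils::write.table(truthTable(truth), file.path(inp, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cfg <- list(design = file.path(inp, "design.tsv"),
              intensities = file.path(inp, "intensities.tsv"),
              samples = file.path(inp, "samples.csv"),
              sequences = file.path(inp, "promoter_sequences.fa"),
              betas = file.path(inp, "betas.csv"),
              detp = file.path(inp, "detp.csv"),
              manifest450k = file.path(inp, "manifest450k.csv"),
              pools = file.path(inp, "pools.csv"),
              ## light resampling settings: the demo shows the moving
              ## parts, not publication-grade interval estimates
              curve = list(n_boot = 200, n_perm = 100, pair_cap = 20000))
  res <- runPipeline(cfg, out_dir, seed = seed)
  invisible(list(results = res, truth = truth))
}
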