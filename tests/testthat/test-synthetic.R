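# Synthetic-cohort generator: determinism, configured rates, measurement
# model, and the emulated genomic structure.

test_that("generators are deterministic given the seed", {
  cfg <- simConfig(n_genes = 60)
  t1 <- simulateTruth(cfg, seed = 5)
  t2 <- simulateTruth(cfg, seed = 5)
  expect_identical(truthTable(t1), truthTable(t2))
  expect_identical(as.character(truthSequences(t1)),
                   as.character(truthSequences(t2)))
  a1 <- simulateMedipArrays(t1, cfg, seed = 6)
  a2 <- simulateMedipArrays(t2, cfg, seed = 6)
  expect_identical(a1$bound, a2$bound)
  b1 <- simulate450kPools(t1, cfg, seed = 8)
  b2 <- simulate450kPools(t2, cfg, seed = 8)
  expect_identical(b1$beta, b2$beta)
  ## generators restore the caller's RNG stream
  set.seed(42); x <- runif(1)
  set.seed(42); invisible(simulateTruth(cfg, seed = 3)); y <- runif(1)
  expect_identical(x, y)
})

test_that("zero effect fraction gives a no-signal cohort with a warning", {
  expect_warning(t0 <- simulateTruth(simConfig(n_genes = 50,
                                               effect_fraction = 0),
                                     seed = 2),
                 "no-signal")
  expect_equal(sum(truthTable(t0)$effect), 0L)
  expect_true(all(is.na(truthTable(t0)$direction)))
})

test_that("effect count and direction bias land within binomial bounds", {
  tt <- truthTable(signalCohort()$truth)
  n_eff <- sum(tt$effect)
  expect_gt(n_eff, 40 - 3 * sqrt(40 * 0.98))
  expect_lt(n_eff, 40 + 3 * sqrt(40 * 0.98))
  n_hypo <- sum(tt$direction == "hypo", na.rm = TRUE)
  expect_lt(abs(n_hypo - 0.82 * n_eff), 3 * sqrt(n_eff * 0.82 * 0.18))
  ## baseline methylation respects its bounds
  expect_true(all(tt$m0 >= 0 & tt$m0 <= 1))
})

test_that("default sample sheet is 19 subjects with 2 replicate arrays", {
  samples <- signalCohort()$cohort$arrays$samples
  expect_equal(nrow(samples), 38L)
  expect_equal(length(unique(samples$subject_id)), 19L)
  expect_true(all(table(samples$subject_id) == 2L))
  expect_equal(sum(samples$group == "CPA"), 10L)  # 5 subjects x 2 arrays
})

test_that("zero-noise ratios invert to the coupling model exactly", {
  cfg <- simConfig(n_genes = 30, probe_sd = 0, array_sd = 0, bio_sd = 0,
                   replicate_sd = 0, gain = 1, offset = 0,
                   effect_fraction = 0)
  truth <- suppressWarnings(simulateTruth(cfg, seed = 3))
  arr <- simulateMedipArrays(truth, cfg, seed = 4)
  ## background subtraction off: identical input distributions, no noise
  ratios <- normalizeRatios(arr, arr$samples, background = "none")
  r <- ratioMatrix(ratios)
  tt <- truthTable(truth)
  design <- truthDesign(truth)
  pr <- probes(design)
  map <- probeMap(design)
  w_expected <- medipDMR:::probeCouplingWeights(design)
  m0 <- tt$m0[match(map$promoter_id[match(rownames(r), map$probe_id)],
                    tt$promoter_id)]
  expect_equal(unname(r[, 1]), unname(m0 * w_expected[rownames(r)]),
               tolerance = 1e-9)
})

test_that("group mean log2FC sign matches the injected direction", {
  fx <- signalCohort()
  tt <- truthTable(fx$truth)
  ps <- fx$probe_stats
  map <- probeMap(fx$design)
  eff <- tt[tt$effect, ]
  lfc_prom <- vapply(eff$promoter_id, function(pid) {
    ids <- map$probe_id[map$promoter_id == pid]
    mean(ps$log2fc[match(ids, ps$probe_id)], na.rm = TRUE)
  }, numeric(1))
  want <- ifelse(eff$direction == "hyper", 1, -1)
  expect_gte(mean(sign(lfc_prom) == want), 0.95)
})

test_that("beta tables respect bounds and injected filter flags", {
  fx <- signalCohort()
  b <- fx$cohort$betas
  expect_true(all(b$beta >= 0 & b$beta <= 1))
  expect_equal(dim(b$beta), c(4000L, 6L))  # 2 CpGs x 2000 promoters, 6 pools
  n_snp <- sum(b$manifest$snp_distance <= 10)
  expect_gt(n_snp, 0)
  flt <- filterProbes450k(b$beta, b$detp, b$manifest)
  ## the SNP filter removes exactly the SNP-proximal CpGs
  expect_equal(unname(flt$report["n_snp"]), n_snp)
  expect_false(any(b$manifest$snp_distance[
    match(rownames(flt$beta), b$manifest$cpg_id)] <= 10))
  expect_error(simulate450kPools(fx$truth,
                                 simConfig(pools_per_group = 1), seed = 1),
               "at least 2 pools")
})

test_that("noise-free pools reproduce the effect size in delta-beta", {
  cfg <- simConfig(n_genes = 80, beta_sd = 0, delta = 0.2,
                   detection_fail_rate = 0, snp_frac = 0)
  truth <- simulateTruth(cfg, seed = 12)
  b <- simulate450kPools(truth, cfg, seed = 13)
  ds <- poolDifferential(b$beta, b$pools$group)
  tt <- truthTable(truth)
  eff_cpg <- b$manifest$promoter_id %in% tt$promoter_id[tt$effect]
  db <- ds$delta_beta[match(b$manifest$cpg_id, ds$cpg_id)]
  ## away from the [0,1] bounds the group difference is exactly +/- delta
  unclipped <- eff_cpg &
    b$manifest$cpg_id %in% rownames(b$beta)[
      apply(b$beta > 0 & b$beta < 1, 1L, all)]
  expect_true(all(abs(abs(db[unclipped]) - 0.2) < 1e-12))
  expect_true(all(abs(db[!eff_cpg]) < 1e-12))
})

test_that("CpG density is linked to effect direction", {
  fx <- signalCohort()
  tt <- truthTable(fx$truth)
  dens <- normalizedCpgDensity(truthSequences(fx$truth),
                               group = ifelse(is.na(tt$direction),
                                              "background", tt$direction))
  tab <- dens$table
  m_hyper <- mean(tab$rho[tab$group == "hyper"], na.rm = TRUE)
  m_hypo <- mean(tab$rho[tab$group == "hypo"], na.rm = TRUE)
  expect_gt(m_hyper, m_hypo)
})

test_that("true group differences decorrelate by twice the cluster scale", {
  edges <- c(0, 50e3, 5e5, 1.5e6, 3e6, 6e6)
  for (sd in 11:13) {
    tt <- truthTable(simulateTruth(simConfig(), seed = sd))
    dm <- ifelse(tt$effect, ifelse(tt$direction == "hyper", 0.3, -0.3), 0)
    dm <- dm + withr::with_seed(sd + 50, stats::rnorm(length(dm), 0, 0.02))
    curve <- spatialCorrelationCurve(dm, tt$chrom, tt$tss,
                                     bin_edges = edges, n_boot = 200,
                                     n_perm = 200, seed = sd)
    b <- curveBins(curve)
    last <- nrow(b)  # the 3-6 Mb bin, beyond twice the 1.5 Mb scale
    inside_null <- is.na(b$r[last]) ||
      (b$ci_hi[last] >= b$null_lo[last] & b$ci_lo[last] <= b$null_hi[last])
    expect_true(inside_null)
    ## short-range structure is present
    expect_gt(b$r[2], b$null_hi[2])
  }
})
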