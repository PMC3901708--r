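# Pooled beta-value arm: probe filters, Welch test on M-values,
# promoter mapping.

toyBeta <- function(beta_rows, detp = NULL, snp = NULL) {
  n <- nrow(beta_rows)
  ids <- sprintf("cg%05d", seq_len(n))
  rownames(beta_rows) <- ids
  colnames(beta_rows) <- c("CPA_P1", "CPA_P2", "CPA_P3",
                           "NPA_P1", "NPA_P2", "NPA_P3")[seq_len(ncol(beta_rows))]
  if (is.null(detp)) detp <- matrix(1e-5, n, ncol(beta_rows),
                                    dimnames = dimnames(beta_rows))
  manifest <- data.frame(cpg_id = ids, chrom = "chr1",
                         pos = 1000 * seq_len(n),
                         snp_distance = if (is.null(snp)) rep(1000, n)
                                        else snp,
                         stringsAsFactors = FALSE)
  list(beta = beta_rows, detp = detp, manifest = manifest)
}

test_that("detection-p and SNP filters drop the right CpGs", {
  b <- toyBeta(matrix(0.5, 5, 6))
  b$detp[c(2, 4), 3] <- 0.01  # fails in one pool -> whole CpG goes
  flt <- filterProbes450k(b$beta, b$detp, b$manifest)
  expect_equal(nrow(flt$beta), 3L)
  expect_equal(unname(flt$report), c(5L, 2L, 0L, 3L))

  ## SNP boundary is inclusive at 10 bp
  b2 <- toyBeta(matrix(0.5, 3, 6), snp = c(10, 11, 500))
  flt2 <- filterProbes450k(b2$beta, b2$detp, b2$manifest)
  expect_equal(rownames(flt2$beta), c("cg00002", "cg00003"))

  ## nothing flagged -> table unchanged
  b3 <- toyBeta(matrix(0.4, 4, 6))
  expect_equal(filterProbes450k(b3$beta, b3$detp, b3$manifest)$beta,
               b3$beta)
  b4 <- toyBeta(matrix(0.5, 2, 6), snp = c(0, 5))
  expect_error(filterProbes450k(b4$beta, b4$detp, b4$manifest),
               "no CpGs left")
})

test_that("the two filters commute", {
  withr::with_seed(81, {
    b <- toyBeta(matrix(runif(60), 10, 6),
                 snp = sample(c(3, 8, 50, 1000), 10, TRUE))
    b$detp[sample(60, 6)] <- 0.02
  })
  joint <- filterProbes450k(b$beta, b$detp, b$manifest)
  ## detection-p first (SNP filter disabled), then SNP
  step1 <- filterProbes450k(b$beta, b$detp, b$manifest, snp_bp = -1)
  m1 <- b$manifest[b$manifest$cpg_id %in% rownames(step1$beta), ]
  ab <- filterProbes450k(step1$beta, step1$detp, m1, detp_max = 2)
  ## SNP first, then detection-p
  step2 <- filterProbes450k(b$beta, b$detp, b$manifest, detp_max = 2)
  m2 <- b$manifest[b$manifest$cpg_id %in% rownames(step2$beta), ]
  ba <- filterProbes450k(step2$beta, step2$detp, m2, snp_bp = -1)
  expect_equal(rownames(ab$beta), rownames(joint$beta))
  expect_equal(rownames(ba$beta), rownames(joint$beta))
})

test_that("pool differential matches a direct Welch evaluation", {
  withr::with_seed(82, m <- matrix(runif(30, 0.2, 0.8), 5, 6))
  b <- toyBeta(m)
  ds <- poolDifferential(b$beta, rep(c("CPA", "NPA"), each = 3))
  for (k in 1:5) {
    M <- log2(m[k, ] / (1 - m[k, ]))
    tt <- stats::t.test(M[1:3], M[4:6])
    expect_equal(ds$t[k], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(ds$df[k], unname(tt$parameter), tolerance = 1e-10)
    expect_equal(ds$p[k], tt$p.value, tolerance = 1e-10)
    expect_equal(ds$delta_beta[k], mean(m[k, 1:3]) - mean(m[k, 4:6]))
  }
  expect_true(all(abs(ds$delta_beta) <= 1))
})

test_that("identical pools give a flagged null result", {
  b <- toyBeta(matrix(rep(c(0.3, 0.6, 0.3, 0.6, 0.3), 6), 5, 6))
  ds <- poolDifferential(b$beta, rep(c("CPA", "NPA"), each = 3))
  expect_true(all(ds$delta_beta == 0))
  expect_true(all(ds$p == 1))
  expect_true(all(ds$zero_variance))
  expect_error(poolDifferential(b$beta[, c(1, 4)], c("CPA", "NPA")),
               "at least 2 pools")
})

test_that("significant CpGs map to promoters through the TSS window", {
  d <- toyDesign(1)  # plus strand, TSS at 100000, window -1000..+200
  tssp <- promoterWindows(d)$tss
  manifest <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                         chrom = "chr1",
                         pos = c(tssp + 100, tssp + 300, tssp - 999),
                         stringsAsFactors = FALSE)
  ds <- data.frame(cpg_id = c("cg1", "cg2", "cg3"),
                   delta_beta = c(0.2, 0.2, -0.1),
                   significant = c(TRUE, TRUE, TRUE),
                   stringsAsFactors = FALSE)
  hits <- mapCpgsToPromoters(ds, manifest, d)
  expect_equal(hits$promoter_id, "P01")
  expect_equal(hits$n_cpgs, 2L)  # TSS+300 falls outside the window
  expect_setequal(strsplit(hits$cpg_ids, ";")[[1]], c("cg1", "cg3"))
  ## nothing significant -> empty hit list
  ds$significant <- FALSE
  expect_equal(nrow(mapCpgsToPromoters(ds, manifest, d)), 0L)
})

test_that("promoter hits cover effect promoters in a clean simulation", {
  cfg <- simConfig(n_genes = 120, beta_sd = 0.005, delta = 0.25,
                   detection_fail_rate = 0, snp_frac = 0)
  truth <- simulateTruth(cfg, seed = 83)
  b <- simulate450kPools(truth, cfg, seed = 84)
  flt <- filterProbes450k(b$beta, b$detp, b$manifest)
  ds <- poolDifferential(flt$beta, b$pools$group)
  hits <- mapCpgsToPromoters(ds, b$manifest, truthDesign(truth))
  tt <- truthTable(truth)
  eff <- tt$promoter_id[tt$effect]
  expect_true(all(eff %in% hits$promoter_id))
  ## delta-beta signs agree with the injected directions
  eff_cpg <- b$manifest$promoter_id %in% eff
  sign_true <- ifelse(tt$direction[match(b$manifest$promoter_id,
                                         tt$promoter_id)] == "hyper",
                      1, -1)[eff_cpg]
  db <- ds$delta_beta[match(b$manifest$cpg_id[eff_cpg], ds$cpg_id)]
  expect_gte(mean(sign(db) == sign_true, na.rm = TRUE), 0.95)
})

test_that("null pools stay near the nominal false-positive rate", {
  for (sd in 86:88) {
    cfg <- simConfig(n_genes = 150, effect_fraction = 0,
                     detection_fail_rate = 0, snp_frac = 0)
    truth <- suppressWarnings(simulateTruth(cfg, seed = sd))
    b <- simulate450kPools(truth, cfg, seed = sd + 10)
    ds <- poolDifferential(b$beta, b$pools$group)
    n <- nrow(ds)
    expect_lte(sum(ds$q < 0.05),
               0.05 * n + 3 * sqrt(n * 0.05 * 0.95))
  }
})
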