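# CpG observed/expected density and the spatial correlation machinery.

test_that("normalized CpG density follows its definition", {
  res <- normalizedCpgDensity("CGCG")
  expect_equal(res$table$rho, (2 / 3) / (0.5 * 0.5))  # 8/3
  ## random sequences against the definitional formula
  withr::with_seed(71, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
      cnt <- countCpg(s)[1, ]
      L <- 40
      want <- if (cnt["c_count"] == 0 || cnt["g_count"] == 0) NA_real_
        else (cnt[["cpg_count"]] / (L - 1)) /
          ((cnt[["c_count"]] / L) * (cnt[["g_count"]] / L))
      expect_equal(normalizedCpgDensity(s)$table$rho, want)
    }
  })
  ## regions without C or G are excluded from the comparison
  res2 <- normalizedCpgDensity(c(a = "CGCGAT", b = "AATTTT", c = "CGCGCG"),
                               group = c("hyper", "hyper", "hypo"))
  expect_true(is.na(res2$table$rho[2]))
})

test_that("density asymmetry is detected between constructed groups", {
  withr::with_seed(72, {
    dense <- vapply(1:30, function(i)
      paste(rep("CGAT", 25), collapse = ""), character(1))
    sparse <- vapply(1:30, function(i)
      paste(sample(c("A", "T", "C", "G"), 100, TRUE,
                   prob = c(.4, .4, .1, .1)), collapse = ""), character(1))
  })
  res <- normalizedCpgDensity(c(dense, sparse),
                              group = rep(c("hyper", "hypo"), each = 30))
  expect_lt(res$test$p, 0.05)
  expect_gt(res$test$median_hyper, res$test$median_hypo)
})

test_that("co-located probes give perfect distance-zero correlation", {
  withr::with_seed(73, {
    pos <- rep(seq(1e5, 5e6, by = 1e5), each = 2)  # duplicated coordinates
    delta <- rep(rnorm(length(pos) / 2), each = 2)
  })
  curve <- spatialCorrelationCurve(delta, rep("c1", length(pos)), pos,
                                   bin_edges = c(0, 10, 2e5, 1e6),
                                   n_boot = 50, n_perm = 50,
                                   min_pairs = 10, seed = 1)
  expect_equal(curveBins(curve)$r[1], 1)
})

test_that("permuted differences stay inside the null band", {
  withr::with_seed(74, {
    pos <- sort(sample(1:3e7, 600))
    delta <- rnorm(600)
  })
  curve <- spatialCorrelationCurve(delta, rep("c1", 600), pos,
                                   bin_edges = c(0, 1e5, 5e5, 1e6, 3e6,
                                                 6e6, 1e7),
                                   n_boot = 100, n_perm = 200, seed = 2)
  b <- curveBins(curve)
  inside <- is.na(b$r) | (b$r >= b$null_lo & b$r <= b$null_hi)
  expect_gte(mean(inside), 0.9)
  ## the permutation band always brackets zero
  expect_true(all(b$null_lo < 0 & b$null_hi > 0, na.rm = TRUE))
})

test_that("block-structured differences correlate below the block scale", {
  withr::with_seed(75, {
    pos <- seq(2.5e4, 3e7, by = 2.5e4)
    block <- pos %/% 5e5
    sgn <- sample(c(-1, 1), max(block) + 1, replace = TRUE)
    delta <- sgn[block + 1] * 0.3 + rnorm(length(pos), 0, 0.1)
  })
  curve <- spatialCorrelationCurve(delta, rep("c1", length(pos)), pos,
                                   bin_edges = c(0, 1e5, 2.5e5, 5e5,
                                                 1.5e6, 3e6),
                                   n_boot = 200, n_perm = 200, seed = 3)
  b <- curveBins(curve)
  ## bins below the 500 kb block scale sit above the null band
  expect_true(all(b$ci_lo[1:2] > b$null_hi[1:2]))
  ## bins beyond 1.5 Mb do not
  expect_false(b$ci_lo[5] > b$null_hi[5])
})

test_that("the curve is deterministic and translation-invariant", {
  withr::with_seed(76, {
    pos <- sort(sample(1:1e7, 300))
    delta <- rnorm(300)
  })
  edges <- c(0, 2e5, 1e6, 5e6)
  args <- list(delta, rep("c1", 300), pos, bin_edges = edges,
               n_boot = 60, n_perm = 60, seed = 4)
  c1 <- do.call(spatialCorrelationCurve, args)
  c2 <- do.call(spatialCorrelationCurve, args)
  expect_identical(curveBins(c1), curveBins(c2))
  args[[3]] <- pos + 123456
  c3 <- do.call(spatialCorrelationCurve, args)
  expect_identical(curveBins(c1), curveBins(c3))
})

test_that("bootstrap interval width shrinks with pair count", {
  withr::with_seed(77, {
    pos_small <- sort(sample(1:5e6, 150))
    pos_big <- sort(sample(1:5e6, 600))
  })
  edges <- c(0, 5e6)
  w <- vapply(list(pos_small, pos_big), function(p) {
    withr::with_seed(78, delta <- rnorm(length(p)))
    b <- curveBins(spatialCorrelationCurve(delta, rep("c1", length(p)), p,
                                           bin_edges = edges, n_boot = 300,
                                           n_perm = 10, pair_cap = 5e5,
                                           seed = 5))
    b$ci_hi[1] - b$ci_lo[1]
  }, numeric(1))
  ## pairs grow ~16x, so the width should drop by roughly 4x
  expect_gt(w[1] / w[2], 2)
})

test_that("degenerate spatial inputs are rejected or reported absent", {
  expect_error(spatialCorrelationCurve(rep(1, 10), rep("c", 10),
                                       1:10 * 1000),
               "constant")
  withr::with_seed(79, {
    pos <- sort(sample(1:1e6, 40))
    delta <- rnorm(40)
  })
  curve <- spatialCorrelationCurve(delta, rep("c1", 40), pos,
                                   bin_edges = c(0, 100, 1e6),
                                   n_boot = 20, n_perm = 20, seed = 6)
  expect_true(is.na(curveBins(curve)$r[1]))  # < 30 pairs at tiny distance
})

test_that("decorrelation length is the leading run of significant bins", {
  mk <- function(r, lo, hi, nlo, nhi) {
    bins <- data.frame(bin_lo = c(0, 1, 2, 3) * 1e6,
                       bin_hi = c(1, 2, 3, 4) * 1e6,
                       n_pairs = 100, r = r, ci_lo = lo, ci_hi = hi,
                       null_lo = nlo, null_hi = nhi)
    methods::new("SpatialCorrCurve", bins = bins,
                 params = list(n_boot = 1, n_perm = 1, pair_cap = 1,
                               min_pairs = 1, seed = 1))
  }
  ## no bin outside the null band -> 0
  flat <- mk(r = c(0, 0, 0, 0), lo = -0.1, hi = 0.1,
             nlo = -0.2, nhi = 0.2)
  expect_equal(decorrelationLength(flat), 0)
  ## significant through bin 2, gap at bin 3 -> upper edge of bin 2
  run <- mk(r = c(0.5, 0.4, 0.05, 0.4),
            lo = c(0.4, 0.3, -0.05, 0.3), hi = c(0.6, 0.5, 0.15, 0.5),
            nlo = rep(-0.1, 4), nhi = rep(0.1, 4))
  expect_equal(decorrelationLength(run), 2e6)
  few <- mk(r = c(0.5, NA, NA, NA), lo = c(0.4, NA, NA, NA),
            hi = c(0.6, NA, NA, NA), nlo = -0.1, nhi = 0.1)
  expect_error(decorrelationLength(few), "at least 3 bins")
})
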