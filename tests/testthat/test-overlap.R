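# Set-overlap enrichment, Fisher exact tests, cohort t-tests, and
# cross-platform concordance.

test_that("hypergeometric overlap p matches hand-computable cases", {
  ## all 5 of A inside B = 5 in a universe of 10: 1 / C(10,5)
  res <- setOverlapTest(5, 5, n_universe = 10, overlap = 5)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  ## no overlap when the expectation is below one: p near 1
  res2 <- setOverlapTest(3, 3, n_universe = 1000, overlap = 0)
  expect_gte(res2$p, 0.3)
  expect_error(setOverlapTest(5, 5, n_universe = 8, overlap = 1),
               "universe smaller")
  ## id-vector interface computes the intersection itself
  res3 <- setOverlapTest(c("a", "b", "c"), c("b", "c", "d"),
                         n_universe = 100)
  expect_equal(res3$n_overlap, 2L)
})

test_that("male and female promoter signatures overlap non-randomly", {
  ## 448- and 430-gene signatures sharing 31 genes among 20,318
  res <- setOverlapTest(448, 430, n_universe = 20318, overlap = 31)
  expect_lt(res$p, 1e-4)
  expect_gt(res$n_overlap, res$expected)  # 31 >> 9.5 expected by chance
})

test_that("hypergeometric tails match a direct summation oracle", {
  withr::with_seed(91, {
    for (i in 1:50) {
      N <- sample(20:1000, 1)
      na <- sample.int(min(N, 200), 1)
      nb <- sample.int(min(N, 200), 1)
      rng <- max(0, na + nb - N):min(na, nb)
      k <- rng[sample.int(length(rng), 1)]
      res <- setOverlapTest(na, nb, n_universe = N, overlap = k)
      direct <- sum(choose(na, k:min(na, nb)) *
                      choose(N - na, nb - (k:min(na, nb)))) / choose(N, nb)
      expect_equal(res$p, direct, tolerance = 1e-12)
    }
  })
})

test_that("overlap test equals one-sided Fisher on the induced 2x2", {
  withr::with_seed(92, {
    for (i in 1:200) {
      N <- sample(20:500, 1)
      na <- sample.int(min(N, 100), 1)
      nb <- sample.int(min(N, 100), 1)
      rng <- max(0, na + nb - N):min(na, nb)
      k <- rng[sample.int(length(rng), 1)]
      res <- setOverlapTest(na, nb, n_universe = N, overlap = k)
      ft <- stats::fisher.test(matrix(c(k, na - k, nb - k,
                                        N - na - nb + k), 2, 2),
                               alternative = "greater")
      expect_equal(res$p, ft$p.value, tolerance = 1e-10)
    }
  })
})

test_that("two-sided Fisher reproduces the cohort table's criminal-record row", {
  ## 5/14 controls vs 1/5 cases with a record
  res <- fisher2x2(matrix(c(5, 9, 1, 4), nrow = 2, byrow = TRUE))
  expect_equal(res$p, 1.000, tolerance = 1e-9)
  expect_false(res$degenerate)
})

test_that("Fisher handles extreme and degenerate tables", {
  res <- fisher2x2(matrix(c(10, 0, 0, 10), 2, 2, byrow = TRUE))
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$odds_ratio, Inf)
  ## an all-zero column is degenerate: p = 1 with a flag
  res2 <- fisher2x2(matrix(c(3, 0, 7, 0), 2, 2, byrow = TRUE))
  expect_equal(res2$p, 1)
  expect_true(res2$degenerate)
  expect_error(fisher2x2(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})

test_that("Fisher p is symmetric under row and column exchange", {
  withr::with_seed(93, {
    for (i in 1:30) {
      m <- matrix(sample(0:15, 4, TRUE), 2, 2)
      p0 <- fisher2x2(m)$p
      expect_equal(fisher2x2(m[2:1, ])$p, p0, tolerance = 1e-12)
      expect_equal(fisher2x2(m[, 2:1])$p, p0, tolerance = 1e-12)
      expect_true(p0 > 0 && p0 <= 1)
    }
  })
})

test_that("two-sample t agrees with t.test and with summary input", {
  withr::with_seed(94, {
    x <- rnorm(5, 1, 1)
    y <- rnorm(14, 0, 1.5)
  })
  for (variant in c("pooled", "welch")) {
    got <- twoSampleT(x, y, variant = variant)
    ref <- stats::t.test(x, y, var.equal = variant == "pooled")
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    ## exact summaries reproduce the raw-vector result
    sm <- twoSampleT(list(mean = mean(x), sd = sd(x), n = 5),
                     list(mean = mean(y), sd = sd(y), n = 14),
                     variant = variant)
    expect_equal(sm$t, got$t, tolerance = 1e-12)
    expect_equal(sm$p, got$p, tolerance = 1e-12)
  }
  eq <- twoSampleT(list(mean = 2, sd = 1, n = 5),
                   list(mean = 2, sd = 3, n = 9), variant = "welch")
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  b <- twoSampleT(list(mean = 1, sd = 0, n = 5),
                  list(mean = 2, sd = 0, n = 5))
  expect_equal(b$p, 0); expect_true(b$boundary)
})

test_that("fold-change concordance behaves on exact and noisy relations", {
  v <- c(a = 1, b = -2, c = 0.5, d = 3)
  expect_equal(foldChangeConcordance(v, v)$r, 1)
  expect_equal(foldChangeConcordance(v, -v)$r, -1)
  expect_error(foldChangeConcordance(v[1:2], v[1:2]), "at least 3")
  expect_error(foldChangeConcordance(v, c(a = 1, b = 1, c = 1, d = 1)),
               "constant")
  ## a noisy slope-one relation over 19 validation regions
  for (sd in 95:97) {
    withr::with_seed(sd, {
      fc <- rnorm(19, 0, 0.5)
      fc2 <- fc + rnorm(19, 0, 0.32)
    })
    names(fc) <- names(fc2) <- sprintf("r%02d", 1:19)
    res <- foldChangeConcordance(fc, fc2)
    expect_gt(res$r, 0.7); expect_lt(res$r, 0.97)
    expect_lt(res$p, 0.001)
  }
})

test_that("common-probe overlap intersects ids and tests enrichment", {
  universe <- sprintf("u%04d", 1:2000)
  withr::with_seed(98, {
    a <- sample(universe, 60)
    b <- c(sample(a, 30), sample(setdiff(universe, a), 30))
  })
  res <- commonProbeOverlap(a, b, universe)
  expect_setequal(res$shared, intersect(a, b))
  expect_lt(res$overlap$p, 0.01)
  ## identical call sets: overlap is the whole set
  res2 <- commonProbeOverlap(a, a, universe)
  expect_equal(res2$overlap$n_overlap, 60L)
  expect_error(commonProbeOverlap(a, c("x1", "x2"), universe),
               "universe")
})
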