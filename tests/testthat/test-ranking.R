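test_that("tie handling follows the min-rank and average conventions", {
  expect_equal(rankWithTies(c(0.9, 0.7, 0.9)), c(1, 3, 1))
  expect_equal(rankWithTies(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_equal(rankWithTies(c(0.9, 0.7, 0.9), tie = "average"),
               c(1.5, 3, 1.5))
  expect_equal(rankWithTies(c(1, 3, 2), largeBetter = FALSE), c(1, 3, 2))
  expect_error(rankWithTies(numeric(0)), "empty")
  expect_error(rankWithTies(c(1, NA)), "finite")
})

test_that("min-tie layout invariant holds for all methods on random data", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:12, 1)
    p <- sample(2:6, 1)
    # duplicate-heavy values to force ties
    s <- matrix(sample(seq(0, 1, by = 0.25), n * p, replace = TRUE), n, p,
                dimnames = list(paste0("c", 1:n), paste0("A", 1:p)))
    for (m in list(rankingMethod("meanThenRank"),
                   rankingMethod("medianThenRank"),
                   rankingMethod("quantileThenRank", q = 0.25),
                   rankingMethod("rankThenMean"),
                   rankingMethod("rankThenMedian"),
                   rankingMethod("testBased"))) {
      r <- ranks(applyRanking(s, m))
      tab <- table(r)
      expected <- cumsum(c(1, head(as.integer(tab), -1)))
      expect_equal(as.numeric(names(tab)), expected,
                   info = paste("method", m$name, "seed", seed))
    }
  }
})

test_that("aggregate-then-rank orders aggregates in the favorable direction", {
  s <- makeSlice(A = c(0.9, 0.8), B = c(0.7, 0.6))
  r <- aggregateThenRank(s, "mean")
  expect_equal(unname(r@values), c(0.85, 0.65))
  expect_equal(ranks(r), c(A = 1, B = 2))

  # mid-point median convention ties both at 0.5
  s2 <- makeSlice(A = c(1, 0), B = c(0.6, 0.4))
  r2 <- aggregateThenRank(s2, "median")
  expect_equal(unname(r2@values), c(0.5, 0.5))
  expect_equal(ranks(r2), c(A = 1, B = 1))

  # disjoint strata force 1..5 on any draw
  expect_equal(ranks(aggregateThenRank(idealSlice(50, 42), "mean")),
               c(A1 = 1, A2 = 2, A3 = 3, A4 = 4, A5 = 5))
})

test_that("rank-then-aggregate averages per-case ranks before re-ranking", {
  sAB <- makeSlice(A = c(0.9, 0.8), B = c(0.5, 0.4))
  expect_equal(ranks(rankThenAggregate(sAB, "mean")), c(A = 1, B = 2))

  # split decisions -> both mean rank 1.5 -> shared rank 1
  sTie <- makeSlice(A = c(0.9, 0.1), B = c(0.5, 0.4))
  r <- rankThenAggregate(sTie, "mean")
  expect_equal(unname(r@values), c(1.5, 1.5))
  expect_equal(ranks(r), c(A = 1, B = 1))

  # total separation: agrees with aggregate-then-rank
  s3 <- makeSlice(A = c(0.9, 0.95), B = c(0.5, 0.55), C = c(0.1, 0.15))
  expect_equal(ranks(rankThenAggregate(s3, "mean")),
               ranks(aggregateThenRank(s3, "mean")))
})

test_that("test-based ranking counts significant superiorities", {
  # complete separation, n = 10: exact one-sided p = 2^-10 survives Holm
  set.seed(1)
  s <- makeSlice(A = runif(10, 0.8, 0.9), B = runif(10, 0.5, 0.6),
                 C = runif(10, 0.1, 0.2))
  r <- testThenRank(s, alpha = 0.05)
  expect_equal(unname(r@values), c(2, 1, 0))
  expect_equal(ranks(r), c(A = 1, B = 2, C = 3))

  # identical data: all scores 0, everyone rank 1
  sEq <- makeSlice(A = c(0.5, 0.6, 0.7), B = c(0.5, 0.6, 0.7),
                   C = c(0.5, 0.6, 0.7))
  expect_equal(ranks(testThenRank(sEq)), c(A = 1, B = 1, C = 1))

  # n = 3, A always better: p = 0.125 > 0.05 -> no significances
  s3 <- makeSlice(A = c(0.9, 0.8, 0.7), B = c(0.5, 0.4, 0.3))
  expect_equal(ranks(testThenRank(s3)), c(A = 1, B = 1))

  expect_error(testThenRank(makeSlice(A = 0.5, B = 0.4)), "2 test cases")
})

test_that("label permutation permutes every ranking equivariantly", {
  set.seed(9)
  s <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("c", 1:8), paste0("A", 1:5)))
  perm <- sample(5)
  sPerm <- s[, perm]
  for (m in list(rankingMethod("meanThenRank"), rankingMethod("rankThenMean"),
                 rankingMethod("testBased"))) {
    r <- ranks(applyRanking(s, m))
    rPerm <- ranks(applyRanking(sPerm, m))
    expect_equal(rPerm, r[colnames(sPerm)])
  }
})

test_that("all methods agree on fully separated data", {
  s <- idealSlice(30, 11)
  expected <- setNames(1:5, paste0("A", 1:5))
  for (m in list(rankingMethod("meanThenRank"),
                 rankingMethod("medianThenRank"),
                 rankingMethod("rankThenMean"), rankingMethod("testBased")))
    expect_equal(ranks(applyRanking(s, m)), expected)
})

test_that("smaller-is-better metrics rank in the opposite direction", {
  s <- makeSlice(A = c(2, 3), B = c(5, 6))
  expect_equal(ranks(aggregateThenRank(s, "mean", largeBetter = FALSE)),
               c(A = 1, B = 2))
  expect_equal(ranks(rankThenAggregate(s, "mean", largeBetter = FALSE)),
               c(A = 1, B = 2))
})
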