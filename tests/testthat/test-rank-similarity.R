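test_that("Kendall's tau reproduces the textbook identities", {
  expect_identical(kendallsTau(1:5, 1:5), 1)
  expect_identical(kendallsTau(1:5, 5:1), -1)
  expect_equal(kendallsTau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  # symmetry and relabeling invariance
  r1 <- c(A = 1, B = 3, C = 2, D = 4)
  r2 <- c(B = 1, A = 2, D = 3, C = 4)
  expect_equal(kendallsTau(r1, r2), kendallsTau(r2, r1))
  expect_warning(tau <- kendallsTau(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_true(is.na(tau))
  expect_error(kendallsTau(c(A = 1, B = 2), c(A = 1, C = 2)),
               "same algorithm set")
})

test_that("tau-b agrees with the reference implementation under ties", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:10, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(kendallsTau(x, y), cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("footrule and Spearman distance match hand computations", {
  expect_equal(spearmanFootrule(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(spearmanFootrule(c(1, 2), c(2, 1)), 2)
  expect_equal(spearmanFootrule(c(1, 2, 3), c(3, 2, 1)), 4)
  expect_equal(spearmanDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(spearmanDistance(c(1, 2), c(2, 1)), 2)
  expect_equal(spearmanDistance(c(1, 2, 3), c(3, 2, 1)), 8)
})

test_that("footrule satisfies distance axioms on tie-free rank vectors", {
  set.seed(3)
  for (i in 1:30) {
    p <- sample(3:6, 1)
    a <- sample(p); b <- sample(p); c <- sample(p)
    expect_equal(spearmanFootrule(a, b), spearmanFootrule(b, a))
    expect_equal(spearmanFootrule(a, a), 0)
    expect_true(spearmanFootrule(a, c) <=
                  spearmanFootrule(a, b) + spearmanFootrule(b, c))
    expect_equal(spearmanDistance(a, b), spearmanDistance(b, a))
  }
})

test_that("mean-rank consensus averages average-tie ranks then min-ranks", {
  cc <- consensusRank(rbind(T1 = c(A = 1, B = 2, C = 3),
                            T2 = c(A = 1, B = 3, C = 2)))
  expect_equal(cc@meanRanks, c(A = 1, B = 2.5, C = 2.5))
  expect_equal(ranks(cc), c(A = 1, B = 2, C = 2))

  # min-tie input is converted to average-tie inside each task
  cc2 <- consensusRank(rbind(T1 = c(A = 1, B = 1, C = 3)))
  expect_equal(cc2@rankMatrix[1, ], c(A = 1.5, B = 1.5, C = 3))

  # single task: consensus = that task's (re-ranked) ranking
  cc3 <- consensusRank(rbind(T1 = c(A = 2, B = 1, C = 3)))
  expect_equal(ranks(cc3), c(A = 2, B = 1, C = 3))

  expect_error(consensusRank(list(c(A = 1, B = 2), c(A = 1, C = 2))),
               "asymmetric")
})

test_that("distance-minimizing consensus matches brute-force enumeration", {
  cd <- consensusRank(rbind(c(A = 1, B = 2, C = 3), c(A = 1, B = 3, C = 2)),
                      method = "distance", distance = "spearman")
  # minimizer set {(1,2,3),(1,3,2)}; lexicographically smallest reported
  expect_equal(ranks(cd), c(A = 1, B = 2, C = 3))

  # independent check: enumerate all 6 permutations by hand
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  obj <- sapply(perms, function(pm)
    spearmanDistance(pm, c(1, 2, 3)) + spearmanDistance(pm, c(1, 3, 2)))
  expect_equal(min(obj), 2)
  expect_equal(which(obj == 2), c(1L, 2L))
})

test_that("consensus accepts Ranking objects and weights tasks equally", {
  s1 <- makeSlice(A = c(0.9, 0.8), B = c(0.5, 0.4))           # 2 cases
  s2 <- makeSlice(A = rep(0.1, 9), B = rep(0.9, 9))           # 9 cases
  r1 <- aggregateThenRank(s1, "mean", task = "T1")
  r2 <- aggregateThenRank(s2, "mean", task = "T2")
  cc <- consensusRank(list(r1, r2))
  # opposite winners with very different n still balance exactly
  expect_equal(cc@meanRanks, c(A = 1.5, B = 1.5))
  expect_equal(ranks(cc), c(A = 1, B = 1))
  expect_equal(challengeTasks(cc), c("T1", "T2"))
})
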