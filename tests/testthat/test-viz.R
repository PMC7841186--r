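test_that("podium placements are per-case permutations with correct frequencies", {
  # top stratum occupies place 1 in every case
  pd <- podiumData(idealSlice(20, 2), seed = 3)
  expect_true(all(pd$places[, "A1"] == 1))
  expect_equal(unname(pd$frequencies["A1", "1"]), 1)
  expect_equal(unname(rowSums(pd$frequencies)), rep(1, 5))
  expect_true(all(apply(pd$places, 1, sort) == 1:5))

  # tied pair on a single case: random but valid permutation, reproducible
  sTie <- makeSlice(A = 0.5, B = 0.5)
  p1 <- podiumData(sTie, seed = 11)
  expect_setequal(as.numeric(p1$places), c(1, 2))
  expect_identical(podiumData(sTie, seed = 11)$places, p1$places)

  # 2 algorithms, A better on 30 of 40 cases -> place-1 frequency 0.75
  s <- makeSlice(A = c(rep(0.9, 30), rep(0.1, 10)),
                 B = c(rep(0.5, 30), rep(0.6, 10)))
  expect_equal(unname(podiumData(s, seed = 1)$frequencies["A", "1"]), 0.75)
})

test_that("heatmap counts tally per-case min-tie ranks with full columns", {
  hc <- heatmapCounts(idealSlice(50, 4))
  expect_equal(unname(diag(hc)), rep(50L, 5))
  expect_equal(unname(colSums(hc)), rep(50L, 5))

  # single case: one nonzero cell per column
  s1 <- makeSlice(A = 0.9, B = 0.5, C = 0.7)
  h1 <- heatmapCounts(s1)
  expect_true(all(colSums(h1 > 0) == 1))

  # full tie on all cases: both columns count rank 1
  sTie <- makeSlice(A = rep(0.5, 10), B = rep(0.5, 10))
  hTie <- heatmapCounts(sTie)
  expect_equal(unname(hTie["1", ]), c(A = 10L, B = 10L), ignore_attr = TRUE)
  expect_equal(unname(hTie["2", ]), c(0L, 0L), ignore_attr = TRUE)
})

test_that("line plot data reports one full ranking per method", {
  lp <- linePlotData(idealSlice(20, 6))
  byMethod <- split(lp$rank[order(lp$algorithm)], lp$method[order(lp$algorithm)])
  for (m in byMethod) expect_equal(m, 1:5, ignore_attr = TRUE)

  # constructed mean/median disagreement (one large outlier) -> crossing
  s <- makeSlice(A = c(0.6, 0.6, 0.6), B = c(0.5, 0.5, 1.0))
  lp2 <- linePlotData(s, methods = list(rankingMethod("meanThenRank"),
                                        rankingMethod("medianThenRank")))
  rA <- lp2$rank[lp2$algorithm == "A"]
  expect_false(all(rA == rA[1]))  # A's rank changes between methods

  lp3 <- linePlotData(s, methods = list(rankingMethod("meanThenRank")))
  expect_equal(nrow(lp3), 2)
})

test_that("blob data frequencies sum to the group size", {
  bd <- blobData(list(A = c(1, 1, 2, 2), B = rep(1, 4)))
  expect_equal(sum(bd$frequencies$count[bd$frequencies$group == "A"]), 4)
  a <- bd$frequencies[bd$frequencies$group == "A", ]
  expect_equal(a$freq, c(0.5, 0.5))
  expect_equal(bd$summary$median[bd$summary$group == "A"], 1.5)
  expect_equal(bd$summary[bd$summary$group == "B", c("lower", "upper")],
               data.frame(lower = 1, upper = 1, row.names = 2L))
  expect_error(blobData(list(A = numeric(0))), "empty")
})

test_that("dendrogram merges identical rankings at height zero", {
  dd <- dendrogramData(rbind(T1 = c(1, 2, 3), T2 = c(1, 2, 3),
                             T3 = c(3, 2, 1)))
  expect_equal(sort(dd$tree$height), c(0, 4))  # footrule((1,2,3),(3,2,1)) = 4
  dd2 <- dendrogramData(rbind(T1 = c(1, 2, 3), T2 = c(1, 2, 3),
                              T3 = c(1, 2, 3)))
  expect_equal(dd2$tree$height, c(0, 0))
  expect_error(dendrogramData(rbind(T1 = c(1, 2, 3))), "2 tasks")
})

test_that("network edges grow exponentially with distance; tied winners uncolored", {
  nd <- networkData(rbind(T1 = c(A = 1, B = 2, C = 3),
                          T2 = c(A = 1, B = 2, C = 3)), growthRate = 0.05)
  expect_equal(nd$edges$length, 1)
  nd2 <- networkData(rbind(T1 = c(A = 1, B = 2, C = 3),
                           T2 = c(A = 3, B = 2, C = 1)), growthRate = 0.05)
  expect_equal(nd2$edges$distance, 4)
  expect_equal(nd2$edges$length, exp(0.2))
  expect_equal(nd2$nodes$winner, c("A", "C"))
  ndTie <- networkData(rbind(T1 = c(A = 1, B = 1, C = 3),
                             T2 = c(A = 1, B = 2, C = 3)))
  expect_true(is.na(ndTie$nodes$winner[1]))
})

test_that("rendering writes image files and rejects invalid requests", {
  out <- withr::local_tempdir()
  s <- idealSlice(15, 8)
  br <- bootstrapRankings(s, b = 30, seed = 2)
  sm <- significanceMatrix(s)
  files <- c(
    renderFigure("dotbox", s, file.path(out, "a.png"), seed = 1),
    renderFigure("podium", podiumData(s, seed = 1), file.path(out, "b.png")),
    renderFigure("heatmap", heatmapCounts(s), file.path(out, "c.png")),
    renderFigure("line", linePlotData(s), file.path(out, "d.png")),
    renderFigure("blob", br, file.path(out, "e.png")),
    renderFigure("violin", br@tauDist, file.path(out, "f.png")),
    renderFigure("significance_map", sm, file.path(out, "g.png")),
    renderFigure("dendrogram",
                 dendrogramData(rbind(T1 = 1:3, T2 = c(2, 1, 3))),
                 file.path(out, "h.png")),
    renderFigure("network",
                 networkData(rbind(T1 = c(A = 1, B = 2, C = 3),
                                   T2 = c(A = 2, B = 1, C = 3))),
                 file.path(out, "i.svg")))
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))

  expect_error(renderFigure("nope", s, file.path(out, "x.png")),
               "unknown figure kind")
  # podium refuses unreadable algorithm counts and points at truncation
  big <- matrix(runif(5 * 31), 5, 31,
                dimnames = list(paste0("c", 1:5), paste0("A", 1:31)))
  expect_error(renderFigure("podium", podiumData(big, seed = 1),
                            file.path(out, "y.png")),
               "top list|truncate")
})
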