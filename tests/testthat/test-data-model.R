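test_that("CSV ingestion parses single- and multi-task layouts", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(task = "T1", algorithm = rep(c("A", "B"), each = 2),
                       case = rep(c("c1", "c2"), 2),
                       value = c(0.9, 0.8, 0.7, 0.6)),
            f, row.names = FALSE)
  d <- loadChallenge(f)
  expect_s4_class(d, "ChallengeData")
  expect_equal(nrow(d@records), 4L)
  expect_equal(challengeTasks(d), "T1")
  expect_setequal(algorithms(d), c("A", "B"))

  # no task column + map omitting task -> implicit task T1
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(algorithm = c("A", "B"), case = "c1",
                       value = c(0.5, 0.4)), f2, row.names = FALSE)
  d2 <- loadChallenge(f2, columnMap = c(algorithm = "algorithm",
                                        case = "case", value = "value"))
  expect_equal(challengeTasks(d2), "T1")

  # custom column names
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(tk = "S", alg = c("A", "B"), id = "c1",
                       dsc = c(0.5, 0.4)), f3, row.names = FALSE)
  d3 <- loadChallenge(f3, columnMap = c(task = "tk", algorithm = "alg",
                                        case = "id", value = "dsc"))
  expect_equal(challengeTasks(d3), "S")
})

test_that("ingestion errors name the offending duplicate or row", {
  dup <- data.frame(task = "T1", algorithm = c("A", "A"), case = c("c1", "c1"),
                    value = c(0.1, 0.2))
  expect_error(challengeData(dup), "task=T1, algorithm=A, case=c1")

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("task,algorithm,case,value",
               "T1,A,c1,0.5", "T1,A,c2,abc"), f)
  expect_error(loadChallenge(f), "unparseable.*row 2")
})

test_that("imputation fills missing cells with the unfavorable value", {
  # algorithm B misses 3 of 10 cases -> 3 cells set to 0
  rec <- rbind(
    data.frame(task = "T1", algorithm = "A", case = paste0("c", 1:10),
               value = seq(0.1, 1, by = 0.1)),
    data.frame(task = "T1", algorithm = "B", case = paste0("c", 1:7),
               value = rep(0.5, 7)))
  d <- imputeMissing(challengeData(rec), worstValue = 0)
  expect_equal(d@imputed, 3L)
  s <- taskSlice(d)
  expect_equal(sum(s[, "B"] == 0), 3)
  expect_false(anyNA(s))

  # complete data is untouched
  comp <- challengeData(randomRecords())
  expect_equal(imputeMissing(comp)@imputed, 0L)
  expect_equal(imputeMissing(comp)@records$value, comp@records$value)

  # all values of one algorithm missing -> all its cells the worst value,
  # hence its mean aggregate equals the worst value
  rec2 <- rbind(
    data.frame(task = "T1", algorithm = "A", case = paste0("c", 1:4),
               value = c(0.9, 0.8, 0.7, 0.6)),
    data.frame(task = "T1", algorithm = "B", case = paste0("c", 1:4),
               value = NA_real_))
  d2 <- imputeMissing(challengeData(rec2), worstValue = 0)
  s2 <- taskSlice(d2)
  expect_equal(unname(colMeans(s2)["B"]), 0)
})

test_that("imputation is idempotent and yields complete task slices", {
  spec <- generatorSpec(n = 12, p = 4, distribution = "random",
                        missingRate = 0.2, seed = 5)
  raw <- generateCustom(spec, tasks = 3)
  once <- imputeMissing(raw)
  twice <- imputeMissing(once)
  expect_equal(twice@records[order(twice@records$task,
                                   twice@records$algorithm,
                                   twice@records$case), ],
               once@records[order(once@records$task, once@records$algorithm,
                                  once@records$case), ],
               ignore_attr = TRUE)
  for (tk in challengeTasks(once)) {
    s <- taskSlice(once, tk)
    expect_false(anyNA(s))
    expect_equal(ncol(s), 4)
  }
})

test_that("direction-aware default worst value and exclusion flagging", {
  rec <- rbind(
    data.frame(task = "T1", algorithm = "A", case = c("c1", "c2"),
               value = c(2, 4)),
    data.frame(task = "T1", algorithm = "B", case = "c1", value = 3),
    data.frame(task = "T2", algorithm = "A", case = "c1", value = 1))
  d <- challengeData(rec, smallBetter = TRUE)
  # B absent from all of T2: excluded there, not fabricated
  expect_equal(d@excluded$task, "T2")
  expect_equal(d@excluded$algorithm, "B")
  imp <- imputeMissing(d)
  s <- taskSlice(imp, "T1")
  # smaller-better default worst value = per-task max (4)
  expect_equal(s["c2", "B"], 4)
  expect_equal(colnames(taskSlice(imp, "T2")), "A")
  rep <- validationReport(imp)
  expect_true(any(grepl("excluded", rep)))
  expect_true(any(grepl("caution", rep)))  # < 20 cases
})
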