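#' Bootstrap the ranking of one task
#'
#' Draws `b` bootstrap samples of the task (n test cases drawn with
#' replacement from its n cases; a case drawn twice contributes twice to
#' aggregates and tests), re-runs the full ranking procedure on every sample
#' and summarizes the resulting rank distributions: the rank-frequency matrix
#' behind blob plots, per-algorithm median ranks and percentile intervals, and
#' the distribution of Kendall's tau between each replicate ranking and the
#' full-data ranking (the violin-plot input). Replicates on which the ranking
#' degenerates to all-ties are kept with the method's tie output; their tau to
#' the full ranking may be undefined and is stored as `NA`.
#'
#' @inheritParams applyRanking
#' @param b number of bootstrap replicates (the conventional default is 1000).
#' @param seed integer seed; fully determines the resamples.
#' @param level coverage of the percentile interval, in percent.
#' @return A [BootstrapResult-class] object.
#' @export
bootstrapRankings <- function(slice, method = rankingMethod("meanThenRank"),
                              b = 1000L, seed = 1L, largeBetter = TRUE,
                              task = "T1", level = 95) {
  slice <- checkSlice(slice)
  stopifnot(b >= 1L, level > 0, level < 100)
  n <- nrow(slice)
  p <- ncol(slice)
  full <- applyRanking(slice, method, largeBetter = largeBetter, task = task)
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, nrow = b, ncol = p,
                 dimnames = list(NULL, colnames(slice)))
  for (i in seq_len(b)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[i, ] <- ranks(applyRanking(slice[idx, , drop = FALSE], method,
                                    largeBetter = largeBetter, task = task))
  }
  freq <- rankFrequency(reps, p)
  med <- apply(reps, 2L, stats::median)
  ints <- t(apply(reps, 2L, bootstrapInterval, level = level))
  colnames(ints) <- c("lower", "upper")
  tau <- tauVector(reps, ranks(full))
  new("BootstrapResult", task = task, method = full@method, b = as.integer(b),
      seed = as.integer(seed), replicates = reps, rankFrequency = freq,
      medianRank = med, intervals = ints, level = level, tauDist = tau,
      fullRanking = full, nCases = as.integer(n), caution = n < 20)
}

rankFrequency <- function(reps, p) {
  algs <- colnames(reps)
  freq <- matrix(0L, nrow = ncol(reps), ncol = p,
                 dimnames = list(algs, as.character(seq_len(p))))
  for (j in seq_len(ncol(reps))) {
    tab <- table(factor(reps[, j], levels = seq_len(p)))
    freq[j, ] <- as.integer(tab)
  }
  freq
}

tauVector <- function(reps, fullRanks) {
  if (ncol(reps) < 2L) return(rep(NA_real_, nrow(reps)))  # tau undefined
  apply(reps, 1L, function(r)
    suppressWarnings(kendallsTau(stats::setNames(r, colnames(reps)),
                                 fullRanks)))
}

#' Percentile bootstrap interval of a rank distribution
#'
#' Empirical percentiles at (100 - level)/2 and 100 - (100 - level)/2, with
#' linear interpolation between order statistics (quantile type 7). The
#' default level 95 yields the 2.5th-97.5th percentile interval.
#'
#' @param rankSamples non-empty numeric vector of ranks.
#' @param level coverage in percent, 0 < level < 100.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' bootstrapInterval(c(1, 1, 1, 2), level = 50)  # 1 1.25
#' @export
bootstrapInterval <- function(rankSamples, level = 95) {
  stopifnot(length(rankSamples) >= 1L, level > 0, level < 100)
  a <- (100 - level) / 200
  unname(stats::quantile(rankSamples, probs = c(a, 1 - a), type = 7))
}

#' Kendall's tau of each bootstrap replicate to a reference ranking
#'
#' Recomputes, replicate by replicate, the tau between the stored bootstrap
#' rankings and a reference (usually full-data) ranking. Replicates whose tau
#' is undefined (completely tied ranking on either side) yield `NA`; they are
#' excluded from violin plots and their count is reported by the report
#' driver.
#'
#' @param result a [BootstrapResult-class] object.
#' @param fullRanking reference [Ranking-class] or named rank vector; defaults
#'   to the full-data ranking stored in `result`.
#' @return Numeric vector of length b, in replicate order.
#' @export
tauToFull <- function(result, fullRanking = NULL) {
  stopifnot(is(result, "BootstrapResult"))
  ref <- if (is.null(fullRanking)) ranks(result@fullRanking)
         else if (is(fullRanking, "Ranking")) ranks(fullRanking)
         else fullRanking
  tauVector(result@replicates, ref)
}

#' Export bootstrap results to CSV
#'
#' Writes the replicate-level rankings (replicate, algorithm, rank) and the
#' summary (algorithm, median, lower, upper) as two CSV files.
#'
#' @param x a [BootstrapResult-class] object.
#' @param replicatePath,summaryPath output CSV paths.
#' @return The two paths, invisibly.
#' @export
writeBootstrap <- function(x, replicatePath, summaryPath) {
  stopifnot(is(x, "BootstrapResult"))
  reps <- data.frame(
    replicate = rep(seq_len(x@b), times = ncol(x@replicates)),
    algorithm = rep(colnames(x@replicates), each = x@b),
    rank = as.vector(x@replicates))
  utils::write.csv(reps, replicatePath, row.names = FALSE)
  utils::write.csv(data.frame(algorithm = names(x@medianRank),
                              median = unname(x@medianRank),
                              lower = x@intervals[, "lower"],
                              upper = x@intervals[, "upper"]),
                   summaryPath, row.names = FALSE)
  invisible(c(replicatePath, summaryPath))
}
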