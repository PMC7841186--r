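#' Podium plot data
#'
#' For every test case the algorithms are assigned to podium places 1..p by
#' their within-case rank; ties are broken randomly under the given seed so
#' that each case's assignment is a unique permutation of the algorithms. The
#' per-algorithm relative frequency of achieving each podium place feeds the
#' bar-chart part of the podium plot.
#'
#' @inheritParams applyRanking
#' @param seed seed for the random tie-break (logged in the result).
#' @return A list of class `podiumData` with elements `places` (cases x
#'   algorithms matrix of podium places, each row a permutation of 1..p),
#'   `values` (the metric values), `frequencies` (algorithms x places matrix
#'   of relative frequencies, rows summing to 1) and `seed`.
#' @export
podiumData <- function(slice, largeBetter = TRUE, seed = 1L) {
  slice <- checkSlice(slice)
  p <- ncol(slice)
  set.seed(as.integer(seed))
  key <- if (largeBetter) -slice else slice
  places <- t(apply(key, 1L, rank, ties.method = "random"))
  if (p == 1L) places <- matrix(places, ncol = 1L)
  dimnames(places) <- dimnames(slice)
  freq <- matrix(0, nrow = p, ncol = p,
                 dimnames = list(colnames(slice), as.character(seq_len(p))))
  for (j in seq_len(p)) {
    tab <- table(factor(places[, j], levels = seq_len(p)))
    freq[j, ] <- as.numeric(tab) / nrow(slice)
  }
  structure(list(places = places, values = slice, frequencies = freq,
                 seed = as.integer(seed)),
            class = "podiumData")
}

#' Ranking heatmap counts
#'
#' Tallies the within-case min-tie ranks ("rank first") into a ranks x
#' algorithms matrix of absolute frequencies: cell (i, Aj) counts the test
#' cases in which algorithm Aj achieved rank i. Tied cases contribute to the
#' shared minimum rank's cell. Every column sums to the task's case count.
#'
#' @inheritParams applyRanking
#' @return Integer matrix, rows = ranks 1..p, columns = algorithms.
#' @export
heatmapCounts <- function(slice, largeBetter = TRUE) {
  slice <- checkSlice(slice)
  p <- ncol(slice)
  perCase <- perCaseRanks(slice, largeBetter)
  counts <- matrix(0L, nrow = p, ncol = p,
                   dimnames = list(as.character(seq_len(p)),
                                   colnames(slice)))
  for (j in seq_len(p)) {
    tab <- table(factor(perCase[, j], levels = seq_len(p)))
    counts[, j] <- as.integer(tab)
  }
  counts
}

#' Line plot data: ranks across ranking methods
#'
#' Applies every requested ranking method to the task and tabulates the rank
#' of each algorithm under each method; parallel lines across methods
#' indicate robustness of the ranking to the method choice, crossing lines
#' sensitivity.
#'
#' @inheritParams applyRanking
#' @param methods list of [rankingMethod()] specifications.
#' @return data.frame with columns `method`, `algorithm`, `rank`.
#' @export
linePlotData <- function(slice, methods = list(rankingMethod("meanThenRank"),
                                               rankingMethod("medianThenRank"),
                                               rankingMethod("rankThenMean"),
                                               rankingMethod("testBased")),
                         largeBetter = TRUE) {
  slice <- checkSlice(slice)
  stopifnot(length(methods) >= 1L)
  rows <- lapply(methods, function(m) {
    rk <- applyRanking(slice, m, largeBetter = largeBetter)
    data.frame(method = rk@method, algorithm = names(ranks(rk)),
               rank = unname(ranks(rk)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$method <- factor(out$method, levels = unique(out$method))
  out
}

#' Blob plot data
#'
#' Summarizes groups of rank samples (one group per algorithm for bootstrap
#' blob plots, per algorithm-across-tasks for cross-task blob plots, per
#' task x algorithm for the stratified variants) into the quantities a blob
#' plot encodes: the frequency of each achieved rank (blob areas), the median
#' rank (black cross) and a percentile interval (black line).
#'
#' @param rankSamples named list mapping each group to its numeric rank
#'   samples.
#' @param level coverage of the percentile interval, in percent.
#' @return A list with `frequencies` (data.frame group, rank, count, freq) and
#'   `summary` (data.frame group, median, lower, upper, size). Counts within a
#'   group sum to the group's sample size.
#' @export
blobData <- function(rankSamples, level = 95) {
  stopifnot(is.list(rankSamples), length(rankSamples) >= 1L)
  if (is.null(names(rankSamples)))
    names(rankSamples) <- paste0("G", seq_along(rankSamples))
  if (any(lengths(rankSamples) == 0L)) stop("empty group")
  freqRows <- lapply(names(rankSamples), function(g) {
    tab <- table(rankSamples[[g]])
    data.frame(group = g, rank = as.numeric(names(tab)),
               count = as.integer(tab),
               freq = as.integer(tab) / length(rankSamples[[g]]),
               stringsAsFactors = FALSE)
  })
  sumRows <- lapply(names(rankSamples), function(g) {
    s <- rankSamples[[g]]
    ci <- bootstrapInterval(s, level = level)
    data.frame(group = g, median = stats::median(s),
               lower = ci[1L], upper = ci[2L], size = length(s),
               stringsAsFactors = FALSE)
  })
  list(frequencies = do.call(rbind, freqRows),
       summary = do.call(rbind, sumRows))
}

# tasks x algorithms rank matrix -> distance matrix over tasks
taskDistances <- function(rankMat, distance = c("footrule", "spearman",
                                                "tau")) {
  distance <- match.arg(distance)
  m <- nrow(rankMat)
  d <- matrix(0, m, m, dimnames = list(rownames(rankMat), rownames(rankMat)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i >= j) next
    d[i, j] <- d[j, i] <- switch(distance,
      footrule = spearmanFootrule(rankMat[i, ], rankMat[j, ]),
      spearman = spearmanDistance(rankMat[i, ], rankMat[j, ]),
      tau = {
        tv <- suppressWarnings(kendallsTau(rankMat[i, ], rankMat[j, ]))
        if (is.na(tv)) 1 else 1 - tv
      })
  }
  d
}

#' Hierarchical clustering of tasks by ranking similarity
#'
#' Computes the pairwise distance matrix between the tasks' algorithm
#' rankings (Spearman's footrule by default, Spearman's distance, or
#' 1 - Kendall's tau) and clusters the tasks hierarchically with complete
#' agglomeration.
#'
#' @param perTask per-task rankings as accepted by [consensusRank()].
#' @param distance `"footrule"`, `"spearman"` or `"tau"`.
#' @param agglomeration linkage passed to [stats::hclust()] (default
#'   `"complete"`).
#' @return A list with `distances` (symmetric matrix) and `tree`
#'   ([stats::hclust] merge tree).
#' @export
dendrogramData <- function(perTask, distance = c("footrule", "spearman",
                                                 "tau"),
                           agglomeration = "complete") {
  rankMat <- asRankMatrix(perTask)
  if (nrow(rankMat) < 2L) stop("need at least 2 tasks")
  d <- taskDistances(rankMat, distance)
  tree <- stats::hclust(stats::as.dist(d), method = agglomeration)
  list(distances = d, tree = tree)
}

#' Network graph of task similarity
#'
#' Builds the complete weighted graph over tasks in which the target length
#' of the edge between two tasks grows exponentially in their ranking
#' distance, `exp(growthRate * distance)`, accentuating large distances.
#' Nodes are colored by the task's unique winning algorithm; tasks with more
#' than one first-ranked algorithm remain uncolored (`NA` winner).
#'
#' @inheritParams dendrogramData
#' @param growthRate exponential growth rate of the edge length in the
#'   distance (default 0.05).
#' @return A list with `nodes` (data.frame task, winner) and `edges`
#'   (data.frame from, to, distance, length).
#' @export
networkData <- function(perTask, distance = c("footrule", "spearman", "tau"),
                        growthRate = 0.05) {
  rankMat <- asRankMatrix(perTask)
  if (nrow(rankMat) < 2L) stop("need at least 2 tasks")
  d <- taskDistances(rankMat, distance)
  m <- nrow(rankMat)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(from = rownames(rankMat)[idx[, 1L]],
                      to = rownames(rankMat)[idx[, 2L]],
                      distance = d[idx],
                      length = exp(growthRate * d[idx]),
                      stringsAsFactors = FALSE)
  winners <- apply(rankMat, 1L, function(r) {
    w <- names(r)[r == min(r)]
    if (length(w) == 1L) w else NA_character_
  })
  nodes <- data.frame(task = rownames(rankMat), winner = winners,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(nodes = nodes, edges = edges)
}
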