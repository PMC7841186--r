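#' Rank values with the challenge tie conventions
#'
#' Rank 1 is best. Under the min rule (the challenge convention) tied values
#' all receive the smallest rank they jointly span, so two tied winners are
#' both ranked 1 and the next algorithm is ranked 3. The average rule replaces
#' ties by the mean of the spanned ranks and is used internally when building
#' consensus rankings.
#'
#' @param values finite numeric vector of metric values or scores.
#' @param largeBetter logical(1); `TRUE` when larger values are better.
#' @param tie `"min"` (default) or `"average"`.
#' @return Numeric vector of ranks, one per input position (integers for
#'   `"min"`, possibly half-integers for `"average"`).
#' @examples
#' rankWithTies(c(0.9, 0.7, 0.9))                  # 1 3 1
#' rankWithTies(c(0.9, 0.7, 0.9), tie = "average") # 1.5 3 1.5
#' @export
rankWithTies <- function(values, largeBetter = TRUE,
                         tie = c("min", "average")) {
  tie <- match.arg(tie)
  if (!length(values)) stop("empty value vector")
  if (!all(is.finite(values))) stop("values must be finite")
  key <- if (largeBetter) -values else values
  r <- rank(key, ties.method = tie)
  as.numeric(r)
}

#' Ranking method specification
#'
#' Bundles a ranking scheme with its parameters so that the same scheme can
#' be applied to full data and to every bootstrap sample.
#'
#' @param name one of `"meanThenRank"`, `"medianThenRank"`,
#'   `"quantileThenRank"` (aggregate-then-rank with mean / median / empirical
#'   quantile), `"rankThenMean"`, `"rankThenMedian"` (rank-then-aggregate) or
#'   `"testBased"` (significance ranking).
#' @param q quantile in (0, 1) for `"quantileThenRank"`; linear-interpolation
#'   empirical quantile.
#' @param alpha significance level for `"testBased"`.
#' @return An object of class `rankingMethod`.
#' @export
rankingMethod <- function(name = c("meanThenRank", "medianThenRank",
                                   "quantileThenRank", "rankThenMean",
                                   "rankThenMedian", "testBased"),
                          q = 0.5, alpha = 0.05) {
  name <- match.arg(name)
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  structure(list(name = name, q = q, alpha = alpha),
            class = "rankingMethod")
}

#' @export
print.rankingMethod <- function(x, ...) {
  cat("ranking method:", x$name)
  if (x$name == "quantileThenRank") cat(" (q =", x$q, ")")
  if (x$name == "testBased") cat(" (alpha =", x$alpha, ")")
  cat("\n")
  invisible(x)
}

#' Apply a ranking method to one task slice
#'
#' @param slice complete cases x algorithms matrix (see [taskSlice()]).
#' @param method a [rankingMethod()] specification.
#' @param largeBetter logical(1) metric direction.
#' @param task task label recorded in the result.
#' @return A [Ranking-class] object.
#' @export
applyRanking <- function(slice, method = rankingMethod("meanThenRank"),
                         largeBetter = TRUE, task = "T1") {
  stopifnot(inherits(method, "rankingMethod"))
  switch(method$name,
    meanThenRank = aggregateThenRank(slice, "mean", largeBetter, task = task),
    medianThenRank = aggregateThenRank(slice, "median", largeBetter,
                                       task = task),
    quantileThenRank = aggregateThenRank(slice, "quantile", largeBetter,
                                         q = method$q, task = task),
    rankThenMean = rankThenAggregate(slice, "mean", largeBetter, task = task),
    rankThenMedian = rankThenAggregate(slice, "median", largeBetter,
                                       task = task),
    testBased = testThenRank(slice, alpha = method$alpha,
                             largeBetter = largeBetter, task = task)
  )
}

checkSlice <- function(slice) {
  if (!is.matrix(slice) || !is.numeric(slice))
    stop("slice must be a numeric cases x algorithms matrix")
  if (anyNA(slice)) stop("slice contains missing values; impute first")
  if (is.null(colnames(slice)))
    colnames(slice) <- paste0("A", seq_len(ncol(slice)))
  slice
}

#' Aggregate-then-rank
#'
#' Aggregates the metric values of each algorithm across all test cases
#' (mean, median with mid-point convention, or an empirical quantile with
#' linear interpolation) and ranks the aggregates with min ties.
#'
#' @inheritParams applyRanking
#' @param agg `"mean"`, `"median"` or `"quantile"`.
#' @param q quantile level for `agg = "quantile"`.
#' @return A [Ranking-class] object.
#' @export
aggregateThenRank <- function(slice, agg = c("mean", "median", "quantile"),
                              largeBetter = TRUE, q = 0.5, task = "T1") {
  slice <- checkSlice(slice)
  agg <- match.arg(agg)
  vals <- switch(agg,
    mean = colMeans(slice),
    median = apply(slice, 2L, stats::median),
    quantile = apply(slice, 2L, stats::quantile, probs = q, type = 7,
                     names = FALSE))
  r <- rankWithTies(vals, largeBetter = largeBetter, tie = "min")
  names(r) <- colnames(slice)
  new("Ranking", task = task,
      method = if (agg == "quantile") sprintf("quantile(%g)ThenRank", q)
               else paste0(agg, "ThenRank"),
      values = vals, ranks = r)
}

#' Rank-then-aggregate
#'
#' Ranks the algorithms within every test case (min ties), aggregates the
#' per-case ranks of each algorithm (mean or median), and re-ranks the
#' aggregated ranks with min ties.
#'
#' @inheritParams aggregateThenRank
#' @param agg `"mean"` or `"median"`.
#' @return A [Ranking-class] object; its `values` slot holds the aggregated
#'   per-case ranks.
#' @export
rankThenAggregate <- function(slice, agg = c("mean", "median"),
                              largeBetter = TRUE, task = "T1") {
  slice <- checkSlice(slice)
  agg <- match.arg(agg)
  perCase <- perCaseRanks(slice, largeBetter)
  vals <- if (agg == "mean") colMeans(perCase)
          else apply(perCase, 2L, stats::median)
  r <- rankWithTies(vals, largeBetter = FALSE, tie = "min")
  names(r) <- colnames(slice)
  new("Ranking", task = task, method = paste0("rankThen", toTitle(agg)),
      values = vals, ranks = r)
}

toTitle <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))

# cases x algorithms matrix of within-case min-tie ranks
perCaseRanks <- function(slice, largeBetter = TRUE) {
  out <- t(apply(slice, 1L, rankWithTies, largeBetter = largeBetter,
                 tie = "min"))
  if (ncol(slice) == 1L) out <- matrix(out, ncol = 1L)  # apply() drops dims
  dimnames(out) <- dimnames(slice)
  out
}

#' Test-based ranking (significance ranking)
#'
#' For every ordered pair (A, B) a one-sided paired Wilcoxon signed-rank test
#' of "A superior to B" is computed; Holm's adjustment is applied over the
#' family of all p(p-1) one-sided tests within the task. Each algorithm is
#' scored by the number of algorithms it significantly outperforms, and the
#' scores are ranked descending with min ties: algorithms with equally many
#' significant superiorities share a rank.
#'
#' @inheritParams applyRanking
#' @param alpha significance level applied to the Holm-adjusted p-values.
#' @return A [Ranking-class]; its `values` slot holds the significance counts.
#' @export
testThenRank <- function(slice, alpha = 0.05, largeBetter = TRUE,
                         task = "T1") {
  slice <- checkSlice(slice)
  if (nrow(slice) < 2L)
    stop("test-based ranking needs at least 2 test cases")
  if (ncol(slice) == 1L) {
    r <- stats::setNames(1, colnames(slice))
    return(new("Ranking", task = task, method = "testBased",
               values = stats::setNames(0, colnames(slice)), ranks = r))
  }
  sm <- significanceMatrix(slice, alpha = alpha, largeBetter = largeBetter,
                           task = task)
  score <- rowSums(sm@incidence, na.rm = TRUE)
  r <- rankWithTies(score, largeBetter = TRUE, tie = "min")
  names(r) <- colnames(slice)
  new("Ranking", task = task, method = "testBased",
      values = as.numeric(score) |> stats::setNames(colnames(slice)),
      ranks = r)
}
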