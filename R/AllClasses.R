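#' @import methods
NULL

#' Challenge assessment data
#'
#' Long-format container for the per-case metric values of a benchmark
#' challenge: one record per (task, algorithm, test case) triple. The metric
#' direction is a single flag for the whole analysis (e.g. the Dice similarity
#' coefficient is larger-is-better). Records may hold `NA` metric values until
#' [imputeMissing()] replaces them with an unfavorable value.
#'
#' @slot records data.frame with columns `task`, `algorithm`, `case`
#'   (character) and `value` (numeric, `NA` allowed before imputation).
#' @slot smallBetter logical(1); `TRUE` if smaller metric values indicate
#'   better performance.
#' @slot imputed integer(1); number of cells filled by [imputeMissing()].
#' @slot excluded data.frame with columns `task`, `algorithm`: algorithms
#'   without any record in a task, excluded from that task's ranking.
#'
#' @seealso [loadChallenge()], [imputeMissing()], [taskSlice()]
#' @export
setClass("ChallengeData",
  representation(
    records = "data.frame",
    smallBetter = "logical",
    imputed = "integer",
    excluded = "data.frame"
  ),
  prototype(
    records = data.frame(task = character(), algorithm = character(),
                         case = character(), value = numeric()),
    smallBetter = FALSE,
    imputed = 0L,
    excluded = data.frame(task = character(), algorithm = character())
  )
)

setValidity("ChallengeData", function(object) {
  r <- object@records
  need <- c("task", "algorithm", "case", "value")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (!is.numeric(r$value))
    return("metric values must be numeric")
  if (length(object@smallBetter) != 1L || is.na(object@smallBetter))
    return("smallBetter must be TRUE or FALSE")
  key <- paste(r$task, r$algorithm, r$case, sep = "\r")
  if (anyDuplicated(key)) {
    d <- r[duplicated(key), , drop = FALSE][1L, ]
    return(sprintf("duplicate record for (task=%s, algorithm=%s, case=%s)",
                   d$task, d$algorithm, d$case))
  }
  inf <- !is.na(r$value) & !is.finite(r$value)
  if (any(inf))
    return("metric values must be finite or NA")
  TRUE
})

#' Per-task algorithm ranking
#'
#' Result of applying one ranking scheme to one task. Ranks start at 1 (best);
#' tied algorithms share the minimum of the ranks they span, so after a tie of
#' k algorithms at rank r the next rank is r + k. For aggregate-based schemes
#' the aggregate value per algorithm is retained; for the test-based scheme the
#' count of significant pairwise superiorities is stored instead.
#'
#' @slot task character(1) task identifier.
#' @slot method character(1) label of the ranking scheme used.
#' @slot values named numeric; per-algorithm aggregate (or significance count).
#' @slot ranks named numeric; per-algorithm rank, min-tie convention.
#' @export
setClass("Ranking",
  representation(
    task = "character",
    method = "character",
    values = "numeric",
    ranks = "numeric"
  )
)

setValidity("Ranking", function(object) {
  if (length(object@ranks) == 0L) return("empty ranking")
  if (is.null(names(object@ranks))) return("ranks must be named by algorithm")
  if (!validMinTieLayout(object@ranks)) return("ranks violate min-tie layout")
  TRUE
})

#' Bootstrap ranking stability result
#'
#' Rankings of one task recomputed on `b` bootstrap samples (n cases drawn
#' with replacement from the task's n cases), plus derived summaries: the
#' rank-frequency matrix, per-algorithm median ranks and percentile intervals,
#' and the distribution of Kendall's tau between each replicate ranking and
#' the full-data ranking.
#'
#' @slot task character(1) task identifier.
#' @slot method character(1) ranking scheme label.
#' @slot b integer(1) number of bootstrap replicates.
#' @slot seed integer(1) RNG seed that fully determines the resamples.
#' @slot replicates b x p numeric matrix of replicate ranks (columns named by
#'   algorithm).
#' @slot rankFrequency p x p integer matrix; `[i, j]` counts replicates in
#'   which algorithm i achieved rank j. Rows sum to b.
#' @slot medianRank named numeric per-algorithm median bootstrap rank.
#' @slot intervals p x 2 matrix of percentile interval endpoints.
#' @slot level numeric(1) interval coverage in percent (default 95).
#' @slot tauDist numeric(b); Kendall's tau of each replicate ranking to the
#'   full-data ranking (`NA` where tau is undefined, e.g. all-tied rankings).
#' @slot fullRanking the [Ranking-class] on the full assessment data.
#' @slot nCases integer(1) number of test cases in the task.
#' @slot caution logical(1); `TRUE` when the task has fewer than 20 cases and
#'   the bootstrap distribution should be interpreted with care.
#' @export
setClass("BootstrapResult",
  representation(
    task = "character",
    method = "character",
    b = "integer",
    seed = "integer",
    replicates = "matrix",
    rankFrequency = "matrix",
    medianRank = "numeric",
    intervals = "matrix",
    level = "numeric",
    tauDist = "numeric",
    fullRanking = "Ranking",
    nCases = "integer",
    caution = "logical"
  )
)

setValidity("BootstrapResult", function(object) {
  if (nrow(object@replicates) != object@b)
    return("replicate matrix must have b rows")
  if (!all(rowSums(object@rankFrequency) == object@b))
    return("rank frequency rows must sum to b")
  if (length(object@tauDist) != object@b)
    return("tauDist must have one entry per replicate")
  ok <- is.na(object@tauDist) | (object@tauDist >= -1 & object@tauDist <= 1)
  if (!all(ok)) return("tau values must lie in [-1, 1]")
  inInt <- object@medianRank >= object@intervals[, 1L] &
    object@medianRank <= object@intervals[, 2L]
  if (!all(inInt)) return("median rank must lie within its interval")
  TRUE
})

#' Pairwise significance matrix
#'
#' Holm-adjusted p-values of all p(p-1) one-sided paired Wilcoxon signed-rank
#' tests within one task ("row algorithm superior to column algorithm") and
#' the boolean incidence of significant superiority at level alpha. The
#' diagonal is undefined (NA).
#'
#' @slot task character(1) task identifier.
#' @slot pValues p x p numeric matrix of Holm-adjusted one-sided p-values.
#' @slot incidence p x p logical matrix; `[i, j]` is `TRUE` when algorithm i is
#'   significantly superior to algorithm j.
#' @slot alpha numeric(1) significance level.
#' @export
setClass("SignificanceMatrix",
  representation(
    task = "character",
    pValues = "matrix",
    incidence = "matrix",
    alpha = "numeric"
  )
)

setValidity("SignificanceMatrix", function(object) {
  p <- object@pValues
  if (nrow(p) != ncol(p)) return("p-value matrix must be square")
  if (!all(is.na(diag(p)))) return("diagonal must be NA")
  off <- p[row(p) != col(p)]
  if (any(!is.na(off) & (off < 0 | off > 1)))
    return("p-values must lie in [0, 1]")
  TRUE
})

#' Cross-task consensus ranking
#'
#' Consensus ranking over the tasks of a multi-task challenge. The per-task
#' rank matrix uses the average-rank tie convention (ties replaced by the mean
#' of the spanned ranks) as required by the mean-rank consensus, which
#' averages each algorithm's ranks across tasks and min-tie ranks these
#' averages; the distance-minimizing variant searches orderings minimizing the
#' summed rank distance to the per-task rankings.
#'
#' @slot rankMatrix tasks x algorithms numeric matrix, average-tie ranks.
#' @slot meanRanks named numeric; mean rank across tasks per algorithm.
#' @slot consensusRanks named numeric; consensus rank (min-tie).
#' @slot method character(1): `"meanRank"` or `"distance"`.
#' @slot distance character(1); rank distance used by the distance method.
#' @export
setClass("ConsensusResult",
  representation(
    rankMatrix = "matrix",
    meanRanks = "numeric",
    consensusRanks = "numeric",
    method = "character",
    distance = "character"
  )
)

setValidity("ConsensusResult", function(object) {
  p <- ncol(object@rankMatrix)
  if (any(object@meanRanks < 1 | object@meanRanks > p))
    return("mean ranks must lie in [1, p]")
  if (!validMinTieLayout(object@consensusRanks))
    return("consensus ranks violate min-tie layout")
  TRUE
})

# Min-tie layout: sorted unique ranks r with multiplicities k satisfy
# r_next = r + k, starting at 1.
validMinTieLayout <- function(ranks) {
  tab <- table(ranks)
  r <- as.numeric(names(tab))
  k <- as.integer(tab)
  all(r == cumsum(c(1, k[-length(k)])))
}
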