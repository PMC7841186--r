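#' Extract ranks
#'
#' @param x an object carrying ranks ([Ranking-class],
#'   [ConsensusResult-class] or [BootstrapResult-class]).
#' @param ... unused.
#' @return Named numeric vector of ranks (for `BootstrapResult`, the ranks of
#'   the full-data ranking).
#' @export
setGeneric("ranks", function(x, ...) standardGeneric("ranks"))

#' Algorithm identifiers
#'
#' @param x a benchrank object.
#' @param ... unused.
#' @return Character vector of algorithm identifiers.
#' @export
setGeneric("algorithms", function(x, ...) standardGeneric("algorithms"))

#' Task identifiers
#'
#' @param x a benchrank object.
#' @param ... unused.
#' @return Character vector of task identifiers.
#' @export
setGeneric("challengeTasks", function(x, ...) standardGeneric("challengeTasks"))

#' Direction of the metric
#'
#' @param x a [ChallengeData-class] object.
#' @param ... unused.
#' @return `TRUE` if smaller metric values are better.
#' @export
setGeneric("smallBetter", function(x, ...) standardGeneric("smallBetter"))

#' @describeIn ranks ranks of a per-task ranking.
#' @export
setMethod("ranks", "Ranking", function(x, ...) x@ranks)

#' @describeIn ranks consensus ranks across tasks.
#' @export
setMethod("ranks", "ConsensusResult", function(x, ...) x@consensusRanks)

#' @describeIn ranks full-data ranks underlying a bootstrap result.
#' @export
setMethod("ranks", "BootstrapResult", function(x, ...) x@fullRanking@ranks)

#' @describeIn algorithms algorithms present in the assessment data.
#' @export
setMethod("algorithms", "ChallengeData", function(x, ...)
  sort(unique(x@records$algorithm)))

#' @describeIn algorithms algorithms of a ranking.
#' @export
setMethod("algorithms", "Ranking", function(x, ...) names(x@ranks))

#' @describeIn algorithms algorithms of a consensus result.
#' @export
setMethod("algorithms", "ConsensusResult", function(x, ...)
  colnames(x@rankMatrix))

#' @describeIn challengeTasks tasks present in the assessment data.
#' @export
setMethod("challengeTasks", "ChallengeData", function(x, ...)
  unique(x@records$task))

#' @describeIn challengeTasks tasks contributing to a consensus.
#' @export
setMethod("challengeTasks", "ConsensusResult", function(x, ...)
  rownames(x@rankMatrix))

#' @describeIn smallBetter metric direction flag.
#' @export
setMethod("smallBetter", "ChallengeData", function(x, ...) x@smallBetter)

setMethod("show", "ChallengeData", function(object) {
  r <- object@records
  cat("ChallengeData:", length(unique(r$task)), "task(s),",
      length(unique(r$algorithm)), "algorithm(s),",
      nrow(r), "records\n")
  cat("  metric direction:",
      if (object@smallBetter) "smaller is better" else "larger is better", "\n")
  if (object@imputed > 0L)
    cat("  imputed cells:", object@imputed, "\n")
  if (nrow(object@excluded) > 0L)
    cat("  per-task exclusions:", nrow(object@excluded), "\n")
  invisible(NULL)
})

setMethod("show", "Ranking", function(object) {
  cat("Ranking for task", object@task, "(", object@method, ")\n")
  ord <- order(object@ranks, names(object@ranks))
  print(data.frame(algorithm = names(object@ranks)[ord],
                   value = unname(object@values)[ord],
                   rank = unname(object@ranks)[ord],
                   row.names = NULL))
  invisible(NULL)
})

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult for task", object@task, "(", object@method, "),",
      object@b, "replicates, seed", object@seed, "\n")
  if (object@caution)
    cat("  caution: fewer than 20 test cases; bootstrap distribution may be",
        "a poor estimate\n")
  print(data.frame(algorithm = names(object@medianRank),
                   median = unname(object@medianRank),
                   lower = object@intervals[, 1L],
                   upper = object@intervals[, 2L],
                   row.names = NULL))
  invisible(NULL)
})

setMethod("show", "SignificanceMatrix", function(object) {
  cat("SignificanceMatrix for task", object@task, "at alpha =",
      object@alpha, "\n")
  cat("  significant superiorities:", sum(object@incidence, na.rm = TRUE),
      "of", sum(!is.na(object@pValues)), "ordered pairs\n")
  invisible(NULL)
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult (", object@method, ") over",
      nrow(object@rankMatrix), "tasks\n")
  ord <- order(object@consensusRanks, names(object@consensusRanks))
  print(data.frame(algorithm = names(object@consensusRanks)[ord],
                   meanRank = unname(object@meanRanks)[ord],
                   consensusRank = unname(object@consensusRanks)[ord],
                   row.names = NULL))
  invisible(NULL)
})
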