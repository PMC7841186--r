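#' Analysis configuration
#'
#' Bundles every knob of a challenge analysis so that a saved configuration
#' plus the input CSV reproduces the entire report. Defaults: aggregate-then-
#' rank with the mean for single-task ordering, mean-rank consensus over
#' per-task significance rankings for multi-task ordering, b = 1000 bootstrap
#' replicates, alpha = 0.05, 95% percentile intervals.
#'
#' @param method a [rankingMethod()] (or its name) used for ordering and
#'   bootstrapping.
#' @param consensusMethod `"meanRank"` or `"distance"`.
#' @param consensusBase ranking scheme used per task before consensus
#'   aggregation; default `"testBased"` (significance ranking).
#' @param b bootstrap replicates.
#' @param alpha significance level.
#' @param level percentile-interval coverage in percent.
#' @param seed master seed for bootstrap resampling and tie-break
#'   randomization.
#' @param smallBetter metric direction.
#' @param worstValue unfavorable value for imputation (`NULL` = default rule
#'   of [imputeMissing()]).
#' @param top optional truncation size: figures show only the `top` first
#'   algorithms of the selected/consensus ranking (tables always show all).
#' @param figures character vector of figure kinds to render, or `"all"`.
#' @param outputDir report output directory.
#' @return A list of class `analysisConfig`.
#' @export
analysisConfig <- function(method = rankingMethod("meanThenRank"),
                           consensusMethod = "meanRank",
                           consensusBase = "testBased",
                           b = 1000L, alpha = 0.05, level = 95, seed = 1L,
                           smallBetter = FALSE, worstValue = NULL,
                           top = NULL, figures = "all",
                           outputDir = "benchrank-report") {
  if (is.character(method)) method <- rankingMethod(method, alpha = alpha)
  stopifnot(inherits(method, "rankingMethod"))
  structure(list(method = method, consensusMethod = consensusMethod,
                 consensusBase = consensusBase, b = as.integer(b),
                 alpha = alpha, level = level, seed = as.integer(seed),
                 smallBetter = smallBetter, worstValue = worstValue,
                 top = if (is.null(top)) NULL else as.integer(top),
                 figures = figures, outputDir = outputDir),
            class = "analysisConfig")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return `readAnalysisConfig` returns an `analysisConfig`;
#'   `writeAnalysisConfig` returns the path invisibly.
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$method
  method <- if (is.list(m))
    rankingMethod(m$name, q = m$q %||% 0.5, alpha = m$alpha %||% 0.05)
  else rankingMethod(m %||% "meanThenRank")
  analysisConfig(method = method,
                 consensusMethod = y$consensusMethod %||% "meanRank",
                 consensusBase = y$consensusBase %||% "testBased",
                 b = y$b %||% 1000L, alpha = y$alpha %||% 0.05,
                 level = y$level %||% 95, seed = y$seed %||% 1L,
                 smallBetter = y$smallBetter %||% FALSE,
                 worstValue = y$worstValue,
                 top = y$top, figures = y$figures %||% "all",
                 outputDir = y$outputDir %||% "benchrank-report")
}

#' @rdname readAnalysisConfig
#' @param config an `analysisConfig` object.
#' @export
writeAnalysisConfig <- function(config, path) {
  stopifnot(inherits(config, "analysisConfig"))
  y <- unclass(config)
  y$method <- unclass(config$method)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full challenge analysis report
#'
#' Wires ingestion, imputation, ranking, bootstrap stability, significance
#' testing and figure rendering into one reproducible bundle written to
#' `config$outputDir`: per-task ranking tables and figures (dot/box, podium,
#' ranking heatmap, line, blob, violin, significance map), and for multi-task
#' inputs additionally the consensus table, cross-task and per-algorithm /
#' per-task bootstrap blob plots, per-task violin plots, the task dendrogram
#' and the task-similarity network graph, plus a navigable Markdown report
#' logging seeds, imputation counts and the small-sample bootstrap caution.
#'
#' @param input path to an assessment-data CSV (see [loadChallenge()]) or a
#'   [ChallengeData-class] object.
#' @param config an [analysisConfig()].
#' @return Invisibly, a list with the per-task results (`rankings`,
#'   `bootstrap`, `significance`), the `consensus` (or `NULL`), and the paths
#'   of all written files.
#' @export
runReport <- function(input, config = analysisConfig()) {
  stopifnot(inherits(config, "analysisConfig"))
  stage <- "ingestion"
  tryCatch({
    data <- if (is(input, "ChallengeData")) input
            else loadChallenge(input, smallBetter = config$smallBetter)
    stage <- "imputation"
    data <- imputeMissing(data, worstValue = config$worstValue)

    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    emit <- function(p) { paths <<- c(paths, p); p }
    fig <- function(kind) identical(config$figures, "all") ||
      kind %in% config$figures
    figPath <- function(...) file.path(config$outputDir, paste0(...))

    writeLines(validationReport(data),
               emit(figPath("validation.txt")))

    tasks <- challengeTasks(data)
    multi <- length(tasks) > 1L
    largeBetter <- !smallBetter(data)
    md <- c("# Challenge analysis report", "",
            sprintf("- tasks: %d; algorithms: %d", length(tasks),
                    length(algorithms(data))),
            sprintf("- ranking method: %s", config$method$name),
            sprintf("- bootstrap replicates: %d (seed %d)", config$b,
                    config$seed),
            sprintf("- significance level: %g", config$alpha),
            sprintf("- imputed cells: %d", data@imputed), "")

    stage <- "ranking"
    results <- list()
    for (tk in tasks) {
      slice <- taskSlice(data, tk)
      res <- analyzeTask(slice, tk, config, largeBetter)
      results[[tk]] <- res
      emit(writeRanking(res$ranking, figPath("ranking_", tk, ".csv")))
      emit(writeSignificanceMatrix(res$significance,
                                   figPath("significance_", tk, ".csv")))
      writeBootstrap(res$bootstrap,
                     figPath("bootstrap_replicates_", tk, ".csv"),
                     figPath("bootstrap_summary_", tk, ".csv"))
      paths <- c(paths, figPath("bootstrap_replicates_", tk, ".csv"),
                 figPath("bootstrap_summary_", tk, ".csv"))
      ord <- names(sort(ranks(res$ranking)))

      stage <- paste0("figures (task ", tk, ")")
      kinds <- c("dotbox", "podium", "heatmap", "line", "blob", "violin",
                 "significance_map")
      rendered <- character(0)
      for (k in kinds) {
        if (!fig(k)) next
        dataK <- switch(k,
          dotbox = slice,
          podium = if (!is.null(config$top) && ncol(slice) > 30)
            podiumData(slice[, utils::head(ord, config$top), drop = FALSE],
                       largeBetter = largeBetter, seed = config$seed)
          else res$podium,
          heatmap = res$heatmap,
          line = res$line,
          blob = res$bootstrap,
          violin = res$bootstrap@tauDist,
          significance_map = res$significance)
        if (k == "podium" && ncol(slice) > 30 && is.null(config$top)) next
        emit(renderFigure(k, dataK, figPath(k, "_", tk, ".png"),
                          seed = config$seed, order = ord,
                          top = config$top))
        rendered <- c(rendered, k)
      }
      nUndef <- sum(is.na(res$bootstrap@tauDist))
      md <- c(md, sprintf("## Task %s", tk),
              sprintf("- cases: %d%s", res$bootstrap@nCases,
                      if (res$bootstrap@caution)
                        " (caution: < 20 cases, bootstrap may be unreliable)"
                      else ""),
              sprintf("- replicates with undefined tau (all-tied ranking): %d",
                      nUndef),
              "", rankingTableMd(res$ranking), "",
              paste(sprintf("![%s](%s_%s.png)", rendered, rendered, tk),
                    collapse = " "), "")
    }

    consensus <- NULL
    if (multi) {
      stage <- "consensus"
      baseRankings <- lapply(tasks, function(tk) {
        applyRanking(taskSlice(data, tk),
                     rankingMethod(config$consensusBase,
                                   alpha = config$alpha),
                     largeBetter = largeBetter, task = tk)
      })
      names(baseRankings) <- tasks
      consensus <- consensusRank(baseRankings, method = config$consensusMethod)
      emit(writeConsensus(consensus, figPath("consensus.csv")))
      consOrd <- names(sort(ranks(consensus)))

      stage <- "multi-task figures"
      rankMat <- consensus@rankMatrix
      if (fig("blob")) {
        crossTask <- lapply(colnames(rankMat), function(a) rankMat[, a])
        names(crossTask) <- colnames(rankMat)
        emit(renderFigure("blob", blobData(crossTask, level = config$level),
                          figPath("blob_across_tasks.png"),
                          order = consOrd, top = config$top))
        for (a in utils::head(consOrd, config$top %||% length(consOrd))) {
          perTaskRanks <- lapply(tasks, function(tk)
            results[[tk]]$bootstrap@replicates[, a])
          names(perTaskRanks) <- tasks
          emit(renderFigure("blob", blobData(perTaskRanks,
                                             level = config$level),
                            figPath("blob_bootstrap_", a, ".png")))
        }
      }
      if (fig("violin")) {
        taus <- lapply(tasks, function(tk) results[[tk]]$bootstrap@tauDist)
        names(taus) <- tasks
        emit(renderFigure("violin", taus, figPath("violin_tasks.png")))
      }
      if (fig("dendrogram"))
        emit(renderFigure("dendrogram", dendrogramData(baseRankings),
                          figPath("dendrogram.png")))
      if (fig("network"))
        emit(renderFigure("network", networkData(baseRankings),
                          figPath("network.png"), seed = config$seed))
      md <- c(md, "## Cross-task consensus", "", consensusTableMd(consensus),
              "",
              "![across tasks](blob_across_tasks.png)",
              "![violins](violin_tasks.png)",
              "![dendrogram](dendrogram.png) ![network](network.png)", "")
    }

    stage <- "report"
    writeLines(md, emit(figPath("report.md")))
    invisible(list(data = data,
                   rankings = lapply(results, `[[`, "ranking"),
                   bootstrap = lapply(results, `[[`, "bootstrap"),
                   significance = lapply(results, `[[`, "significance"),
                   consensus = consensus, paths = paths))
  }, error = function(e) {
    stop("report failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

analyzeTask <- function(slice, task, config, largeBetter) {
  ranking <- applyRanking(slice, config$method, largeBetter = largeBetter,
                          task = task)
  list(
    ranking = ranking,
    bootstrap = bootstrapRankings(slice, config$method, b = config$b,
                                  seed = config$seed,
                                  largeBetter = largeBetter, task = task,
                                  level = config$level),
    significance = significanceMatrix(slice, alpha = config$alpha,
                                      largeBetter = largeBetter, task = task),
    podium = podiumData(slice, largeBetter = largeBetter,
                        seed = config$seed),
    heatmap = heatmapCounts(slice, largeBetter = largeBetter),
    line = linePlotData(slice, largeBetter = largeBetter)
  )
}

rankingTableMd <- function(ranking) {
  ord <- order(ranks(ranking), names(ranks(ranking)))
  c("| algorithm | value | rank |", "|---|---|---|",
    sprintf("| %s | %.4g | %g |", names(ranks(ranking))[ord],
            unname(ranking@values)[ord], unname(ranks(ranking))[ord]))
}

consensusTableMd <- function(consensus) {
  ord <- order(ranks(consensus), names(ranks(consensus)))
  c("| algorithm | mean rank | consensus rank |", "|---|---|---|",
    sprintf("| %s | %.3g | %g |", names(ranks(consensus))[ord],
            unname(consensus@meanRanks)[ord],
            unname(ranks(consensus))[ord]))
}
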