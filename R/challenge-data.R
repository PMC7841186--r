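#' Construct challenge assessment data from a data frame
#'
#' @param records data.frame with (at least) task, algorithm, case and value
#'   columns; names configurable via `columnMap`.
#' @param smallBetter logical(1); `TRUE` if smaller metric values are better.
#' @param columnMap named character vector mapping the canonical names
#'   `task`, `algorithm`, `case`, `value` to the column names present in
#'   `records`. A map omitting `task` declares a single-task challenge and an
#'   implicit task `"T1"` is used.
#' @return A [ChallengeData-class] object.
#' @export
challengeData <- function(records,
                          smallBetter = FALSE,
                          columnMap = c(task = "task", algorithm = "algorithm",
                                        case = "case", value = "value")) {
  need <- c("algorithm", "case", "value")
  if (!all(need %in% names(columnMap)))
    stop("columnMap must map at least ", paste(need, collapse = ", "))
  missingCols <- setdiff(unname(columnMap), names(records))
  if (length(missingCols))
    stop("column(s) not found in input: ", paste(missingCols, collapse = ", "))
  out <- data.frame(
    task = if ("task" %in% names(columnMap))
      as.character(records[[columnMap[["task"]]]]) else
        rep("T1", nrow(records)),
    algorithm = as.character(records[[columnMap[["algorithm"]]]]),
    case = as.character(records[[columnMap[["case"]]]]),
    value = parseMetricValues(records[[columnMap[["value"]]]]),
    stringsAsFactors = FALSE
  )
  key <- paste(out$task, out$algorithm, out$case, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate record for (task=%s, algorithm=%s, case=%s)",
      d$task, d$algorithm, d$case))
  }
  new("ChallengeData", records = out, smallBetter = smallBetter,
      imputed = 0L, excluded = findExclusions(out))
}

parseMetricValues <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v) & toupper(x) != "NA")
  if (length(bad))
    stop("unparseable metric value ", shQuote(x[bad[1L]]),
         " in row ", bad[1L])
  v
}

# Algorithms with no record at all in a task, relative to the union of
# algorithms across tasks: excluded from that task's ranking.
findExclusions <- function(records) {
  algs <- unique(records$algorithm)
  tasks <- unique(records$task)
  ex <- expand.grid(task = tasks, algorithm = algs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  present <- unique(records[, c("task", "algorithm")])
  key <- function(d) paste(d$task, d$algorithm, sep = "\r")
  ex[!(key(ex) %in% key(present)), , drop = FALSE]
}

#' Load challenge assessment data from a CSV file
#'
#' Reads a long-format CSV of challenge results: one row per metric value with
#' columns for the task, the algorithm, the test-case identifier and the
#' metric value (default header `task,algorithm,case,value`; UTF-8, decimal
#' point `.`). Single-task files without a task column are accepted when
#' `columnMap` omits `task`; they receive the implicit task `"T1"`.
#'
#' @inheritParams challengeData
#' @param path path to the CSV file.
#' @return A validated [ChallengeData-class] object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(task = "T1", algorithm = rep(c("A", "B"), each = 2),
#'                      case = rep(c("c1", "c2"), 2),
#'                      value = c(0.9, 0.8, 0.7, 0.6)),
#'           f, row.names = FALSE)
#' loadChallenge(f)
#' @export
loadChallenge <- function(path,
                          columnMap = c(task = "task",
                                        algorithm = "algorithm",
                                        case = "case", value = "value"),
                          smallBetter = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  challengeData(raw, smallBetter = smallBetter, columnMap = columnMap)
}

#' Impute missing metric values with an unfavorable value
#'
#' Missing values arise when an algorithm does not deliver a metric value for
#' a test case. For every algorithm participating in a task (i.e. having at
#' least one record there), each absent or `NA` cell of the task's
#' cases x algorithms grid is set to `worstValue`. Algorithms without any
#' record in a task are not fabricated; they stay excluded from that task
#' (and are flagged in the validation report).
#'
#' @param data a [ChallengeData-class] object.
#' @param worstValue finite numeric(1) used as the unfavorable value. Default:
#'   0 for larger-is-better metrics (the usual convention for non-negative
#'   scores such as the Dice coefficient), the observed per-task maximum for
#'   smaller-is-better metrics.
#' @return A [ChallengeData-class] with complete per-task grids; the number of
#'   imputed cells is recorded in the object and shown by `show()`.
#' @export
imputeMissing <- function(data, worstValue = NULL) {
  stopifnot(is(data, "ChallengeData"))
  if (!is.null(worstValue) && (!is.numeric(worstValue) ||
                               !is.finite(worstValue)))
    stop("worstValue must be a finite number")
  rec <- data@records
  pieces <- split(rec, rec$task)
  nImp <- 0L
  filled <- lapply(pieces, function(tr) {
    wv <- worstValue
    if (is.null(wv)) {
      wv <- if (data@smallBetter) {
        if (all(is.na(tr$value)))
          stop("cannot derive worstValue for task ", tr$task[1L],
               ": all values missing")
        max(tr$value, na.rm = TRUE)
      } else 0
    }
    cases <- unique(tr$case)
    algs <- unique(tr$algorithm)
    grid <- expand.grid(case = cases, algorithm = algs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$task <- tr$task[1L]
    m <- merge(grid, tr, by = c("task", "algorithm", "case"),
               all.x = TRUE, sort = FALSE)
    miss <- is.na(m$value)
    nImp <<- nImp + sum(miss)
    m$value[miss] <- wv
    m[, c("task", "algorithm", "case", "value")]
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  new("ChallengeData", records = out, smallBetter = data@smallBetter,
      imputed = data@imputed + nImp, excluded = data@excluded)
}

#' Extract one task as a cases x algorithms matrix
#'
#' @param data a [ChallengeData-class] object.
#' @param task task identifier; may be omitted for single-task data.
#' @param requireComplete error when the slice still contains missing cells
#'   (run [imputeMissing()] first).
#' @return Numeric matrix, rows = test cases, columns = algorithms (sorted).
#' @export
taskSlice <- function(data, task = NULL, requireComplete = TRUE) {
  stopifnot(is(data, "ChallengeData"))
  tasks <- unique(data@records$task)
  if (is.null(task)) {
    if (length(tasks) != 1L)
      stop("multi-task data: specify the task")
    task <- tasks
  }
  if (!task %in% tasks) stop("unknown task: ", task)
  tr <- data@records[data@records$task == task, , drop = FALSE]
  cases <- unique(tr$case)
  algs <- sort(unique(tr$algorithm))
  m <- matrix(NA_real_, nrow = length(cases), ncol = length(algs),
              dimnames = list(cases, algs))
  m[cbind(match(tr$case, cases), match(tr$algorithm, algs))] <- tr$value
  if (requireComplete && anyNA(m))
    stop("task ", task, " has missing cells; run imputeMissing() first")
  m
}

#' Text validation report for assessment data
#'
#' Summarizes the challenge structure, the number of imputed cells and any
#' per-task algorithm exclusions.
#'
#' @param data a [ChallengeData-class] object.
#' @return Character vector of report lines (also usable with `writeLines`).
#' @export
validationReport <- function(data) {
  stopifnot(is(data, "ChallengeData"))
  r <- data@records
  lines <- c(
    "Assessment data validation",
    sprintf("  tasks: %d", length(unique(r$task))),
    sprintf("  algorithms: %d", length(unique(r$algorithm))),
    sprintf("  records: %d", nrow(r)),
    sprintf("  metric direction: %s",
            if (data@smallBetter) "smaller is better" else "larger is better"),
    sprintf("  imputed cells (set to unfavorable value): %d", data@imputed)
  )
  if (nrow(data@excluded) > 0L) {
    lines <- c(lines, "  algorithms excluded from tasks (no records):",
               sprintf("    task %s: %s", data@excluded$task,
                       data@excluded$algorithm))
  } else {
    lines <- c(lines, "  exclusions: none")
  }
  lines <- c(lines,
    "  note: imputed values participate in rankings and significance tests")
  for (tk in unique(r$task)) {
    n <- length(unique(r$case[r$task == tk]))
    if (n < 20)
      lines <- c(lines, sprintf(
        "  caution: task %s has only %d test cases; bootstrap results should be treated with caution",
        tk, n))
  }
  lines
}

#' Export a ranking to CSV
#'
#' Writes a two-column table (algorithm, rank) with the aggregate value as an
#' optional third column.
#'
#' @param x a [Ranking-class] object.
#' @param path output CSV path.
#' @param includeValues include the aggregate-value column.
#' @return The path, invisibly.
#' @export
writeRanking <- function(x, path, includeValues = TRUE) {
  stopifnot(is(x, "Ranking"))
  ord <- order(x@ranks, names(x@ranks))
  d <- data.frame(algorithm = names(x@ranks)[ord],
                  rank = unname(x@ranks)[ord])
  if (includeValues && !all(is.na(x@values)))
    d$value <- unname(x@values)[ord]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
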