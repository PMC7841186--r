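#' Fully separated synthetic challenge
#'
#' Emulates a best-case challenge in which the ranking of five algorithms is
#' clear and indisputable: metric values mimic a Dice-like score in \[0, 1\]
#' and are drawn uniformly from disjoint strata \[0.9, 1), \[0.8, 0.9),
#' \[0.7, 0.8), \[0.6, 0.7) and \[0.5, 0.6) for algorithms A1..A5. Every A1
#' value therefore exceeds every A2 value and so on, for any draw: all ranking
#' schemes agree and bootstrap rank distributions are degenerate.
#'
#' @param n number of test cases (the reference scenario uses 50).
#' @param seed integer RNG seed.
#' @return A [ChallengeData-class] with one task `"T1"` and algorithms
#'   `A1`..`A5` (larger is better).
#' @export
generateIdeal <- function(n = 50L, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  upper <- seq(1.0, 0.6, by = -0.1)
  recs <- do.call(rbind, lapply(1:5, function(k) {
    data.frame(task = "T1", algorithm = paste0("A", k),
               case = paste0("c", seq_len(n)),
               value = stats::runif(n, min = upper[k] - 0.1, max = upper[k]),
               stringsAsFactors = FALSE)
  }))
  challengeData(recs, smallBetter = FALSE)
}

#' Fully random synthetic challenge
#'
#' Emulates a challenge in which all differences between algorithms are due
#' to chance: 250 normal draws with mean 1.5 and variance 1 are transformed by
#' the logistic function 1/(1 + exp(-x)) into a skewed distribution on
#' (0, 1) and assigned to algorithms A1..A5 sequentially by draw order
#' (draws 1-50 to A1, and so on), giving n = 50 test cases. All algorithms
#' share the identical distribution, so the only correct ranking assigns one
#' shared rank.
#'
#' @param seed integer RNG seed.
#' @param n number of test cases per algorithm (reference scenario: 50).
#' @return A [ChallengeData-class] with one task `"T1"` and algorithms
#'   `A1`..`A5` (larger is better).
#' @export
generateRandom <- function(seed = 1L, n = 50L) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed))
  vals <- stats::plogis(stats::rnorm(5L * n, mean = 1.5, sd = 1))
  recs <- data.frame(task = "T1",
                     algorithm = rep(paste0("A", 1:5), each = n),
                     case = rep(paste0("c", seq_len(n)), times = 5L),
                     value = vals, stringsAsFactors = FALSE)
  challengeData(recs, smallBetter = FALSE)
}

#' Generator specification for custom synthetic challenges
#'
#' @param n cases per task; recycled to `tasks` in [generateCustom()].
#' @param p number of algorithms.
#' @param distribution `"ideal"` (disjoint uniform strata, best algorithm
#'   first) or `"random"` (identical logistic-transformed normal distribution
#'   for all algorithms); recycled across tasks.
#' @param missingRate probability that a cell is missing before imputation.
#' @param seed integer RNG seed.
#' @return An object of class `generatorSpec`.
#' @export
generatorSpec <- function(n = 50L, p = 5L, distribution = "ideal",
                          missingRate = 0, seed = 1L) {
  stopifnot(all(n >= 1L), p >= 1L, missingRate >= 0, missingRate < 1)
  if (!all(distribution %in% c("ideal", "random")))
    stop("unsupported distribution: ",
         paste(setdiff(distribution, c("ideal", "random")), collapse = ", "))
  structure(list(n = as.integer(n), p = as.integer(p),
                 distribution = distribution,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "generatorSpec")
}

#' Generate a custom (multi-task) synthetic challenge
#'
#' Builds multi-task fixtures mixing well-separated and random tasks with
#' configurable case counts and a missingness rate (cells removed before
#' imputation). For `"ideal"` tasks with p algorithms, algorithm k draws
#' uniformly from a stratum of width 1/(p + 4) stacked directly below its
#' predecessor's, so the strata are disjoint and the true order is A1 > ... >
#' Ap. For `"random"` tasks all algorithms share the logistic-transformed
#' normal(1.5, 1) distribution.
#'
#' @param spec a [generatorSpec()].
#' @param tasks number of tasks.
#' @return A [ChallengeData-class]; values missing at rate `missingRate` are
#'   `NA` and must be handled by [imputeMissing()].
#' @export
generateCustom <- function(spec = generatorSpec(), tasks = 1L) {
  stopifnot(inherits(spec, "generatorSpec"), tasks >= 1L)
  set.seed(spec$seed)
  ns <- rep_len(spec$n, tasks)
  dists <- rep_len(spec$distribution, tasks)
  p <- spec$p
  width <- 1 / (p + 4)
  recs <- do.call(rbind, lapply(seq_len(tasks), function(t) {
    n <- ns[t]
    vals <- if (dists[t] == "ideal") {
      unlist(lapply(seq_len(p), function(k)
        stats::runif(n, min = 1 - k * width, max = 1 - (k - 1) * width)))
    } else {
      stats::plogis(stats::rnorm(p * n, mean = 1.5, sd = 1))
    }
    data.frame(task = paste0("T", t),
               algorithm = rep(paste0("A", seq_len(p)), each = n),
               case = rep(paste0("c", seq_len(n)), times = p),
               value = vals, stringsAsFactors = FALSE)
  }))
  if (spec$missingRate > 0) {
    drop <- stats::runif(nrow(recs)) < spec$missingRate
    recs$value[drop] <- NA_real_
  }
  challengeData(recs, smallBetter = FALSE)
}

#' Write assessment data in the CSV schema read by [loadChallenge()]
#'
#' @param data a [ChallengeData-class] object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeChallenge <- function(data, path) {
  stopifnot(is(data, "ChallengeData"))
  utils::write.csv(data@records, path, row.names = FALSE)
  invisible(path)
}
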