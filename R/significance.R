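#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether the metric values `x` are superior to the paired values `y`
#' in the metric's favorable direction (alternative: "x better than y"). Zero
#' differences are dropped before ranking the absolute differences (classic
#' signed-rank convention); the number dropped is reported via an attribute.
#' For at most `exactLimit` nonzero pairs the exact null distribution of the
#' positive-rank sum is computed by dynamic programming over the (possibly
#' tied, hence averaged) ranks, which agrees with full enumeration of all
#' 2^n sign assignments. Beyond the limit a normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' @param x,y paired numeric vectors of equal length (pairing by test case).
#' @param largeBetter logical(1); `TRUE` when larger metric values are better.
#' @param exactLimit exact-distribution threshold on the number of nonzero
#'   pairs (default 25).
#' @return One-sided p-value (numeric scalar) with attributes `nZero` (number
#'   of dropped zero differences) and `degenerate` (`TRUE` when all
#'   differences were zero, in which case p = 1).
#' @examples
#' wilcoxonOneSided(c(5, 6, 7), c(1, 2, 3))  # 2^-3 = 0.125
#' @export
wilcoxonOneSided <- function(x, y, largeBetter = TRUE, exactLimit = 25L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- if (largeBetter) x - y else y - x
  nZero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    p <- 1
    attr(p, "nZero") <- nZero
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  r <- rank(abs(d))  # average ranks for tied magnitudes
  W <- sum(r[d > 0])
  p <- if (n <= exactLimit) exactSignedRankTail(r, W)
       else normalSignedRankTail(r, W, n)
  p <- min(max(p, 0), 1)
  attr(p, "nZero") <- nZero
  attr(p, "degenerate") <- FALSE
  p
}

# P(W+ >= w) under random independent signs; exact, tie-aware.
# Ranks are doubled so averaged (half-integer) ranks become integers, then the
# count of subsets attaining each rank-sum is built by convolution.
exactSignedRankTail <- function(ranks, w) {
  ri <- as.integer(round(2 * ranks))
  total <- sum(ri)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (wi in ri) {
    counts <- counts + c(numeric(wi), counts[seq_len(length(counts) - wi)])
  }
  target <- as.integer(round(2 * w))  # 2W is always an integer
  sum(counts[(target + 1L):(total + 1L)]) / 2^length(ranks)
}

normalSignedRankTail <- function(ranks, w, n) {
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(1)
  z <- (w - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Holm step-down adjustment
#'
#' Family-wise error controlling step-down adjustment: the sorted p-values are
#' multiplied by m, m-1, ..., 1, made monotone by the running maximum and
#' capped at 1.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' holmAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.04 0.04
#' @export
holmAdjust <- function(pValues) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "holm")
}

#' Pairwise significance matrix for one task
#'
#' Computes all p(p-1) one-sided paired Wilcoxon signed-rank tests
#' ("row algorithm superior to column algorithm"), applies Holm's adjustment
#' over that family, and thresholds at `alpha` to obtain the incidence of
#' significant superiority shown in significance maps.
#'
#' @inheritParams applyRanking
#' @param alpha significance level.
#' @return A [SignificanceMatrix-class] object.
#' @export
significanceMatrix <- function(slice, alpha = 0.05, largeBetter = TRUE,
                               task = "T1") {
  slice <- checkSlice(slice)
  if (nrow(slice) < 2L) stop("need at least 2 test cases")
  p <- ncol(slice)
  algs <- colnames(slice)
  raw <- matrix(NA_real_, p, p, dimnames = list(algs, algs))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    raw[i, j] <- as.numeric(
      wilcoxonOneSided(slice[, i], slice[, j], largeBetter = largeBetter))
  }
  off <- row(raw) != col(raw)
  adj <- raw
  adj[off] <- holmAdjust(raw[off])
  inc <- adj <= alpha
  diag(inc) <- NA
  new("SignificanceMatrix", task = task, pValues = adj,
      incidence = inc, alpha = alpha)
}

#' Export a significance matrix to CSV
#'
#' Writes the Holm-adjusted one-sided p-values as a square table.
#'
#' @param x a [SignificanceMatrix-class] object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeSignificanceMatrix <- function(x, path) {
  stopifnot(is(x, "SignificanceMatrix"))
  utils::write.csv(as.data.frame(x@pValues), path, row.names = TRUE)
  invisible(path)
}
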