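alignRankVectors <- function(r1, r2) {
  if (is.null(names(r1)) || is.null(names(r2))) {
    if (length(r1) != length(r2))
      stop("rank vectors must cover the same algorithm set")
    return(list(r1 = as.numeric(r1), r2 = as.numeric(r2)))
  }
  if (!setequal(names(r1), names(r2)))
    stop("rank vectors must cover the same algorithm set; mismatch: ",
         paste(union(setdiff(names(r1), names(r2)),
                     setdiff(names(r2), names(r1))), collapse = ", "))
  nm <- names(r1)
  list(r1 = as.numeric(r1), r2 = as.numeric(r2[nm]))
}

#' Kendall's tau between two ranking lists
#'
#' Rank correlation from pairwise concordances and discordances: 1 for
#' identical order, -1 for inverted order. The tie-corrected tau-b variant is
#' used since challenge rankings frequently contain ties. When either vector
#' is completely tied the coefficient is undefined and `NA` is returned with
#' a warning.
#'
#' @param r1,r2 rank vectors over the same algorithm set (aligned by names
#'   when named, by position otherwise). [Ranking-class] objects are accepted.
#' @return tau in \[-1, 1\], or `NA` when undefined.
#' @examples
#' kendallsTau(1:5, 1:5)   #  1
#' kendallsTau(1:5, 5:1)   # -1
#' @export
kendallsTau <- function(r1, r2) {
  if (is(r1, "Ranking")) r1 <- ranks(r1)
  if (is(r2, "Ranking")) r2 <- ranks(r2)
  a <- alignRankVectors(r1, r2)
  if (length(a$r1) < 2L) stop("need at least 2 algorithms")
  if (stats::var(a$r1) == 0 || stats::var(a$r2) == 0) {
    warning("Kendall's tau undefined for a completely tied ranking")
    return(NA_real_)
  }
  tauB(a$r1, a$r2)
}

# tau-b from explicit concordance/discordance counts; exact (no sqrt noise)
# at the boundary values -1 and 1.
tauB <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2L)
  dx <- sign(x[ij[1L, ]] - x[ij[2L, ]])
  dy <- sign(y[ij[1L, ]] - y[ij[2L, ]])
  s <- sum(dx * dy)
  n0 <- n * (n - 1) / 2
  tiePairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tiePairs(x)
  n2 <- tiePairs(y)
  denom2 <- (n0 - n1) * (n0 - n2)
  if (abs(s) == n0 - n1 && n1 == n2 && s != 0) return(sign(s))  # exact bounds
  s / sqrt(denom2)
}

#' Spearman's footrule distance
#'
#' Sum of the absolute rank differences between two ranking lists; 0 for
#' complete concordance, increasing with discrepancy.
#'
#' @inheritParams kendallsTau
#' @return Nonnegative numeric distance.
#' @examples
#' spearmanFootrule(c(1, 2, 3), c(3, 2, 1))  # 4
#' @export
spearmanFootrule <- function(r1, r2) {
  if (is(r1, "Ranking")) r1 <- ranks(r1)
  if (is(r2, "Ranking")) r2 <- ranks(r2)
  a <- alignRankVectors(r1, r2)
  sum(abs(a$r1 - a$r2))
}

#' Spearman's distance
#'
#' Sum of the squared rank differences between two ranking lists (closely
#' related to the squared Euclidean distance between rank vectors).
#'
#' @inheritParams kendallsTau
#' @return Nonnegative numeric distance.
#' @examples
#' spearmanDistance(c(1, 2, 3), c(3, 2, 1))  # 8
#' @export
spearmanDistance <- function(r1, r2) {
  if (is(r1, "Ranking")) r1 <- ranks(r1)
  if (is(r2, "Ranking")) r2 <- ranks(r2)
  a <- alignRankVectors(r1, r2)
  sum((a$r1 - a$r2)^2)
}

# per-task rankings (list of Ranking or named rank vectors, or a matrix
# tasks x algorithms) -> tasks x algorithms rank matrix
asRankMatrix <- function(perTask) {
  if (is.matrix(perTask)) {
    m <- perTask
    if (is.null(colnames(m))) colnames(m) <- paste0("A", seq_len(ncol(m)))
    if (is.null(rownames(m))) rownames(m) <- paste0("T", seq_len(nrow(m)))
    return(m)
  }
  stopifnot(is.list(perTask), length(perTask) >= 1L)
  vecs <- lapply(perTask, function(x) if (is(x, "Ranking")) ranks(x) else x)
  nms <- lapply(vecs, names)
  if (any(vapply(nms, is.null, logical(1L)))) {
    len <- unique(vapply(vecs, length, integer(1L)))
    if (length(len) != 1L)
      stop("rank vectors differ in length and are unnamed")
    vecs <- lapply(vecs, function(v)
      stats::setNames(as.numeric(v), paste0("A", seq_along(v))))
    nms <- lapply(vecs, names)
  }
  ref <- nms[[1L]]
  bad <- !vapply(nms, setequal, logical(1L), y = ref)
  if (any(bad)) {
    odd <- unique(unlist(lapply(nms[bad], function(n)
      union(setdiff(n, ref), setdiff(ref, n)))))
    stop("algorithm sets differ across tasks; asymmetric: ",
         paste(odd, collapse = ", "))
  }
  m <- do.call(rbind, lapply(vecs, function(v) as.numeric(v[ref])))
  colnames(m) <- ref
  taskNames <- names(perTask)
  rownames(m) <- if (!is.null(taskNames) && all(nzchar(taskNames))) taskNames
                 else vapply(seq_along(perTask), function(i) {
                   x <- perTask[[i]]
                   if (is(x, "Ranking") && nzchar(x@task)) x@task
                   else paste0("T", i)
                 }, character(1L))
  m
}

# convert each row (task) to the average-rank tie convention
averageTieRankMatrix <- function(rankMat) {
  if (ncol(rankMat) == 1L) {
    rankMat[] <- 1
    return(rankMat)
  }
  out <- t(apply(rankMat, 1L, rank, ties.method = "average"))
  dimnames(out) <- dimnames(rankMat)
  out
}

#' Cross-task consensus ranking
#'
#' Aggregates the per-task rankings of a multi-task challenge into one
#' consensus ranking. Each task contributes equally, independent of its
#' sample size or stability. Two methods are offered:
#' \describe{
#'   \item{`"meanRank"`}{per-task ranks are converted to the average-rank tie
#'     convention, averaged across tasks per algorithm, and the averages are
#'     min-tie ranked. This is the special case of distance-minimizing
#'     consensus under Spearman's distance.}
#'   \item{`"distance"`}{searches for the tie-free ordering minimizing the sum
#'     of rank distances (`"spearman"` or `"footrule"`) to the per-task
#'     rankings: exhaustively over all permutations for up to 8 algorithms,
#'     by mean-rank initialization plus local pairwise-swap descent beyond.
#'     When several orderings tie, the lexicographically smallest rank vector
#'     is reported.}
#' }
#'
#' @param perTask list of [Ranking-class] objects or named rank vectors (one
#'   per task, identical algorithm sets), or a tasks x algorithms rank matrix.
#' @param method `"meanRank"` (default) or `"distance"`.
#' @param distance rank distance for `method = "distance"`.
#' @return A [ConsensusResult-class] object.
#' @examples
#' consensusRank(rbind(c(1, 2, 3), c(1, 3, 2)))
#' @export
consensusRank <- function(perTask, method = c("meanRank", "distance"),
                          distance = c("spearman", "footrule")) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  rankMat <- averageTieRankMatrix(asRankMatrix(perTask))
  meanRanks <- colMeans(rankMat)
  if (method == "meanRank") {
    cons <- rankWithTies(meanRanks, largeBetter = FALSE, tie = "min")
    names(cons) <- colnames(rankMat)
  } else {
    cons <- distanceConsensus(rankMat, distance)
  }
  new("ConsensusResult", rankMatrix = rankMat, meanRanks = meanRanks,
      consensusRanks = cons, method = method,
      distance = if (method == "distance") distance else "")
}

distFun <- function(distance) {
  switch(distance,
         spearman = function(a, b) sum((a - b)^2),
         footrule = function(a, b) sum(abs(a - b)))
}

consensusObjective <- function(candidate, rankMat, df) {
  sum(apply(rankMat, 1L, df, b = candidate))
}

distanceConsensus <- function(rankMat, distance) {
  p <- ncol(rankMat)
  df <- distFun(distance)
  if (p <= 8L) {
    perms <- permutations(p)
    obj <- apply(perms, 1L, consensusObjective, rankMat = rankMat, df = df)
    best <- which(obj == min(obj))
    # lexicographically smallest rank vector among the minimizers
    cand <- perms[best, , drop = FALSE]
    ord <- do.call(order, as.data.frame(cand))
    res <- cand[ord[1L], ]
  } else {
    res <- rank(colMeans(rankMat), ties.method = "first")
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      cur <- consensusObjective(res, rankMat, df)
      for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
        cand <- res
        cand[c(i, j)] <- cand[c(j, i)]
        if (consensusObjective(cand, rankMat, df) < cur) {
          res <- cand
          improved <- TRUE
          cur <- consensusObjective(res, rankMat, df)
        }
      }
    }
  }
  stats::setNames(as.numeric(res), colnames(rankMat))
}

# all permutations of 1..n as an n! x n matrix, lexicographic order
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Export a consensus ranking to CSV
#'
#' Writes algorithm, mean rank and consensus rank plus one rank column per
#' task.
#'
#' @param x a [ConsensusResult-class] object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeConsensus <- function(x, path) {
  stopifnot(is(x, "ConsensusResult"))
  ord <- order(x@consensusRanks, names(x@consensusRanks))
  d <- data.frame(algorithm = colnames(x@rankMatrix)[ord],
                  meanRank = unname(x@meanRanks)[ord],
                  consensusRank = unname(x@consensusRanks)[ord])
  perTask <- t(x@rankMatrix)[ord, , drop = FALSE]
  colnames(perTask) <- paste0("rank.", colnames(perTask))
  utils::write.csv(cbind(d, as.data.frame(perTask)), path, row.names = FALSE)
  invisible(path)
}
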