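# shared fixtures and independent oracles

# cases x algorithms slice from per-algorithm value vectors
makeSlice <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  m
}

# brute-force one-sided signed-rank p-value by full enumeration of the 2^n
# sign assignments (independent oracle; n <= ~15)
enumSignedRankP <- function(x, y, largeBetter = TRUE) {
  d <- if (largeBetter) x - y else y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mean(ws >= w - 1e-9)
}

# random long-format records for a single task
randomRecords <- function(n = 8, p = 3, seed = 1) {
  set.seed(seed)
  data.frame(task = "T1",
             algorithm = rep(paste0("A", seq_len(p)), each = n),
             case = rep(paste0("c", seq_len(n)), times = p),
             value = round(runif(n * p), 3),
             stringsAsFactors = FALSE)
}

idealSlice <- function(n = 50, seed = 1) {
  taskSlice(imputeMissing(generateIdeal(n, seed)))
}

randomSlice <- function(seed = 1) {
  taskSlice(imputeMissing(generateRandom(seed)))
}
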