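#' @importFrom rlang .data
NULL

figureKinds <- c("dotbox", "podium", "heatmap", "line", "blob", "violin",
                 "significance_map", "dendrogram", "network")

#' Render a challenge figure
#'
#' Renders the computed data of one figure kind to an image file. Computation
#' and rendering are separated: every plottable quantity comes from one of
#' the `*Data` functions (or a [SignificanceMatrix-class] /
#' [BootstrapResult-class]) and can be unit-tested without graphics.
#' Rendering is deterministic given the data, the seed and the style options.
#'
#' Supported kinds and their expected `data`:
#' \describe{
#'   \item{`dotbox`}{cases x algorithms matrix; box plots with horizontally
#'     jittered dots (seeded jitter).}
#'   \item{`podium`}{a [podiumData()] result; dots on podium places connected
#'     per test case ("spaghetti"), with the place-frequency bar chart
#'     underneath. Refuses more than 30 algorithms and suggests truncating to
#'     a top list.}
#'   \item{`heatmap`}{a [heatmapCounts()] matrix.}
#'   \item{`line`}{a [linePlotData()] data frame.}
#'   \item{`blob`}{a [blobData()] result (or a [BootstrapResult-class], whose
#'     rank frequencies are used); blob area proportional to rank frequency,
#'     median marked by a cross, percentile interval by a line.}
#'   \item{`violin`}{numeric vector of Kendall's tau values (the
#'     [tauToFull()] output), or a named list of such vectors (one violin per
#'     task); undefined (`NA`) entries are dropped.}
#'   \item{`significance_map`}{a [SignificanceMatrix-class]; yellow = row
#'     algorithm significantly superior to column algorithm, blue = not.}
#'   \item{`dendrogram`}{a [dendrogramData()] result.}
#'   \item{`network`}{a [networkData()] result; node positions via a
#'     force-directed layout honoring the exponential edge lengths, nodes
#'     colored by unique task winners.}
#' }
#'
#' @param kind one of `"dotbox"`, `"podium"`, `"heatmap"`, `"line"`,
#'   `"blob"`, `"violin"`, `"significance_map"`, `"dendrogram"`, `"network"`.
#' @param data computed figure data (see Details).
#' @param path output file; extension `.png` or `.svg` selects the device.
#' @param width,height device size in inches.
#' @param seed seed for jitter and layout randomness.
#' @param order optional character vector fixing the algorithm order on the
#'   axes (typically the selected or consensus ranking order).
#' @param top optional integer; truncate the displayed algorithms to the
#'   first `top` of `order`.
#' @param ... unused style extensions.
#' @return The path, invisibly.
#' @export
renderFigure <- function(kind, data, path, width = 7, height = 5, seed = 1L,
                         order = NULL, top = NULL, ...) {
  if (!kind %in% figureKinds)
    stop("unknown figure kind: ", kind, " (expected one of ",
         paste(figureKinds, collapse = ", "), ")")
  builder <- switch(kind,
    dotbox = buildDotBox,
    podium = buildPodium,
    heatmap = buildHeatmap,
    line = buildLine,
    blob = buildBlob,
    violin = buildViolin,
    significance_map = buildSignificanceMap,
    dendrogram = buildDendrogram,
    network = buildNetwork)
  obj <- builder(data, seed = seed, order = order, top = top)
  writeFigure(obj, path, width = width, height = height)
  invisible(path)
}

writeFigure <- function(obj, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg"))
    stop("unsupported output format: ", ext, " (use png or svg)")
  if (inherits(obj, "gg") || inherits(obj, "ggplot")) {
    ggplot2::ggsave(path, plot = obj, width = width, height = height,
                    dpi = 150, device = ext)
  } else if (is.function(obj)) {
    if (ext == "png") grDevices::png(path, width = width, height = height,
                                     units = "in", res = 150)
    else grDevices::svg(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    obj()
  } else stop("internal: unrenderable object")
  invisible(path)
}

truncAlgorithms <- function(algs, order, top) {
  if (!is.null(order)) algs <- intersect(order, algs)
  if (!is.null(top)) algs <- utils::head(algs, top)
  algs
}

sliceToLong <- function(slice) {
  data.frame(case = rep(rownames(slice), times = ncol(slice)),
             algorithm = rep(colnames(slice), each = nrow(slice)),
             value = as.vector(slice), stringsAsFactors = FALSE)
}

buildDotBox <- function(data, seed = 1L, order = NULL, top = NULL) {
  slice <- checkSlice(data)
  algs <- truncAlgorithms(colnames(slice), order, top)
  d <- sliceToLong(slice[, algs, drop = FALSE])
  d$algorithm <- factor(d$algorithm, levels = algs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$algorithm, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_point(
      position = ggplot2::position_jitter(width = 0.2, height = 0,
                                          seed = seed),
      alpha = 0.5, size = 1, color = "steelblue") +
    ggplot2::labs(x = NULL, y = "metric value") +
    ggplot2::theme_minimal()
}

buildPodium <- function(data, seed = 1L, order = NULL, top = NULL) {
  stopifnot(inherits(data, "podiumData"))
  p <- ncol(data$places)
  if (p > 30)
    stop("podium plots with more than 30 algorithms are unreadable; ",
         "truncate to a top list (see the 'top' argument of runReport)")
  places <- data$places
  vals <- data$values
  algs <- colnames(places)
  n <- nrow(places)
  off <- (match(rep(algs, each = n), algs) - (p + 1) / 2) / (p + 1) * 0.8
  d <- data.frame(case = rep(rownames(places), times = p),
                  algorithm = rep(algs, each = n),
                  place = as.vector(places), value = as.vector(vals))
  d$x <- d$place + off
  upper <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value,
                                           color = .data$algorithm)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$case), color = "grey70",
                       linewidth = 0.2) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq_len(p),
                                labels = as.character(seq_len(p))) +
    ggplot2::labs(x = "podium place", y = "metric value") +
    ggplot2::theme_minimal()
  fr <- data$frequencies
  fd <- data.frame(algorithm = rep(rownames(fr), times = ncol(fr)),
                   place = rep(as.integer(colnames(fr)), each = nrow(fr)),
                   freq = as.vector(fr))
  lower <- ggplot2::ggplot(fd, ggplot2::aes(x = .data$place, y = .data$freq,
                                            fill = .data$algorithm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = seq_len(p)) +
    ggplot2::labs(x = "podium place", y = "frequency") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(upper, lower, ncol = 1L, heights = c(2, 1),
                          guides = "collect")
  } else upper
}

#' @importFrom ggplot2 ggplot
NULL

buildHeatmap <- function(data, seed = 1L, order = NULL, top = NULL) {
  stopifnot(is.matrix(data))
  algs <- truncAlgorithms(colnames(data), order, top)
  m <- data[, algs, drop = FALSE]
  d <- data.frame(rank = rep(as.integer(rownames(m)), times = ncol(m)),
                  algorithm = rep(colnames(m), each = nrow(m)),
                  count = as.vector(m))
  d$algorithm <- factor(d$algorithm, levels = algs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$algorithm, y = .data$rank,
                                  fill = .data$count)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_y_reverse(breaks = unique(d$rank)) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::labs(x = NULL, y = "rank per test case") +
    ggplot2::theme_minimal()
}

buildLine <- function(data, seed = 1L, order = NULL, top = NULL) {
  stopifnot(is.data.frame(data),
            all(c("method", "algorithm", "rank") %in% names(data)))
  d <- data
  if (!is.null(order) || !is.null(top)) {
    algs <- truncAlgorithms(unique(d$algorithm), order, top)
    d <- d[d$algorithm %in% algs, , drop = FALSE]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$rank,
                                  group = .data$algorithm,
                                  color = .data$algorithm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_reverse(breaks = sort(unique(d$rank))) +
    ggplot2::labs(x = "ranking method", y = "rank") +
    ggplot2::theme_minimal()
}

buildBlob <- function(data, seed = 1L, order = NULL, top = NULL) {
  if (is(data, "BootstrapResult")) {
    samples <- lapply(seq_len(ncol(data@replicates)),
                      function(j) data@replicates[, j])
    names(samples) <- colnames(data@replicates)
    data <- blobData(samples, level = data@level)
  }
  stopifnot(is.list(data), all(c("frequencies", "summary") %in% names(data)))
  fr <- data$frequencies
  sm <- data$summary
  groups <- truncAlgorithms(unique(fr$group), order, top)
  fr <- fr[fr$group %in% groups, , drop = FALSE]
  sm <- sm[sm$group %in% groups, , drop = FALSE]
  fr$group <- factor(fr$group, levels = groups)
  sm$group <- factor(sm$group, levels = groups)
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$group, y = .data$rank)) +
    ggplot2::geom_linerange(data = sm,
                            ggplot2::aes(x = .data$group, y = NULL,
                                         ymin = .data$lower,
                                         ymax = .data$upper),
                            color = "black") +
    ggplot2::geom_point(ggplot2::aes(size = .data$freq,
                                     color = .data$group),
                        alpha = 0.7) +
    ggplot2::geom_point(data = sm,
                        ggplot2::aes(x = .data$group, y = .data$median),
                        shape = 4, size = 3, color = "black") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::scale_y_reverse(breaks = sort(unique(fr$rank))) +
    ggplot2::guides(color = "none") +
    ggplot2::labs(x = NULL, y = "rank", size = "frequency") +
    ggplot2::theme_minimal()
}

buildViolin <- function(data, seed = 1L, order = NULL, top = NULL) {
  if (is.numeric(data)) data <- list(task = data)
  stopifnot(is.list(data))
  d <- do.call(rbind, lapply(names(data), function(g) {
    tau <- data[[g]]
    tau <- tau[!is.na(tau)]
    if (!length(tau)) return(NULL)
    data.frame(group = g, tau = tau, stringsAsFactors = FALSE)
  }))
  if (is.null(d)) stop("no defined tau values to plot")
  med <- vapply(split(d$tau, d$group), stats::median, numeric(1L))
  d$group <- factor(d$group, levels = names(sort(-med)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$tau)) +
    ggplot2::geom_violin(fill = "lightsteelblue", scale = "width") +
    ggplot2::geom_boxplot(width = 0.1, outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Kendall's tau to full-data ranking") +
    ggplot2::theme_minimal()
}

buildSignificanceMap <- function(data, seed = 1L, order = NULL, top = NULL) {
  stopifnot(is(data, "SignificanceMatrix"))
  inc <- data@incidence
  algs <- truncAlgorithms(colnames(inc), order, top)
  inc <- inc[algs, algs, drop = FALSE]
  d <- data.frame(superior = rep(rownames(inc), times = ncol(inc)),
                  over = rep(colnames(inc), each = nrow(inc)),
                  significant = as.vector(inc))
  d <- d[!is.na(d$significant), , drop = FALSE]
  d$superior <- factor(d$superior, levels = algs)
  d$over <- factor(d$over, levels = rev(algs))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$superior, y = .data$over,
                                  fill = .data$significant)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "gold", `FALSE` = "navy"),
                               name = "significantly superior") +
    ggplot2::labs(x = "algorithm (superior?)", y = "compared against") +
    ggplot2::theme_minimal()
}

buildDendrogram <- function(data, seed = 1L, order = NULL, top = NULL) {
  stopifnot(is.list(data), "tree" %in% names(data))
  tree <- data$tree
  function() {
    # plot via dendrogram: plot.hclust rejects trees with only two leaves
    graphics::plot(stats::as.dendrogram(tree),
                   main = "Task clustering by ranking distance",
                   ylab = "distance")
  }
}

buildNetwork <- function(data, seed = 1L, order = NULL, top = NULL) {
  stopifnot(is.list(data), all(c("nodes", "edges") %in% names(data)))
  nodes <- data$nodes
  edges <- data$edges
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes$task)
  winners <- nodes$winner
  pal <- grDevices::hcl.colors(max(1L, length(unique(stats::na.omit(winners)))),
                               "Dark 3")
  cols <- rep("white", nrow(nodes))
  known <- !is.na(winners)
  cols[known] <- pal[as.integer(factor(winners[known]))]
  function() {
    set.seed(seed)
    layout <- igraph::layout_with_kk(g, weights = edges$length)
    igraph::plot.igraph(g, layout = layout, vertex.color = cols,
                        vertex.label.color = "black", vertex.size = 28,
                        edge.color = "grey60")
    if (any(known))
      graphics::legend("topleft", legend = unique(winners[known]),
                       pt.bg = pal[as.integer(factor(unique(winners[known])))],
                       pch = 21, title = "task winner", bty = "n")
  }
}
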