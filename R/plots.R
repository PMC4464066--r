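## Manhattan-style visualization of a targeted scan and network drawing.
## Three plot types share the y-axis -log10(p) and the blue/red coding of
## correlation sign; they differ in the x-axis:
##   type 1 - m/z, type 2 - retention time, type 3 - mean log10 intensity.

manhattan_xaxis <- c("1" = "mz", "2" = "rt", "3" = "mean_log_intensity")
manhattan_xlab  <- c("1" = "m/z", "2" = "retention time (s)",
                     "3" = "mean log10 intensity")

#' Manhattan plot of a targeted MWAS result
#'
#' One point per scanned feature at `-log10(p)`, colored blue for positive
#' and red for negative correlations. The x-axis is the feature m/z
#' (type 1), retention time (type 2) or mean log10 intensity (type 3). A
#' dashed horizontal line marks the BH significance cutoff — the largest
#' p-value with `q < alpha` — and is omitted when no feature is
#' significant.
#'
#' @param result an `mwas` fit (see [run_targeted_mwas()]) or one of its
#'   per-target result data frames.
#' @param plot_type 1, 2 or 3.
#' @param alpha FDR level for the threshold line (default: the fit's
#'   alpha, else 0.05).
#' @param path output file; `NULL` draws on the active device.
#' @param format `"pdf"` or `"svg"` (used when `path` is given).
#' @param target which target of a multi-target fit to plot.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, a list describing the rendered plot: `plot_type`,
#'   `x` source, `n_points`, `threshold` (the `-log10 p` cutoff, `NA` when
#'   no line was drawn) and `path`.
#' @export
plot_manhattan <- function(result, plot_type = 1, alpha = NULL, path = NULL,
                           format = c("pdf", "svg"), target = 1L, ...) {
  format <- match.arg(format)
  if (inherits(result, "mwas")) {
    if (is.null(alpha)) alpha <- result$alpha
    result <- result$results[[target]]
  }
  if (is.null(alpha)) alpha <- 0.05
  if (!is.data.frame(result) || nrow(result) == 0L)
    stop("result is empty; nothing to plot", call. = FALSE)
  if (!length(plot_type) == 1L || !plot_type %in% c(1, 2, 3))
    stop("plot_type must be 1, 2 or 3", call. = FALSE)
  key <- as.character(plot_type)
  ok <- !is.na(result$p)
  if (!any(ok)) stop("no defined p-values to plot", call. = FALSE)
  x <- result[[manhattan_xaxis[key]]][ok]
  y <- -log10(pmax(result$p[ok], 1e-300))
  col <- ifelse(result$r[ok] >= 0, "blue", "red")

  sig_p <- result$p[ok][!is.na(result$q[ok]) & result$q[ok] < alpha]
  threshold <- if (length(sig_p)) -log10(max(sig_p)) else NA_real_

  if (!is.null(path)) {
    if (format == "pdf") grDevices::pdf(path, width = 7, height = 5)
    else grDevices::svg(path, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(x, y, pch = 20, col = col,
                 xlab = manhattan_xlab[key],
                 ylab = expression(-log[10](italic(p))),
                 main = sprintf("Type %d Manhattan plot", plot_type), ...)
  if (!is.na(threshold)) graphics::abline(h = threshold, lty = 2)

  invisible(list(plot_type = as.integer(plot_type), x = manhattan_xaxis[[key]],
                 n_points = sum(ok), threshold = threshold, path = path))
}

#' @describeIn plot_manhattan `plot()` method for `mwas` fits.
#' @param x an `mwas` fit.
#' @export
plot.mwas <- function(x, plot_type = 1, target = 1L, path = NULL, ...) {
  plot_manhattan(x, plot_type = plot_type, alpha = x$alpha, path = path,
                 target = target, ...)
}

#' Draw an association network
#'
#' Force-directed (Fruchterman-Reingold) layout with a caller-supplied
#' seed, so the same network and seed always yield identical coordinates.
#' Seed metabolites are drawn as squares, recruited features as circles
#' shaded by depth; edges are blue for positive and red for negative
#' correlations, with width scaled by `|r|`.
#'
#' @param network an `assoc_network` with at least one node.
#' @param path output file; `NULL` draws on the active device.
#' @param format `"pdf"` or `"svg"`.
#' @param layout_seed integer seed for the layout (default 1).
#' @param ... further arguments passed to [igraph::plot.igraph()].
#' @return invisibly, a list with the layout coordinate matrix and `path`.
#' @export
plot_network <- function(network, path = NULL, format = c("pdf", "svg"),
                         layout_seed = 1L, ...) {
  stopifnot(inherits(network, "assoc_network"))
  format <- match.arg(format)
  if (nrow(network$nodes) == 0L) stop("network has no nodes", call. = FALSE)
  g <- as_igraph(network)
  set.seed(as.integer(layout_seed))
  coords <- igraph::layout_with_fr(g)
  if (!is.null(path)) {
    if (format == "pdf") grDevices::pdf(path, width = 7, height = 7)
    else grDevices::svg(path, width = 7, height = 7)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ecol <- if (igraph::ecount(g) > 0)
    ifelse(igraph::E(g)$weight >= 0, "blue", "red") else NULL
  ewid <- if (igraph::ecount(g) > 0) 0.5 + 2 * abs(igraph::E(g)$weight) else NULL
  vshape <- ifelse(network$nodes$is_seed, "square", "circle")
  vcol <- c("gold", "skyblue", "grey80")[network$nodes$depth + 1L]
  igraph::plot.igraph(g, layout = coords, vertex.shape = vshape,
                      vertex.color = vcol, vertex.size = 8,
                      vertex.label.cex = 0.5, edge.color = ecol,
                      edge.width = ewid, ...)
  invisible(list(layout = coords, path = path))
}

#' @export
plot.assoc_network <- function(x, ...) plot_network(x, ...)
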