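## GML export/import of association networks (Cytoscape-compatible),
## delegated to igraph's plain-GML reader/writer.

#' Convert an association network to an igraph graph
#'
#' Vertex attributes: `name`/`label` (feature id), `mz`, `rt`, `isseed`
#' (0/1), `depth`; edge attributes: `weight` (signed r), `qvalue`, `depth`.
#' Graph attributes record the construction method and thresholds.
#'
#' @param network an `assoc_network`.
#' @return an undirected [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "assoc_network"))
  g <- igraph::make_empty_graph(n = nrow(network$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = network$nodes$id)
  g <- igraph::set_vertex_attr(g, "label", value = network$nodes$id)
  g <- igraph::set_vertex_attr(g, "mz", value = network$nodes$mz)
  g <- igraph::set_vertex_attr(g, "rt", value = network$nodes$rt)
  g <- igraph::set_vertex_attr(g, "isseed", value = as.numeric(network$nodes$is_seed))
  g <- igraph::set_vertex_attr(g, "depth", value = as.numeric(network$nodes$depth))
  if (nrow(network$edges) > 0L) {
    ends <- rbind(match(network$edges$from, network$nodes$id),
                  match(network$edges$to, network$nodes$id))
    g <- igraph::add_edges(g, as.vector(ends))
    g <- igraph::set_edge_attr(g, "weight", value = network$edges$r)
    g <- igraph::set_edge_attr(g, "qvalue", value = network$edges$q)
    g <- igraph::set_edge_attr(g, "depth", value = as.numeric(network$edges$depth))
  }
  g <- igraph::set_graph_attr(g, "method", network$method)
  g <- igraph::set_graph_attr(g, "corr", network$corr)
  g <- igraph::set_graph_attr(g, "rmin", network$r_min)
  g <- igraph::set_graph_attr(g, "qmax", network$q_max)
  g
}

#' Write an association network as GML
#'
#' Plain Graph Modelling Language with integer node ids and the attributes
#' listed under [as_igraph()]; the file loads directly into Cytoscape and
#' parses back with [read_gml()] to an isomorphic graph.
#'
#' @param network an `assoc_network`.
#' @param path output path (conventionally `.gml`).
#' @return `path`, invisibly.
#' @export
write_gml <- function(network, path) {
  g <- as_igraph(network)
  ok <- tryCatch({ igraph::write_graph(g, path, format = "gml"); TRUE },
                 error = function(e) stop("cannot write GML to ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a GML network written by [write_gml()]
#'
#' @param path path to a GML file.
#' @return an `assoc_network` (thresholds restored from the graph
#'   attributes when present).
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "gml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(
    id = as.character(va$label),
    feature_index = seq_len(igraph::vcount(g)),
    mz = as.numeric(va$mz), rt = as.numeric(va$rt),
    is_seed = as.numeric(va$isseed) > 0,
    depth = as.integer(va$depth),
    stringsAsFactors = FALSE
  )
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g, names = FALSE)
    ea <- igraph::edge_attr(g)
    edges <- data.frame(
      from = nodes$id[el[, 1L]], to = nodes$id[el[, 2L]],
      r = as.numeric(ea$weight), q = as.numeric(ea$qvalue),
      depth = as.integer(ea$depth), stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(from = character(), to = character(), r = numeric(),
                        q = numeric(), depth = integer(), stringsAsFactors = FALSE)
  }
  ga <- igraph::graph_attr(g)
  new_assoc_network(nodes, edges,
                    method = if (!is.null(ga$method)) ga$method else "full",
                    corr = if (!is.null(ga$corr)) ga$corr else "unknown",
                    r_min = if (!is.null(ga$rmin)) ga$rmin else 0,
                    q_max = if (!is.null(ga$qmax)) ga$qmax else 1)
}
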