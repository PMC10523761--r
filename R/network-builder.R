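# Construction of the unspecific interaction network and its tissue-specific
# restriction. Networks are undirected simple igraph objects: no self-loops,
# no multi-edges, no isolated nodes.

cleanGraph <- function(g) {
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Build the unspecific interaction network
#'
#' Collapses an edge list (duplicates, reversed duplicates) into an
#' undirected simple graph, dropping self-loops; nodes are the endpoints of
#' the surviving edges, so the result has no isolated vertices.
#'
#' @param edges data.frame with columns `p1`, `p2` (see [readEdgeList()]),
#'   or a two-column character matrix.
#' @param label free-text label stored in the graph's `name` attribute.
#' @return an undirected simple `igraph` graph.
#' @examples
#' g <- buildNetwork(data.frame(p1 = c("A", "B", "A"), p2 = c("B", "A", "A")))
#' igraph::ecount(g)  # 1
#' @export
buildNetwork <- function(edges, label = "unspecific") {
  if (is.matrix(edges))
    edges <- data.frame(p1 = edges[, 1L], p2 = edges[, 2L])
  stopifnot(all(c("p1", "p2") %in% names(edges)))
  if (nrow(edges) == 0L)
    stop("empty edge list")
  g <- igraph::graph_from_data_frame(edges[, c("p1", "p2")],
                                     directed = FALSE)
  g <- cleanGraph(g)
  if (igraph::ecount(g) == 0L)
    stop("no edges survive cleaning (all pairs were self-loops)")
  g$name <- label
  g
}

#' Restrict a network to an expression universe
#'
#' Keeps only edges whose both endpoints lie in the universe (interactions
#' between expressed proteins), then re-cleans, dropping the proteins left
#' isolated. Idempotent, and monotone: shrinking the universe can only remove
#' nodes and edges.
#'
#' @param net an `igraph` network from [buildNetwork()].
#' @param universe character vector of expressed gene identifiers.
#' @param label label for the filtered network.
#' @return an undirected simple `igraph` graph.
#' @export
filterByUniverse <- function(net, universe, label = "tissue") {
  keep <- intersect(igraph::V(net)$name, universe)
  g <- cleanGraph(igraph::induced_subgraph(net, keep))
  if (igraph::ecount(g) == 0L)
    stop("no interaction between universe proteins survives the filter")
  g$name <- label
  g
}

#' Summarise a network
#'
#' @param net an `igraph` network.
#' @return list with `n_nodes`, `n_edges`, `n_components`, `degree_mean`,
#'   `degree_median` and `degree_max`.
#' @export
networkSummary <- function(net) {
  deg <- igraph::degree(net)
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       n_components = igraph::components(net)$no,
       degree_mean = if (length(deg)) mean(deg) else NA_real_,
       degree_median = if (length(deg)) stats::median(deg) else NA_real_,
       degree_max = if (length(deg)) max(deg) else NA_real_)
}
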