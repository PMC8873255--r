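#' Build the mobility ("cognitive") graph of a participant
#'
#' The full trace (all movements, alone and accompanied) is rasterized to
#' the grid; every occupied cell becomes a node and an undirected edge
#' connects two cells containing consecutive samples.  Each inter-sample
#' time interval accrues as dwell time to the cell of the interval's first
#' sample.  Cells merely crossed in transit are then filtered out: nodes
#' with dwell below `dwell_threshold` are removed one at a time in
#' ascending dwell order (ties broken by cell key for determinism), and on
#' each removal the node's current neighbours are pairwise connected so
#' that connectivity through the removed cell is preserved.  Self-loops
#' and parallel edges are discarded.
#'
#' @param trace A projected trace.
#' @param grid A [grid_spec()].
#' @param dwell_threshold Seconds of dwell required to keep a node
#'   (default 300).
#' @return An undirected simple [igraph::graph] with vertex attributes
#'   `name` (cell key) and `dwell` (seconds).
#' @export
build_graph <- function(trace, grid = grid_spec(), dwell_threshold = 300) {
  n <- nrow(trace$samples)
  if (n == 0) stop("empty trace")
  cells <- rasterize(trace$xy, grid)$cell
  dwell_tab <- if (n > 1) {
    tapply(diff(trace$samples$time), cells[-n], sum)
  } else NULL
  nodes <- sort(unique(cells))
  dwell <- stats::setNames(rep(0, length(nodes)), nodes)
  if (!is.null(dwell_tab)) dwell[names(dwell_tab)] <- dwell_tab
  adj <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  if (n > 1) {
    a <- cells[-n]; b <- cells[-1]
    keep <- a != b
    for (e in which(keep)) {
      adj[[a[e]]] <- union(adj[[a[e]]], b[e])
      adj[[b[e]]] <- union(adj[[b[e]]], a[e])
    }
  }
  adj <- remove_transit_nodes(adj, dwell, dwell_threshold)
  dwell <- dwell[names(adj)]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(names(adj), dwell = as.numeric(dwell))
  el <- do.call(rbind, lapply(names(adj), function(v) {
    to <- adj[[v]][adj[[v]] > v]
    if (length(to) == 0) NULL else cbind(v, to)
  }))
  if (!is.null(el) && nrow(el) > 0)
    g <- igraph::add_edges(g, t(el))
  g
}

# iteratively drop sub-threshold nodes in ascending dwell order (ties by
# name), pairwise connecting each removed node's current neighbours so that
# connectivity through the removed cell is preserved
remove_transit_nodes <- function(adj, dwell, dwell_threshold) {
  sub <- which(dwell < dwell_threshold)
  queue <- names(dwell)[sub][order(dwell[sub], names(dwell)[sub])]
  for (v in queue) {
    nb <- adj[[v]]
    for (u in nb) {
      adj[[u]] <- setdiff(union(adj[[u]], nb), c(u, v))
    }
    adj[[v]] <- NULL
  }
  adj
}

#' Hop-distance centralities of a mobility graph
#'
#' Closeness of a node is the reciprocal of the sum of its shortest-path
#' hop distances to the other nodes, computed within its connected
#' component and rescaled by the component's share of the graph
#' (Wasserman-Faust): \eqn{C(u) = \frac{k-1}{\sum_v d(u,v)} \cdot
#' \frac{k-1}{n-1}} for a component of size \eqn{k} in a graph of size
#' \eqn{n}.  Betweenness is the normalised fraction of shortest paths
#' passing through a node, and degree centrality the fraction of other
#' nodes it is connected to.
#'
#' @param graph An [igraph::graph] from [build_graph()].
#' @return A data frame with columns `node`, `closeness`, `betweenness`,
#'   `degree_centrality`, all in `[0, 1]`.
#' @export
centralities <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) stop("centralities need at least 2 nodes")
  comp <- igraph::components(graph)
  d <- igraph::distances(graph)
  clo <- vapply(seq_len(n), function(u) {
    k <- comp$csize[comp$membership[u]]
    if (k < 2) return(0)
    dv <- d[u, comp$membership == comp$membership[u]]
    ((k - 1) / sum(dv)) * ((k - 1) / (n - 1))
  }, numeric(1))
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = TRUE)
  deg <- igraph::degree(graph) / (n - 1)
  data.frame(node = igraph::V(graph)$name, closeness = clo,
             betweenness = as.numeric(btw),
             degree_centrality = as.numeric(deg),
             stringsAsFactors = FALSE)
}

#' Graph-topology feature block for a participant
#'
#' The number of nodes enters as a scalar; each centrality, being a
#' per-node quantity, is represented as a `bins`-bin normalised histogram
#' over `[0, 1]` (the same representation used for per-segment features).
#' Participants whose graphs have fewer than `min_nodes` nodes carry too
#' little topological signal and are excluded.
#'
#' @param graph An [igraph::graph] from [build_graph()].
#' @param bins Number of histogram bins (default 10).
#' @param min_nodes Minimum node count for inclusion (default 10).
#' @return A list with `node_count` and normalised histograms `closeness`,
#'   `betweenness`, `degree_centrality`, or `NULL` (with a message) when
#'   the graph is too small.
#' @export
graph_feature_vector <- function(graph, bins = 10, min_nodes = 10) {
  nc <- igraph::vcount(graph)
  if (nc < min_nodes) {
    message(sprintf("graph has %d < %d nodes; participant excluded from graph features",
                    nc, min_nodes))
    return(NULL)
  }
  tab <- centralities(graph)
  list(node_count = nc,
       closeness = make_histogram(tab$closeness, bins, c(0, 1)),
       betweenness = make_histogram(tab$betweenness, bins, c(0, 1)),
       degree_centrality = make_histogram(tab$degree_centrality, bins, c(0, 1)))
}
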