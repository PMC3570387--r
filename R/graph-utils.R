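# Internal directed-graph helpers shared across modules. Graphs are passed
# around as edge data.frames (parent, child, ...) over a character node set;
# igraph is used for the structural algorithms.

#' @importFrom igraph graph_from_data_frame is_dag topo_sort V
edgesToIgraph <- function(edges, nodes) {
  df <- data.frame(from = as.character(edges$parent),
                   to = as.character(edges$child),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = TRUE, vertices = nodes)
}

edgesAreAcyclic <- function(edges, nodes) {
  if (!nrow(edges)) return(TRUE)
  igraph::is_dag(edgesToIgraph(edges, nodes))
}

# Topological order of node names; errors on cycles.
topoOrder <- function(edges, nodes) {
  g <- edgesToIgraph(edges, nodes)
  if (!igraph::is_dag(g)) stop("graph contains a directed cycle")
  names(igraph::topo_sort(g, mode = "out"))
}

# Adjacency-matrix cycle test used inside the hill climb: would adding
# parent -> child create a cycle, i.e. is parent reachable from child?
# adj is a logical parent x child matrix.
reachableFrom <- function(adj, from, to) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    nxt <- which(adj[v, ] & !seen)
    if (length(nxt)) stack <- c(stack, nxt)
  }
  FALSE
}
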