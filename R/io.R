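# Plain-text interchange: TSV matrices (genes as rows, first column the
# gene identifier, header row of array identifiers), flag matrices of the
# same shape, target maps, 4-column truth edge lists, GMT gene sets and a
# GraphML export for network viewers.

#' Read and write expression/flag matrices as TSV
#'
#' The matrix format has a header row of array identifiers, gene
#' identifiers in the first column (named \code{gene}) and one column per
#' array. Flags use the same layout with values in \{Good, Bad\}.
#'
#' @param path file path.
#' @param values matrix with dimnames to write.
#' @return \code{readMatrixTSV()} returns a matrix with dimnames.
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname readMatrixTSV
#' @export
writeMatrixTSV <- function(values, path) {
  df <- data.frame(gene = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an array-to-target map (array_id, target_gene)
#' @param map named character vector (names = array ids).
#' @param path file path.
#' @return \code{readTargetMapTSV()} returns a named character vector.
#' @export
writeTargetMapTSV <- function(map, path) {
  utils::write.table(
    data.frame(array_id = names(map), target_gene = unname(map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTargetMapTSV
#' @export
readTargetMapTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$target_gene, df$array_id)
}

#' Read/write a network edge list as TSV
#'
#' Ground truths use 4 columns (parent, child, sign, weight); consensus
#' networks use (parent, child, frequency, sign). Any data.frame with a
#' parent and child column round-trips.
#'
#' @param edges data.frame of edges, or an object with [networkEdges()].
#' @param path file path.
#' @return \code{readEdgeListTSV()} returns the edge data.frame.
#' @export
writeEdgeListTSV <- function(edges, path) {
  utils::write.table(networkEdges(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeListTSV
#' @export
readEdgeListTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path path to a .gmt file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  sets
}

#' Export a network as GraphML
#'
#' Writes the directed network in GraphML so it can be opened in generic
#' graph viewers (Cytoscape, Gephi, yEd). Edge attributes present in the
#' edge table (frequency, sign, weight) are carried along.
#'
#' @param network a \linkS4class{ConsensusNetwork},
#'   \linkS4class{GroundTruthNetwork} or edge data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGraphML <- function(network, path) {
  ed <- networkEdges(network)
  nodes <- networkNodes(network)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$parent, to = ed$child,
               ed[setdiff(names(ed), c("parent", "child"))]),
    directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
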