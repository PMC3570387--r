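# Hub identification and validation: children counts, hub ranking, hub
# neighbourhoods, hub-child correlation across the disruptant panel,
# predicted knockdown directions, gene-set enrichment of hub children and
# recovery metrics against a planted truth.

#' Count distinct direct children of every node
#'
#' @param network a \linkS4class{ConsensusNetwork},
#'   \linkS4class{GroundTruthNetwork} or edge data.frame (parent, child);
#'   duplicate parent-child rows count once.
#' @param descendants if TRUE, count all distinct descendants instead of
#'   direct children only.
#' @return named integer vector over all nodes (0 for childless nodes).
#' @examples
#' ed <- data.frame(parent = c("H", "H", "H"), child = c("a", "b", "a"))
#' countChildren(ed)[["H"]]   # duplicate H->a counted once: 2
#' @export
countChildren <- function(network, descendants = FALSE) {
  ed <- unique(networkEdges(network)[, c("parent", "child")])
  nodes <- networkNodes(network)
  if (descendants) {
    g <- edgesToIgraph(ed, nodes)
    n <- vapply(nodes, function(v)
      length(igraph::subcomponent(g, v, mode = "out")) - 1L, integer(1))
    return(stats::setNames(as.integer(n), nodes))
  }
  tab <- table(factor(ed$parent, levels = nodes))
  stats::setNames(as.integer(tab), nodes)
}

#' Rank hub genes by number of children
#'
#' Sorts genes by distinct direct children (descending), assigning tied
#' genes the minimum rank of their tie group; within a tie the listing is
#' lexicographic for output stability. The table is truncated to the top
#' \code{topK} genes and/or those with at least \code{minChildren}
#' children.
#'
#' @inheritParams countChildren
#' @param topK keep at most this many genes (default 50).
#' @param minChildren keep only genes with at least this many children
#'   (default 1).
#' @return data.frame (gene, n_children, rank), sorted.
#' @examples
#' ed <- data.frame(parent = c("A", "A", "B", "C"), child = c("x", "y", "x", "y"))
#' rankHubs(ed, topK = 50)
#' @export
rankHubs <- function(network, topK = 50L, minChildren = 1L,
                     descendants = FALSE) {
  stopifnot(topK >= 1)
  cc <- countChildren(network, descendants)
  cc <- cc[cc >= minChildren]
  if (!length(cc))
    return(data.frame(gene = character(), n_children = integer(),
                      rank = integer()))
  ord <- order(-cc, names(cc))
  cc <- cc[ord]
  rk <- rank(-cc, ties.method = "min")
  head(data.frame(gene = names(cc), n_children = unname(cc),
                  rank = as.integer(rk), row.names = NULL), topK)
}

#' Extract the immediate neighbourhood of a hub
#'
#' Edge set restricted to edges incident to the given gene: its parents
#' and its children.
#'
#' @inheritParams countChildren
#' @param gene hub gene identifier.
#' @return list with \code{edges} (the incident edge rows),
#'   \code{parents}, \code{children}, and their counts.
#' @export
hubSubnetwork <- function(network, gene) {
  nodes <- networkNodes(network)
  if (!gene %in% nodes)
    stop(sprintf("gene '%s' is not in the network", gene))
  ed <- networkEdges(network)
  inc <- ed[ed$parent == gene | ed$child == gene, , drop = FALSE]
  parents <- sort(unique(inc$parent[inc$child == gene]))
  children <- sort(unique(inc$child[inc$parent == gene]))
  list(edges = inc, parents = parents, children = children,
       nParents = length(parents), nChildren = length(children))
}

#' Hub-child correlations across the disruptant panel
#'
#' Pearson correlation (the default; \code{method} is passed to
#' [stats::cor()]) between the hub's z-score row and each child's z-score
#' row across all arrays of the panel. A zero-variance row yields NA for
#' that child rather than an error.
#'
#' @param panel a \linkS4class{DisruptantPanel} or genes x arrays matrix.
#' @param hub hub gene identifier.
#' @param children character vector of child gene identifiers.
#' @param method correlation method (default \code{"pearson"}).
#' @return named numeric vector of correlations in [-1, 1] (NA where
#'   undefined).
#' @export
hubChildCorrelations <- function(panel, hub, children,
                                 method = "pearson") {
  z <- if (is(panel, "SummarizedExperiment")) assay(panel, "z") else panel
  miss <- setdiff(c(hub, children), rownames(z))
  if (length(miss))
    stop("gene(s) absent from the panel: ", paste(miss, collapse = ", "))
  hv <- z[hub, ]
  vapply(children, function(ch) {
    cv <- z[ch, ]
    if (stats::sd(hv) == 0 || stats::sd(cv) == 0) return(NA_real_)
    stats::cor(hv, cv, method = method)
  }, numeric(1))
}

#' Predicted direction of each child under hub knockdown
#'
#' A child positively correlated with the hub is predicted to go DOWN
#' when the hub is knocked down; a negatively correlated child to go UP;
#' zero or undefined correlation gives no call.
#'
#' @param correlations named numeric vector from
#'   [hubChildCorrelations()].
#' @return named character vector with values \code{"down"}, \code{"up"}
#'   or \code{"none"}.
#' @export
predictKnockdownDirection <- function(correlations) {
  out <- ifelse(is.na(correlations) | correlations == 0, "none",
                ifelse(correlations > 0, "down", "up"))
  stats::setNames(out, names(correlations))
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the actual overlap between the query genes and the
#' set, within the given universe (sets are intersected with the universe
#' first); Benjamini-Hochberg q-values are computed across sets. An
#' overlap of 0 has p = P(X >= 0) = 1.
#'
#' @param queryGenes character vector (must lie within the universe).
#' @param geneSets named list of character vectors (e.g. from
#'   [readGMT()]).
#' @param universe character vector of all eligible genes.
#' @return data.frame (gene_set_name, overlap_count, set_size, p_value,
#'   q_value), one row per set, in input order.
#' @examples
#' hypergeometricEnrichment(letters[1:5],
#'   list(s = letters[1:5]), letters[1:20])
#' @export
hypergeometricEnrichment <- function(queryGenes, geneSets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must not be empty")
  queryGenes <- unique(queryGenes)
  bad <- setdiff(queryGenes, universe)
  if (length(bad))
    stop("query gene(s) outside the universe: ", paste(bad, collapse = ", "))
  N <- length(universe)
  n <- length(queryGenes)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, queryGenes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(gene_set_name = nm, overlap_count = k, set_size = K,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Histogram of children counts across all nodes
#'
#' Tabulates how many nodes have each number of distinct direct
#' children — the degree distribution summary usually shown alongside a
#' hub table. Write it out with [writeEdgeListTSV()]-style tools or plot
#' it directly.
#'
#' @inheritParams countChildren
#' @return data.frame (n_children, frequency) sorted by n_children.
#' @export
childrenCountHistogram <- function(network, descendants = FALSE) {
  cc <- countChildren(network, descendants)
  tab <- table(cc)
  data.frame(n_children = as.integer(names(tab)),
             frequency = as.integer(tab), row.names = NULL)
}

#' Directed-edge recovery against a planted truth
#'
#' @param inferred,truth networks or edge data.frames over the same gene
#'   universe; duplicate edges are deduplicated.
#' @return list with \code{precision} (0 when nothing inferred),
#'   \code{recall}, \code{f1} (0 when both are 0), and the raw counts.
#' @export
edgeRecovery <- function(inferred, truth) {
  key <- function(x) {
    ed <- unique(networkEdges(x)[, c("parent", "child")])
    paste(ed$parent, ed$child, sep = "\r")
  }
  inf <- key(inferred); tru <- key(truth)
  tp <- length(intersect(inf, tru))
  precision <- if (length(inf)) tp / length(inf) else 0
  recall <- if (length(tru)) tp / length(tru) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       nInferred = length(inf), nTruth = length(tru), nCorrect = tp)
}

#' Rank of each planted hub in the children-count ranking
#'
#' @param hubTable data.frame from [rankHubs()] (use \code{topK = Inf} to
#'   rank every node).
#' @param plantedHubs character vector of planted hub identifiers.
#' @return named numeric vector of ranks; hubs absent from the table get
#'   \code{Inf}.
#' @export
hubRecoveryRank <- function(hubTable, plantedHubs) {
  r <- hubTable$rank[match(plantedHubs, hubTable$gene)]
  r[is.na(r)] <- Inf
  stats::setNames(as.numeric(r), plantedHubs)
}
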