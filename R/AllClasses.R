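#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Planted ground-truth regulatory network
#'
#' A signed, weighted directed acyclic graph over a set of genes, with a
#' designated subset of hub genes wired to a prescribed number of direct
#' children. Used as the evaluation reference for synthetic pipeline runs:
#' the generator simulates expression data from it and the inference stages
#' are scored against it.
#'
#' @slot genes character vector of gene identifiers (unique).
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{sign} (+1/-1) and \code{weight} (> 0); one row per directed edge.
#' @slot hubs character vector naming the designated hub genes.
#'
#' @seealso [makeGroundTruth()], [edgeRecovery()], [hubRecoveryRank()]
#' @export
setClass("GroundTruthNetwork",
  representation(genes = "character", edges = "data.frame",
                 hubs = "character"))

setValidity("GroundTruthNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("parent", "child", "sign", "weight")
  if (!all(need %in% names(ed)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene identifiers must be unique")
  if (nrow(ed)) {
    if (!all(ed$parent %in% object@genes) || !all(ed$child %in% object@genes))
      msg <- c(msg, "edge endpoints must be listed in genes")
    if (any(ed$parent == ed$child))
      msg <- c(msg, "self-edges are not allowed")
    if (!all(ed$sign %in% c(-1, 1)))
      msg <- c(msg, "edge signs must be +1 or -1")
    if (!all(ed$weight > 0))
      msg <- c(msg, "edge weights must be positive")
    if (anyDuplicated(ed[, c("parent", "child")]))
      msg <- c(msg, "duplicate edges are not allowed")
    if (!edgesAreAcyclic(ed, object@genes))
      msg <- c(msg, "network must be a DAG (directed cycle found)")
  }
  if (!all(object@hubs %in% object@genes))
    msg <- c(msg, "hubs must be a subset of genes")
  if (length(msg)) msg else TRUE
})

#' Replicated time-course expression experiment
#'
#' A \linkS4class{SummarizedExperiment} whose columns are individual arrays
#' of a replicated time course; \code{colData} carries \code{replicate}
#' (integer) and \code{hours} (numeric time after the stimulus). The single
#' assay \code{"log2"} holds log2-scale expression, genes in rows.
#'
#' @seealso [TimecourseExperiment()], [timecourseCube()],
#'   [simulateTimecourse()]
#' @export
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
  cd <- colData(object)
  if (!all(c("replicate", "hours") %in% names(cd)))
    return("colData must contain 'replicate' and 'hours'")
  tab <- table(cd$replicate, cd$hours)
  if (any(tab != 1))
    return("each (replicate, hours) combination must appear exactly once")
  if (is.null(rownames(object)))
    return("gene identifiers (rownames) are required")
  TRUE
})

#' siRNA disruptant panel
#'
#' A \linkS4class{SummarizedExperiment} holding one array per gene
#' knockdown. \code{colData$target} names the gene targeted on each array.
#' The assay \code{"z"} holds within-array z-scores of log2 ratios against
#' a virtual median array (see [toZPanel()]); an optional assay
#' \code{"log2"} may carry the pre-transformation values.
#'
#' @seealso [DisruptantPanel()], [toZPanel()], [simulateDisruptants()]
#' @export
setClass("DisruptantPanel", contains = "SummarizedExperiment")

setValidity("DisruptantPanel", function(object) {
  cd <- colData(object)
  if (!"target" %in% names(cd))
    return("colData must contain 'target' (gene knocked down on each array)")
  if (is.null(rownames(object)))
    return("gene identifiers (rownames) are required")
  if (!"z" %in% SummarizedExperiment::assayNames(object))
    return("assay 'z' (within-array z-scores) is required")
  z <- SummarizedExperiment::assay(object, "z")
  mu <- colMeans(z)
  sdv <- apply(z, 2, stats::sd)
  if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9))
    return("each array's z-scores must have mean 0 and sd 1 (tol 1e-9)")
  TRUE
})

#' Bootstrap edge-confidence matrix
#'
#' Dense parent-by-child matrix of bootstrap probabilities: entry (i, j) is
#' the fraction of bootstrap-estimated networks containing the edge
#' i -> j. Entries are exact multiples of 1/\code{n_bootstrap}; the
#' diagonal is zero (no self-edges).
#'
#' @slot matrix numeric parent x child matrix in [0, 1], dimnames = genes.
#' @slot n_bootstrap integer, number of bootstrap networks summarized.
#' @slot provenance either \code{"time_prior"} or \code{"static_consensus"}.
#'
#' @seealso [timePrior()], [edgeConfidence()]
#' @export
setClass("EdgeConfidence",
  representation(matrix = "matrix", n_bootstrap = "integer",
                 provenance = "character"))

setValidity("EdgeConfidence", function(object) {
  m <- object@matrix
  nb <- object@n_bootstrap
  if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m)))
    return("matrix must be square with identical row/column gene names")
  if (any(m < 0 | m > 1)) return("entries must lie in [0, 1]")
  if (any(diag(m) != 0)) return("diagonal (self-edges) must be zero")
  if (length(nb) != 1L || nb < 1L) return("n_bootstrap must be a count >= 1")
  if (max(abs(m * nb - round(m * nb))) > 1e-9)
    return("entries must be exact multiples of 1/n_bootstrap")
  if (!object@provenance %in% c("time_prior", "static_consensus"))
    return("provenance must be 'time_prior' or 'static_consensus'")
  TRUE
})

#' Consensus network from bootstrap structure searches
#'
#' Directed network keeping, for every edge observed across bootstrap
#' structure searches, its occurrence frequency and a correlation-derived
#' sign. Each underlying per-bootstrap graph is a DAG, but the consensus
#' union need not be.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{frequency} in [0, 1] and \code{sign} in \{-1, 0, +1\}.
#' @slot n_bootstraps integer number of bootstrap searches summarized.
#'
#' @seealso [bootstrapStaticNetwork()], [countChildren()], [rankHubs()]
#' @export
setClass("ConsensusNetwork",
  representation(nodes = "character", edges = "data.frame",
                 n_bootstraps = "integer"))

setValidity("ConsensusNetwork", function(object) {
  ed <- object@edges
  need <- c("parent", "child", "frequency", "sign")
  if (!all(need %in% names(ed)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(ed)) {
    if (!all(ed$parent %in% object@nodes) || !all(ed$child %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed nodes")
    if (any(ed$parent == ed$child)) msg <- c(msg, "no self-edges allowed")
    if (any(ed$frequency < 0 | ed$frequency > 1))
      msg <- c(msg, "frequencies must lie in [0, 1]")
    nb <- object@n_bootstraps
    if (max(abs(ed$frequency * nb - round(ed$frequency * nb))) > 1e-9)
      msg <- c(msg, "frequencies must be multiples of 1/n_bootstraps")
    if (!all(ed$sign %in% c(-1, 0, 1)))
      msg <- c(msg, "edge signs must be -1, 0 or +1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf("GroundTruthNetwork: %d genes, %d signed edges, %d hub(s)\n",
              length(object@genes), nrow(object@edges), length(object@hubs)))
  if (length(object@hubs)) {
    cc <- countChildren(object)
    cat("  hubs:",
        paste(sprintf("%s (%d children)", object@hubs, cc[object@hubs]),
              collapse = ", "), "\n")
  }
})

setMethod("show", "EdgeConfidence", function(object) {
  cat(sprintf("EdgeConfidence [%s]: %d genes, %d bootstraps, %d edges >= 0.8\n",
              object@provenance, nrow(object@matrix), object@n_bootstrap,
              sum(object@matrix >= 0.8)))
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf("ConsensusNetwork: %d nodes, %d edges (%d bootstraps)\n",
              length(object@nodes), nrow(object@edges), object@n_bootstraps))
})
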