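#' Construct a TimecourseExperiment from a log2 matrix
#'
#' @param values genes x arrays numeric matrix (log2 scale), rownames =
#'   gene identifiers.
#' @param replicate integer vector, one entry per column.
#' @param hours numeric vector of sampling times, one entry per column.
#' @return A \linkS4class{TimecourseExperiment}.
#' @export
TimecourseExperiment <- function(values, replicate, hours) {
  se <- SummarizedExperiment(
    assays = list(log2 = values),
    colData = DataFrame(replicate = as.integer(replicate),
                        hours = as.numeric(hours),
                        row.names = colnames(values)))
  new("TimecourseExperiment", se)
}

#' Construct a DisruptantPanel from a z-score matrix
#'
#' @param z genes x arrays matrix of within-array z-scores (each column
#'   mean 0, sd 1).
#' @param target character vector: the gene knocked down on each array.
#' @return A \linkS4class{DisruptantPanel}.
#' @seealso [toZPanel()] which builds one from raw log2 values.
#' @export
DisruptantPanel <- function(z, target) {
  se <- SummarizedExperiment(
    assays = list(z = z),
    colData = DataFrame(target = as.character(target),
                        row.names = colnames(z)))
  new("DisruptantPanel", se)
}

#' Time-course data as a genes x replicates x timepoints cube
#'
#' @param tc a \linkS4class{TimecourseExperiment}.
#' @return 3-dimensional numeric array with dimnames
#'   (gene, replicate, timepoint-hours).
#' @export
timecourseCube <- function(tc) {
  cd <- colData(tc)
  reps <- sort(unique(cd$replicate))
  tps <- sort(unique(cd$hours))
  vals <- assay(tc, "log2")
  cube <- array(NA_real_, dim = c(nrow(vals), length(reps), length(tps)),
                dimnames = list(rownames(vals), paste0("rep", reps),
                                paste0("t", tps)))
  for (r in seq_along(reps)) for (k in seq_along(tps)) {
    j <- which(cd$replicate == reps[r] & cd$hours == tps[k])
    cube[, r, k] <- vals[, j]
  }
  cube
}

#' @rdname timecourseCube
#' @export
timecourseHours <- function(tc) sort(unique(colData(tc)$hours))

#' Array-to-target map of a disruptant panel
#'
#' @param panel a \linkS4class{DisruptantPanel} (or raw disruptant
#'   \code{SummarizedExperiment} with \code{colData$target}).
#' @return named character vector: names are array identifiers, values the
#'   targeted genes.
#' @export
targetMap <- function(panel) {
  stats::setNames(as.character(colData(panel)$target), colnames(panel))
}

#' Accessors for bootstrap edge confidences
#'
#' @param x an \linkS4class{EdgeConfidence}.
#' @return \code{edgeConfidence()} the parent x child probability matrix;
#'   \code{nBootstraps()} the bootstrap count.
#' @export
edgeConfidence <- function(x) x@matrix

#' @rdname edgeConfidence
#' @export
nBootstraps <- function(x) {
  if (is(x, "ConsensusNetwork")) x@n_bootstraps else x@n_bootstrap
}

#' Edge table and node set of a network object
#'
#' @param x a \linkS4class{ConsensusNetwork} or
#'   \linkS4class{GroundTruthNetwork}.
#' @return \code{networkEdges()}: the edge data.frame;
#'   \code{networkNodes()}: the character node set.
#' @export
networkEdges <- function(x) {
  if (is(x, "ConsensusNetwork") || is(x, "GroundTruthNetwork")) x@edges
  else if (is.data.frame(x)) x
  else stop("no edge table for objects of class ", class(x)[1])
}

#' @rdname networkEdges
#' @export
networkNodes <- function(x) {
  if (is(x, "ConsensusNetwork")) x@nodes
  else if (is(x, "GroundTruthNetwork")) x@genes
  else if (is.data.frame(x)) unique(c(x$parent, x$child))
  else stop("no node set for objects of class ", class(x)[1])
}
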