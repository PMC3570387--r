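# Concordant-regulation gene selection over a replicated time course.
#
# Log2 ratios of each timepoint against a reference timepoint (first or
# last) are z-scored across genes within every (replicate, timepoint)
# slice; genes whose |z| clears a threshold at a run of adjacent
# timepoints, consistently across replicates, are called concordantly
# regulated. The final list is the union of the first-reference and
# last-reference selections.

#' Per-slice z-scores of time-course log2 ratios
#'
#' For every gene, replicate and timepoint, the log2 ratio against the
#' reference timepoint (\code{"first"} or \code{"last"}) is computed
#' within the same replicate; within each (replicate, timepoint) slice the
#' ratios are then standardized across genes (centred on the slice mean,
#' scaled by the slice's sample standard deviation). The reference slice
#' itself is identically zero (ratio of each value to itself) and is
#' excluded from selection scanning.
#'
#' @param tc a \linkS4class{TimecourseExperiment}.
#' @param reference \code{"first"} or \code{"last"} timepoint.
#' @return A \linkS4class{ZScoreCube}.
#' @export
timecourseZScores <- function(tc, reference = c("first", "last")) {
  reference <- match.arg(reference)
  cube <- timecourseCube(tc)
  nT <- dim(cube)[3]
  refIdx <- if (reference == "first") 1L else nT
  ratio <- sweep(cube, c(1, 2), cube[, , refIdx])
  z <- ratio
  for (r in seq_len(dim(cube)[2])) {
    for (k in seq_len(nT)) {
      if (k == refIdx) { z[, r, k] <- 0; next }
      v <- ratio[, r, k]
      s <- stats::sd(v)
      if (s == 0)
        stop(sprintf(
          "zero cross-gene sd of log2 ratios in replicate %d, timepoint %s",
          r, dimnames(cube)[[3]][k]))
      z[, r, k] <- (v - mean(v)) / s
    }
  }
  new("ZScoreCube", z = z, reference = reference, referenceIndex = refIdx)
}

#' Standardized time-course ratio cube
#'
#' Genes x replicates x timepoints array of z-scores produced by
#' [timecourseZScores()]; the slice at the reference timepoint is zero,
#' every other (replicate, timepoint) slice has mean 0 and sd 1 across
#' genes.
#'
#' @slot z the 3-d z-score array.
#' @slot reference \code{"first"} or \code{"last"}.
#' @slot referenceIndex integer index of the reference timepoint.
#' @export
setClass("ZScoreCube",
  representation(z = "array", reference = "character",
                 referenceIndex = "integer"))

setValidity("ZScoreCube", function(object) {
  if (length(dim(object@z)) != 3) return("z must be a 3-d array")
  if (!object@reference %in% c("first", "last"))
    return("reference must be 'first' or 'last'")
  TRUE
})

# longest run of TRUE in a logical vector
longestRun <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Select concordantly regulated genes from a z-score cube
#'
#' A gene is selected when there exist at least \code{minAdjacent}
#' consecutive non-reference timepoints at which its |z| reaches
#' \code{zThreshold} with a consistent sign, and this holds under the
#' chosen replicate rule (default: in every replicate).
#'
#' Note on the threshold direction: the criterion is \code{|z| >= 2}, i.e.
#' \code{z <= -2} or \code{z >= +2}. A band-pass reading
#' ("-2 <= z <= +2") would select the UNregulated majority of genes and
#' contradicts the goal of finding significantly regulated transcripts;
#' this implementation deliberately selects the tails.
#'
#' @param zcube a \linkS4class{ZScoreCube}.
#' @param zThreshold minimum |z| (default 2).
#' @param minAdjacent minimum run of adjacent qualifying timepoints
#'   (default 2; must be >= 2).
#' @param replicateRule \code{"all"} (default), \code{"majority"} or
#'   \code{"any"}: how many replicates must individually satisfy the
#'   criterion.
#' @param sameSign require a consistent direction within the qualifying
#'   run (default TRUE).
#' @return character vector of selected gene identifiers.
#' @export
selectConcordant <- function(zcube, zThreshold = 2, minAdjacent = 2L,
                             replicateRule = c("all", "majority", "any"),
                             sameSign = TRUE) {
  replicateRule <- match.arg(replicateRule)
  stopifnot(minAdjacent >= 2L, zThreshold > 0)
  z <- zcube@z
  keepT <- setdiff(seq_len(dim(z)[3]), zcube@referenceIndex)
  nR <- dim(z)[2]
  needed <- switch(replicateRule, all = nR, majority = ceiling(nR / 2),
                   any = 1L)
  genes <- dimnames(z)[[1]]
  sel <- vapply(seq_along(genes), function(gi) {
    hits <- 0L
    for (r in seq_len(nR)) {
      v <- z[gi, r, keepT]
      ok <- if (sameSign) {
        longestRun(v >= zThreshold) >= minAdjacent ||
          longestRun(v <= -zThreshold) >= minAdjacent
      } else {
        longestRun(abs(v) >= zThreshold) >= minAdjacent
      }
      if (ok) hits <- hits + 1L
    }
    hits >= needed
  }, logical(1))
  genes[sel]
}

#' Concordant selection with first/last-reference union
#'
#' Runs [selectConcordant()] with the first timepoint as reference and
#' again with the last timepoint as reference, and returns the union of
#' the two gene lists — the final list of concordantly regulated genes.
#'
#' @inheritParams selectConcordant
#' @param tc a \linkS4class{TimecourseExperiment}.
#' @return character vector (sorted, unique) of selected genes.
#' @examples
#' gt <- makeGroundTruth(30, c(H = 10), seed = 2)
#' tc <- simulateTimecourse(gt, simulationConfig(noiseSd = 0.1, seed = 2))
#' concordantUnion(tc)
#' @export
concordantUnion <- function(tc, zThreshold = 2, minAdjacent = 2L,
                            replicateRule = c("all", "majority", "any"),
                            sameSign = TRUE) {
  replicateRule <- match.arg(replicateRule)
  first <- selectConcordant(timecourseZScores(tc, "first"), zThreshold,
                            minAdjacent, replicateRule, sameSign)
  last <- selectConcordant(timecourseZScores(tc, "last"), zThreshold,
                           minAdjacent, replicateRule, sameSign)
  sort(union(first, last))
}
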