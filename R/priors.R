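# Structure priors for the static network search: the bootstrap dynamic
# time prior Z1 (edges recurrently found in first-order dynamic networks
# fitted to combinatorial resamples of the replicated time course) and the
# siRNA array prior Z2 (knockdown target -> responder weights from the
# disruptant panel's within-array z-scores).

#' Combinatorial bootstrap scheme for the time prior
#'
#' With R replicate time courses over T timepoints there are R^T possible
#' single-replicate combination time courses (3^8 = 6561 for the default
#' design). Each bootstrap draws \code{nDraws} of these combinations
#' uniformly with replacement (default 25, i.e. 8 x 25 = 200 arrays per
#' bootstrap), fits a dynamic network, and the procedure is repeated
#' \code{nBootstraps} times (default 100) to estimate per-edge bootstrap
#' probabilities.
#'
#' @slot nDraws combination time courses drawn per bootstrap.
#' @slot nBootstraps number of bootstrap network fits.
#' @slot seed master seed; per-bootstrap child seeds are spawned from it
#'   so runs are reproducible.
#' @export
setClass("BootstrapScheme",
  representation(nDraws = "integer", nBootstraps = "integer",
                 seed = "integer"))

setValidity("BootstrapScheme", function(object) {
  if (object@nDraws < 1L) return("nDraws must be >= 1")
  if (object@nBootstraps < 1L) return("nBootstraps must be >= 1")
  TRUE
})

#' @describeIn BootstrapScheme-class Constructor.
#' @param nDraws,nBootstraps,seed see slots.
#' @export
bootstrapScheme <- function(nDraws = 25L, nBootstraps = 100L, seed = 1L) {
  new("BootstrapScheme", nDraws = as.integer(nDraws),
      nBootstraps = as.integer(nBootstraps), seed = as.integer(seed))
}

#' Number of possible combination time courses
#'
#' @param tc a \linkS4class{TimecourseExperiment}.
#' @return replicates^timepoints (6561 for 3 replicates x 8 timepoints).
#' @export
combinationCount <- function(tc) {
  cd <- colData(tc)
  length(unique(cd$replicate))^length(unique(cd$hours))
}

#' Draw combination time courses for one bootstrap
#'
#' Each drawn series picks, independently and uniformly with replacement
#' at every timepoint, the value vector of one replicate, yielding a
#' single-replicate combination time course; \code{nDraws} such series
#' form one bootstrap sample (timepoints x nDraws arrays in total).
#'
#' @param tc a \linkS4class{TimecourseExperiment}.
#' @param scheme a [bootstrapScheme()].
#' @param seed seed for this draw (defaults to the scheme's master seed).
#' @return list of genes x timepoints matrices, length \code{nDraws}.
#' @export
resampleTimecourses <- function(tc, scheme = bootstrapScheme(),
                                seed = scheme@seed) {
  cube <- timecourseCube(tc)
  nR <- dim(cube)[2]; nT <- dim(cube)[3]
  withSeed(seed, {
    lapply(seq_len(scheme@nDraws), function(d) {
      pick <- sample.int(nR, nT, replace = TRUE)
      series <- sapply(seq_len(nT), function(k) cube[, pick[k], k])
      dimnames(series) <- list(dimnames(cube)[[1]], dimnames(cube)[[3]])
      series
    })
  })
}

#' Enumerate every combination time course (toy designs only)
#'
#' Exhaustive counterpart of [resampleTimecourses()] for oracle checks;
#' refuses designs with more than \code{maxCombinations} combinations
#' (full enumeration of realistic designs, e.g. 6561 combinations, is the
#' reason the bootstrap scheme exists).
#'
#' @inheritParams resampleTimecourses
#' @param maxCombinations refusal threshold (default 256).
#' @return list of genes x timepoints matrices, one per combination.
#' @export
enumerateCombinations <- function(tc, maxCombinations = 256L) {
  cube <- timecourseCube(tc)
  nR <- dim(cube)[2]; nT <- dim(cube)[3]
  if (nR^nT > maxCombinations)
    stop(sprintf("%d^%d = %g combinations exceed the enumeration limit (%d)",
                 nR, nT, nR^nT, maxCombinations))
  grid <- as.matrix(expand.grid(rep(list(seq_len(nR)), nT)))
  lapply(seq_len(nrow(grid)), function(i) {
    series <- sapply(seq_len(nT), function(k) cube[, grid[i, k], k])
    dimnames(series) <- list(dimnames(cube)[[1]], dimnames(cube)[[3]])
    series
  })
}

# Greedy forward-backward parent selection for one child over candidate
# parent indices, maximizing the decomposable family score.
# `base` holds always-included covariate indices (e.g. the child's own
# lag in the dynamic stage); they are conditioned on but never reported.
greedyParents <- function(cache, child, candidates, maxParents,
                          base = integer(0), tol = 1e-9) {
  cur <- integer(0)
  curScore <- scoreFamilyIdx(cache, child, base)
  repeat {
    bestGain <- tol; bestSet <- NULL
    if (length(cur) < maxParents) {
      cand <- setdiff(candidates, cur)
      if (length(cand)) {
        s <- scoreAdditionsIdx(cache, child, c(base, cur), cand)
        k <- which.max(s)
        if (s[k] - curScore > bestGain) {
          bestGain <- s[k] - curScore
          bestSet <- sort(c(cur, cand[k]))
        }
      }
    }
    for (drop in cur) {
      s <- scoreFamilyIdx(cache, child, c(base, setdiff(cur, drop)))
      if (s - curScore > bestGain) { bestGain <- s - curScore
                                     bestSet <- setdiff(cur, drop) }
    }
    if (is.null(bestSet)) break
    cur <- bestSet
    curScore <- curScore + bestGain
  }
  list(parents = cur, score = curScore)
}

#' Fit a first-order dynamic network to combination time courses
#'
#' Stationary first-order model: for every child gene, parents are chosen
#' (greedy forward-backward selection, up to \code{maxParents}) to
#' maximize the family score of the regression of child(t+1) on the
#' parents' values at t, pooling the consecutive-timepoint transition
#' pairs of all supplied series. Time ordering resolves edge direction,
#' so no acyclicity constraint is applied; self-loops are excluded by
#' default.
#'
#' By default the child's own lagged value is included as a baseline
#' covariate of every family (never reported as an edge): first-order
#' dynamics make a gene's past its strongest predictor, and without
#' conditioning on it any co-regulated gene can proxy that
#' autocorrelation, flooding the fit with sibling edges. Candidate
#' parents therefore compete to explain the residual drive.
#'
#' @param seriesList list of genes x timepoints matrices (e.g. from
#'   [resampleTimecourses()]).
#' @param config a [scorerConfig()].
#' @param maxParents in-degree cap (default 3).
#' @param candidates optional character vector restricting candidate
#'   parents (default: all genes).
#' @param excludeSelf drop the child itself from its candidate parents
#'   (default TRUE).
#' @param autoregressive condition every family on the child's own lag
#'   (default TRUE).
#' @return data.frame of directed edges (parent, child).
#' @export
fitDynamicNetwork <- function(seriesList, config = scorerConfig(),
                              maxParents = 3L, candidates = NULL,
                              excludeSelf = TRUE, autoregressive = TRUE) {
  if (maxParents < 0) stop("maxParents must be >= 0")
  stopifnot(length(seriesList) >= 1, ncol(seriesList[[1]]) >= 2)
  genes <- rownames(seriesList[[1]])
  nT <- ncol(seriesList[[1]])
  X <- do.call(cbind, lapply(seriesList, function(s) s[, -nT, drop = FALSE]))
  Y <- do.call(cbind, lapply(seriesList, function(s) s[, -1, drop = FALSE]))
  cache <- scorerCache(X, Y, config)
  candIdx <- if (is.null(candidates)) seq_along(genes)
             else match(candidates, genes)
  parent <- character(); child <- character()
  for (ci in seq_along(genes)) {
    cand <- if (excludeSelf) setdiff(candIdx, ci) else candIdx
    fit <- greedyParents(cache, ci, cand, maxParents,
                         base = if (autoregressive) ci else integer(0))
    if (length(fit$parents)) {
      parent <- c(parent, genes[fit$parents])
      child <- c(child, rep(genes[ci], length(fit$parents)))
    }
  }
  data.frame(parent = parent, child = child, stringsAsFactors = FALSE)
}

#' Bootstrap dynamic-network time prior (Z1)
#'
#' Runs [fitDynamicNetwork()] on \code{nBootstraps} independent
#' combination resamples of the time course. The bootstrap probability of
#' edge i -> j is the fraction of bootstrap networks containing it; edges
#' with probability >= \code{threshold} (default 0.8) form the binary
#' prior matrix Z1.
#'
#' @param tc a \linkS4class{TimecourseExperiment}.
#' @param scheme a [bootstrapScheme()].
#' @param config a [scorerConfig()].
#' @param maxParents in-degree cap per dynamic fit.
#' @param threshold bootstrap-probability threshold for Z1, in (0, 1].
#' @param candidates optional candidate-parent restriction.
#' @return list with \code{confidence} (an \linkS4class{EdgeConfidence})
#'   and \code{Z1} (binary parent x child matrix).
#' @export
timePrior <- function(tc, scheme = bootstrapScheme(),
                      config = scorerConfig(), maxParents = 3L,
                      threshold = 0.8, candidates = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  genes <- rownames(tc)
  counts <- matrix(0L, length(genes), length(genes),
                   dimnames = list(genes, genes))
  seeds <- withSeed(scheme@seed,
                    sample.int(.Machine$integer.max - 1L,
                               scheme@nBootstraps))
  for (b in seq_len(scheme@nBootstraps)) {
    series <- resampleTimecourses(tc, scheme, seed = seeds[b])
    ed <- fitDynamicNetwork(series, config, maxParents, candidates)
    if (nrow(ed)) counts[cbind(ed$parent, ed$child)] <-
        counts[cbind(ed$parent, ed$child)] + 1L
  }
  conf <- counts / scheme@nBootstraps
  confidence <- new("EdgeConfidence", matrix = conf,
                    n_bootstrap = scheme@nBootstraps,
                    provenance = "time_prior")
  Z1 <- (conf >= threshold) * 1
  list(confidence = confidence, Z1 = Z1)
}

#' siRNA array prior (Z2)
#'
#' For every candidate edge i -> j with i a knockdown target, the prior
#' weight is the magnitude of gene j's within-array z-score on the array
#' that targeted i, kept only when it reaches \code{zCutoff} (default 2);
#' the z-score's sign is stored separately for knockdown-direction
#' prediction. Rows of untargeted genes, and the diagonal, are zero.
#'
#' @param panel a \linkS4class{DisruptantPanel}.
#' @param zCutoff minimum |z| for a nonzero prior weight.
#' @return list with \code{Z2} (non-negative parent x child weights) and
#'   \code{sign} (matching -1/0/+1 matrix).
#' @export
arrayPrior <- function(panel, zCutoff = 2) {
  z <- assay(panel, "z")
  tm <- targetMap(panel)
  dup <- unique(tm[duplicated(tm)])
  if (length(dup))
    stop("multiple arrays target gene(s): ", paste(dup, collapse = ", "),
         "; collapse replicates before building the array prior")
  genes <- rownames(z)
  bad <- setdiff(tm, genes)
  if (length(bad))
    stop("target gene(s) absent from the panel rows: ",
         paste(bad, collapse = ", "))
  Z2 <- matrix(0, length(genes), length(genes),
               dimnames = list(genes, genes))
  sgn <- Z2
  for (a in names(tm)) {
    i <- tm[[a]]
    zv <- z[, a]
    hit <- abs(zv) >= zCutoff & genes != i
    Z2[i, hit] <- abs(zv[hit])
    sgn[i, hit] <- sign(zv[hit])
  }
  list(Z2 = Z2, sign = sgn, zCutoff = zCutoff)
}
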