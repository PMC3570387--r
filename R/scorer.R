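# Decomposable family score for network structure search.
#
# Each child gene is modelled as an additive regression on its parents,
# f(child) = intercept + sum_p f_p(parent_p), with f_p expanded in a
# B-spline basis (or a single linear term), Gaussian residuals and a ridge
# penalty on the basis coefficients. The returned score is a penalized
# log-likelihood approximation to the log marginal likelihood (BIC by
# default), so that higher is better and the total network score
# decomposes over (child, parent-set) families. Basis matrices and all
# cross-products are precomputed once per dataset; the per-family linear
# algebra runs in compiled code (src/family_score.cpp) because it sits in
# the innermost loop of the greedy searches.

#' Family scorer configuration
#'
#' @param basisType \code{"bspline"} (additive smooth terms, default) or
#'   \code{"linear"}.
#' @param nBasis basis dimension per parent for B-splines (default 6,
#'   minimum 2).
#' @param lambda positive ridge penalty on basis coefficients
#'   (default 0.1); the intercept is never penalized.
#' @param approximation \code{"bic"} (default): logLik - k/2 log n with k
#'   the effective number of parameters; \code{"laplace"}: logLik minus
#'   the ridge-evidence Occam factor 1/2 (log det(X'X + lambda D) -
#'   k log lambda).
#' @return a validated list of class \code{"FamilyScorerConfig"}.
#' @export
scorerConfig <- function(basisType = c("bspline", "linear"), nBasis = 6L,
                         lambda = 0.1,
                         approximation = c("bic", "laplace")) {
  basisType <- match.arg(basisType)
  approximation <- match.arg(approximation)
  nBasis <- as.integer(nBasis)
  if (basisType == "bspline" && nBasis < 2L)
    stop("nBasis must be >= 2 for the B-spline basis")
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(basisType = basisType, nBasis = nBasis, lambda = lambda,
                 approximation = approximation,
                 approxFlag = if (approximation == "bic") 0L else 1L),
            class = "FamilyScorerConfig")
}

# Standardize matrix rows (genes) across samples; zero-variance rows
# become all-zero so they can never carry signal.
standardizeRows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

# Column-centred B-spline basis of a standardized vector; zero vectors get
# an all-zero basis.
#' @importFrom splines bs
geneBasis <- function(x, nBasis) {
  if (all(x == 0) || stats::sd(x) == 0) return(matrix(0, length(x), nBasis))
  B <- splines::bs(x, df = nBasis)
  sweep(unclass(B)[, , drop = FALSE], 2, colMeans(B))
}

# Precompute everything family scoring needs for one dataset.
# X: genes x n predictor values; Y: genes x n response values (same gene
# order; identical to X for the static stage, lagged for the dynamic one).
# Both the configured basis and a plain linear basis are prepared so that
# small-sample families can fall back to the linear one.
scorerCache <- function(X, Y = X, config = scorerConfig()) {
  stopifnot(identical(rownames(X), rownames(Y)), ncol(X) == ncol(Y))
  genes <- rownames(X)
  if (is.null(genes)) stop("gene rownames are required")
  n <- ncol(X)
  Xs <- standardizeRows(X)
  Ys <- standardizeRows(Y)
  m <- if (config$basisType == "bspline") config$nBasis else 1L
  if (config$basisType == "bspline") {
    Bfull <- matrix(0, n, length(genes) * m)
    for (i in seq_along(genes))
      Bfull[, (i - 1L) * m + seq_len(m)] <- geneBasis(Xs[i, ], m)
  } else {
    Bfull <- t(Xs)
  }
  D1 <- cbind(1, Bfull)
  Dl <- cbind(1, t(Xs))
  list(genes = genes, n = n, m = m, config = config,
       G = crossprod(D1), Gl = crossprod(Dl),
       XtY = crossprod(D1, t(Ys)), XtYl = crossprod(Dl, t(Ys)),
       yty = rowSums(Ys^2))
}

# Design-column indices of a parent set (1 = intercept).
familyIdx <- function(parents, m) {
  if (!length(parents)) return(1L)
  c(1L, as.integer(outer(seq_len(m), (parents - 1L) * m + 1L, `+`)))
}

# TRUE when families with k parents must fall back to the linear basis.
needsLinear <- function(cache, k) {
  cache$config$basisType == "bspline" && cache$n <= 1L + k * cache$m
}

# Penalized ridge regression score of one family (integer gene indices).
scoreFamilyIdx <- function(cache, child, parents) {
  cfg <- cache$config
  if (needsLinear(cache, length(parents)) && cfg$basisType == "bspline")
    warning(sprintf(
      "family of '%s': %d samples too few for %d B-spline columns; using a linear basis",
      cache$genes[child], cache$n, 1L + length(parents) * cache$m),
      call. = FALSE)
  if (cfg$basisType == "linear" || needsLinear(cache, length(parents))) {
    if (cache$n <= 1L + length(parents))
      stop(sprintf("family of '%s': too few samples (%d) even for a linear fit",
                   cache$genes[child], cache$n))
    cppFamilyScore(cache$Gl, cache$XtYl, cache$yty, child,
                   familyIdx(parents, 1L), cache$n, cfg$lambda,
                   cfg$approxFlag)
  } else {
    cppFamilyScore(cache$G, cache$XtY, cache$yty, child,
                   familyIdx(parents, cache$m), cache$n, cfg$lambda,
                   cfg$approxFlag)
  }
}

# Scores of (child, parents + cand) for every cand in `candidates`,
# in one compiled call. Returns a vector aligned with `candidates`.
scoreAdditionsIdx <- function(cache, child, parents, candidates) {
  if (!length(candidates)) return(numeric(0))
  cfg <- cache$config
  if (cfg$basisType == "linear" || needsLinear(cache, length(parents) + 1L)) {
    if (cache$n <= 2L + length(parents))
      stop(sprintf("family of '%s': too few samples (%d) even for a linear fit",
                   cache$genes[child], cache$n))
    cppScoreAdditions(cache$Gl, cache$XtYl, cache$yty, child,
                      familyIdx(parents, 1L), 1L + candidates, 1L,
                      cache$n, cfg$lambda, cfg$approxFlag)
  } else {
    m <- cache$m
    cppScoreAdditions(cache$G, cache$XtY, cache$yty, child,
                      familyIdx(parents, m),
                      1L + (candidates - 1L) * m + 1L, m,
                      cache$n, cfg$lambda, cfg$approxFlag)
  }
}

#' Score one child/parent-set family
#'
#' Fits the penalized additive regression of a child gene on a set of
#' parent genes and returns the penalized log-likelihood score (higher is
#' better). The score is decomposable: a network's data score is the sum
#' of its families' scores, which is what both the dynamic-network fit and
#' the static structure search maximize. When the sample size is too
#' small for the B-spline design the family falls back to a linear basis
#' with a warning.
#'
#' @param child gene identifier of the response.
#' @param parentSet character vector of parent gene identifiers (may be
#'   empty; must not contain the child).
#' @param data genes x samples numeric matrix (rows standardized
#'   internally).
#' @param config a [scorerConfig()].
#' @return scalar score.
#' @examples
#' x <- matrix(rnorm(300), 3, 100, dimnames = list(c("a", "b", "c"), NULL))
#' x[2, ] <- sin(2 * x[1, ]) + rnorm(100, 0, 0.1)
#' familyScore("b", "a", x) > familyScore("b", character(), x)
#' @export
familyScore <- function(child, parentSet, data, config = scorerConfig()) {
  if (child %in% parentSet) stop("parentSet must not contain the child")
  genes <- rownames(data)
  miss <- setdiff(c(child, parentSet), genes)
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  cache <- scorerCache(data, data, config)
  scoreFamilyIdx(cache, match(child, genes),
                 match(parentSet, genes))
}
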