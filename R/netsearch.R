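# Prior-guided static Bayesian network structure search over the
# disruptant panel. The posterior score of a DAG decomposes as
#   sum_child familyScore(child, parents) + sum_edge edge prior energy,
# with the per-edge energy -kappa + gamma1*Z1 + gamma2*Z2: every edge pays
# a baseline penalty kappa, edges supported by the time prior (Z1) or the
# array prior (Z2) pay less or are rewarded. Search is greedy hill
# climbing over single-edge additions, deletions and reversals under an
# acyclicity constraint and an in-degree cap, with random restarts;
# consensus bootstrapping of the arrays yields per-edge frequencies.

#' Graph-prior hyperparameters
#'
#' @param kappa baseline penalty paid by every edge (> 0, default 2).
#' @param gamma1 log-prior bonus per unit of the binary time prior Z1
#'   (default 2).
#' @param gamma2 log-prior bonus per unit of the array-prior weight Z2
#'   (default 0.5).
#' @return validated list of class \code{"PriorHyperparameters"}.
#' @export
priorHyper <- function(kappa = 2, gamma1 = 2, gamma2 = 0.5) {
  if (kappa <= 0) stop("kappa must be positive")
  if (gamma1 < 0 || gamma2 < 0) stop("gamma1 and gamma2 must be >= 0")
  structure(list(kappa = kappa, gamma1 = gamma1, gamma2 = gamma2),
            class = "PriorHyperparameters")
}

# Per-edge prior-energy matrix over the gene universe.
edgePriorMatrix <- function(genes, Z1, Z2, hyper) {
  P <- matrix(-hyper$kappa, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (!is.null(Z1)) P <- P + hyper$gamma1 * Z1[genes, genes]
  if (!is.null(Z2)) P <- P + hyper$gamma2 * Z2[genes, genes]
  diag(P) <- 0
  P
}

#' Log prior of a graph under the edge-energy model
#'
#' Sum over the graph's edges of \code{-kappa + gamma1 Z1[i,j] +
#' gamma2 Z2[i,j]}; the empty graph has log prior 0. Additive over edges,
#' hence decomposable alongside the family score.
#'
#' @param graph edge data.frame (parent, child) or an object with
#'   [networkEdges()].
#' @param Z1 binary time-prior matrix (parent x child) or NULL.
#' @param Z2 non-negative array-prior weight matrix or NULL.
#' @param hyper a [priorHyper()].
#' @return scalar log prior.
#' @export
graphLogPrior <- function(graph, Z1 = NULL, Z2 = NULL,
                          hyper = priorHyper()) {
  ed <- networkEdges(graph)
  if (!nrow(ed)) return(0)
  genes <- unique(c(ed$parent, ed$child,
                    if (!is.null(Z1)) rownames(Z1),
                    if (!is.null(Z2)) rownames(Z2)))
  P <- edgePriorMatrix(genes, Z1, Z2, hyper)
  sum(P[cbind(ed$parent, ed$child)])
}

transitiveClosure <- function(adj) {
  R <- adj * 1
  repeat {
    nxt <- ((R + R %*% R) > 0) * 1
    if (identical(nxt, R)) break
    R <- nxt
  }
  R > 0
}

# One steepest-ascent hill climb from a given adjacency matrix.
#
# Incremental bookkeeping: addS[i, j] holds the family score of
# (child j, parents_j + i) and delS[i, j] that of (child j, parents_j - i);
# both depend only on child j's current parent set, so after a move only
# the touched children's columns are refreshed (one batched compiled call
# each). Legality (acyclicity via the transitive closure, the in-degree
# cap) is re-masked every iteration. Ties break lexicographically by
# (parent, child), additions before deletions before reversals.
hillClimb <- function(cache, P, adj, maxParents, tol = 1e-9) {
  N <- nrow(adj)
  parents <- lapply(seq_len(N), function(j) which(adj[, j]))
  fam <- numeric(N)
  addS <- matrix(NA_real_, N, N)
  delS <- matrix(NA_real_, N, N)
  refresh <- function(j) {
    fam[j] <<- scoreFamilyIdx(cache, j, parents[[j]])
    addS[, j] <<- NA_real_
    delS[, j] <<- NA_real_
    cand <- setdiff(seq_len(N), c(j, parents[[j]]))
    if (length(cand) && length(parents[[j]]) < maxParents)
      addS[cand, j] <<- scoreAdditionsIdx(cache, j, parents[[j]], cand)
    for (p in parents[[j]])
      delS[p, j] <<- scoreFamilyIdx(cache, j, setdiff(parents[[j]], p))
  }
  for (j in seq_len(N)) refresh(j)
  total <- sum(fam) + sum(P[adj])
  famRow <- function() matrix(fam, N, N, byrow = TRUE)
  repeat {
    closure <- transitiveClosure(adj)
    gainAddRaw <- addS - famRow() + P      # unmasked: reused by reversals
    gainAdd <- gainAddRaw
    gainAdd[adj | t(closure) | diag(N) > 0] <- NA_real_
    gainDel <- delS - famRow() - P
    gainDel[!adj] <- NA_real_
    best <- tol; move <- NULL
    pickBest <- function(gm, type) {
      mx <- suppressWarnings(max(gm, na.rm = TRUE))
      if (is.finite(mx) && mx > best) {
        hits <- which(gm == mx, arr.ind = TRUE)
        hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
        best <<- mx; move <<- c(type, hits[1, 1], hits[1, 2])
      }
    }
    pickBest(gainAdd, 1L)
    pickBest(gainDel, 2L)
    # reversals: del (i,j) + add (j,i); path legality checked lazily on
    # candidates that could beat the current best
    gainRev <- gainDel + t(gainAddRaw)
    cand <- which(!is.na(gainRev) & gainRev > best, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(-gainRev[cand], cand[, 1], cand[, 2])
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (gainRev[i, j] <= best) break
        adjTmp <- adj; adjTmp[i, j] <- FALSE
        if (!reachableFrom(adjTmp, i, j)) {
          best <- gainRev[i, j]; move <- c(3L, i, j)
          break
        }
      }
    }
    if (is.null(move)) break
    type <- move[1L]; i <- move[2L]; j <- move[3L]
    if (type == 1L) {
      adj[i, j] <- TRUE
      parents[[j]] <- sort(c(parents[[j]], i))
    } else if (type == 2L) {
      adj[i, j] <- FALSE
      parents[[j]] <- setdiff(parents[[j]], i)
    } else {
      adj[i, j] <- FALSE; adj[j, i] <- TRUE
      parents[[j]] <- setdiff(parents[[j]], i)
      parents[[i]] <- sort(c(parents[[i]], j))
      refresh(i)
    }
    refresh(j)
    total <- total + best
  }
  list(adj = adj, parents = parents, fam = fam, total = total)
}

randomStartAdj <- function(N, maxParents, p = 2 / N) {
  perm <- sample.int(N)
  adj <- matrix(FALSE, N, N)
  for (a in seq_len(N - 1L)) for (b in seq.int(a + 1L, N)) {
    i <- perm[a]; j <- perm[b]
    if (stats::runif(1) < p && sum(adj[, j]) < maxParents) adj[i, j] <- TRUE
  }
  adj
}

#' Prior-guided static network structure search
#'
#' Maximizes the decomposable posterior score (family scores plus edge
#' prior energies) by greedy hill climbing over single-edge additions,
#' deletions and reversals, keeping the graph acyclic and each in-degree
#' at most \code{maxParents}. The first restart climbs from the empty
#' graph with steepest ascent (ties broken lexicographically by (parent,
#' child)); further restarts climb from seeded random DAGs, and the
#' best-scoring result is returned. Deterministic for a fixed seed.
#'
#' @param data genes x arrays matrix, or a \linkS4class{DisruptantPanel}
#'   (its \code{"z"} assay is used).
#' @param Z1,Z2 optional prior matrices over (a superset of) the genes;
#'   see [timePrior()] and [arrayPrior()].
#' @param config a [scorerConfig()].
#' @param hyper a [priorHyper()].
#' @param maxParents in-degree cap (>= 1, default 3).
#' @param nRestarts number of hill-climb restarts (default 2).
#' @param seed RNG seed for the random restarts.
#' @return list with \code{edges} (data.frame parent, child),
#'   \code{score} (posterior score of the returned DAG), \code{adj}
#'   (logical parent x child matrix) and \code{emptyScore}.
#' @export
searchStaticNetwork <- function(data, Z1 = NULL, Z2 = NULL,
                                config = scorerConfig(),
                                hyper = priorHyper(), maxParents = 3L,
                                nRestarts = 2L, seed = 1L) {
  if (maxParents < 1) stop("maxParents must be >= 1")
  if (is(data, "SummarizedExperiment")) data <- assay(data, "z")
  genes <- rownames(data)
  N <- length(genes)
  cache <- scorerCache(data, data, config)
  P <- edgePriorMatrix(genes, Z1, Z2, hyper)
  emptyScore <- sum(vapply(seq_len(N), function(j)
    scoreFamilyIdx(cache, j, integer(0)), numeric(1)))
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      start <- if (r == 1L) matrix(FALSE, N, N)
               else randomStartAdj(N, maxParents)
      fit <- hillClimb(cache, P, start, maxParents)
      if (is.null(best) || fit$total > best$total + 1e-9) best <- fit
    }
  })
  idx <- which(best$adj, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  list(edges = data.frame(parent = genes[idx[ord, 1]],
                          child = genes[idx[ord, 2]],
                          stringsAsFactors = FALSE),
       score = best$total, adj = best$adj, emptyScore = emptyScore)
}

#' Consensus network by bootstrap over arrays
#'
#' Resamples the panel's arrays with replacement (to the original array
#' count), runs [searchStaticNetwork()] on each bootstrap sample, and
#' summarizes: an edge's frequency is the fraction of bootstrap DAGs
#' containing it, and edges at or above \code{edgeFreqThreshold} form the
#' consensus network. Each edge's sign is the sign of the Pearson
#' correlation between parent and child z-rows across the full panel.
#'
#' @inheritParams searchStaticNetwork
#' @param panel a \linkS4class{DisruptantPanel} or genes x arrays matrix.
#' @param nBootstraps bootstrap searches (default 100).
#' @param edgeFreqThreshold consensus frequency threshold (default 0.5;
#'   not dictated by the underlying method — tune to taste).
#' @param nRestarts hill-climb restarts per bootstrap (default 1).
#' @return a \linkS4class{ConsensusNetwork}.
#' @export
bootstrapStaticNetwork <- function(panel, Z1 = NULL, Z2 = NULL,
                                   config = scorerConfig(),
                                   hyper = priorHyper(), maxParents = 3L,
                                   nBootstraps = 100L,
                                   edgeFreqThreshold = 0.5,
                                   nRestarts = 1L, seed = 1L) {
  if (nBootstraps < 1) stop("nBootstraps must be >= 1")
  z <- if (is(panel, "SummarizedExperiment")) assay(panel, "z") else panel
  genes <- rownames(z)
  counts <- matrix(0L, length(genes), length(genes),
                   dimnames = list(genes, genes))
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L,
                                     2L * nBootstraps))
  for (b in seq_len(nBootstraps)) {
    cols <- withSeed(seeds[b], sample.int(ncol(z), replace = TRUE))
    fit <- searchStaticNetwork(z[, cols, drop = FALSE], Z1, Z2, config,
                               hyper, maxParents, nRestarts,
                               seed = seeds[nBootstraps + b])
    if (nrow(fit$edges))
      counts[cbind(fit$edges$parent, fit$edges$child)] <-
        counts[cbind(fit$edges$parent, fit$edges$child)] + 1L
  }
  freq <- counts / nBootstraps
  keep <- which(freq >= edgeFreqThreshold & row(freq) != col(freq),
                arr.ind = TRUE)
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  edgeSign <- function(i, j) {
    if (stats::sd(z[i, ]) == 0 || stats::sd(z[j, ]) == 0) return(0)
    s <- sign(stats::cor(z[i, ], z[j, ]))
    if (is.na(s)) 0 else s
  }
  sgn <- if (nrow(keep)) mapply(edgeSign, keep[, 1], keep[, 2]) else numeric(0)
  new("ConsensusNetwork", nodes = genes,
      edges = data.frame(parent = genes[keep[, 1]],
                         child = genes[keep[, 2]],
                         frequency = freq[keep], sign = as.numeric(sgn),
                         stringsAsFactors = FALSE),
      n_bootstraps = as.integer(nBootstraps))
}
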