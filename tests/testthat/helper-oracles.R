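# Independent oracles used to check the package's implementations.
# They deliberately avoid the code paths they verify: graph enumeration
# instead of hill climbing, lm() instead of the compiled ridge scorer,
# combinatorial enumeration instead of phyper().

# All DAGs over `genes` (<= 4 nodes): enumerate every subset of ordered
# pairs and keep the acyclic ones. 3 nodes -> 25 DAGs, 4 -> 543.
enumerateDAGs <- function(genes) {
  pairs <- expand.grid(parent = genes, child = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$parent != pairs$child, ]
  nP <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^nP - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nP) - 1)) > 0)
    ed <- pairs[sel, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$parent, to = ed$child), directed = TRUE,
      vertices = genes)
    if (igraph::is_dag(g)) out[[length(out) + 1L]] <- ed
  }
  out
}

# Posterior score of a given DAG using the package's decomposable pieces
# called family-by-family (the quantity hill climbing maximizes).
oracleGraphScore <- function(edges, data, Z1 = NULL, Z2 = NULL,
                             config = scorerConfig(),
                             hyper = priorHyper()) {
  genes <- rownames(data)
  fam <- sum(vapply(genes, function(ch) {
    familyScore(ch, edges$parent[edges$child == ch], data, config)
  }, numeric(1)))
  fam + graphLogPrior(edges, Z1, Z2, hyper)
}

# Gaussian log-likelihood + BIC-on-parameter-count score of a plain
# least-squares fit; independent check of the ridge scorer's ordering
# (penalties differ slightly, so only orderings/gaps are compared).
lmScore <- function(y, X = NULL) {
  n <- length(y)
  fit <- if (is.null(X)) lm(y ~ 1) else lm(y ~ X)
  rss <- sum(residuals(fit)^2)
  s2 <- rss / n
  -n / 2 * (log(2 * pi * s2) + 1) - 0.5 * length(coef(fit)) * log(n)
}

# Exact upper-tail hypergeometric p by enumeration over all possible
# query draws of size n from the universe (feasible for |universe| <= 20).
enumHyperP <- function(overlap, setSize, universeSize, querySize) {
  total <- choose(universeSize, querySize)
  p <- 0
  for (k in overlap:min(setSize, querySize)) {
    p <- p + choose(setSize, k) *
      choose(universeSize - setSize, querySize - k)
  }
  p / total
}
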