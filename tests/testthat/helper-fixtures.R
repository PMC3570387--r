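# Small planted structures built in code, shared across test files.

# Directed chain g1 -> g2 -> ... -> gk with all-positive unit-ish weights.
# Chains are fully identifiable from noise-free dynamics (no two genes
# share an identical trajectory shape), unlike sibling fan-outs.
chainTruth <- function(k, weights = rep(0.8, k - 1), signs = rep(1, k - 1)) {
  genes <- paste0("g", seq_len(k))
  new("GroundTruthNetwork", genes = genes,
      edges = data.frame(parent = genes[-k], child = genes[-1],
                         sign = signs, weight = weights,
                         stringsAsFactors = FALSE),
      hubs = character(0))
}

# Genes x arrays matrix with one planted linear edge x -> y plus
# independent noise genes; samples i.i.d. so the static scorer applies.
plantedPairData <- function(n = 60, nNoise = 1, beta = 0.9, sd = 0.3,
                            seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- beta * x + rnorm(n, 0, sd)
    m <- rbind(A = x, B = y)
    if (nNoise > 0) {
      nz <- matrix(rnorm(n * nNoise), nNoise, n)
      rownames(nz) <- paste0("N", seq_len(nNoise))
      m <- rbind(m, nz)
    }
    m
  })
}
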