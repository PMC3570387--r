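#' Simulation configuration
#'
#' Bundles the parameters of the synthetic expression generator: the
#' sampling design (timepoints in hours, replicate count), the dynamics
#' (decay, stimulus), the noise level on the log2 scale and the knockdown
#' depth of the disruptant arrays.
#'
#' The defaults emulate the survival-factor-deprivation study design the
#' package targets: eight timepoints at 0, 0.5, 1.5, 3, 6, 9, 12 and 24
#' hours, three replicates, and knockdowns that reduce the target to 20%
#' of its baseline abundance.
#'
#' @slot timepoints numeric, strictly increasing sampling times (hours).
#' @slot nReplicates integer, replicate time courses (>= 1).
#' @slot noiseSd numeric, Gaussian noise sd on the log2 scale (>= 0).
#' @slot knockdownFactor numeric in (0, 1]: residual fraction of target
#'   expression on its knockdown array (0.2 = knocked down to 20%).
#' @slot decay numeric in [0, 1): autoregressive persistence of each
#'   gene's log2 deviation between consecutive timepoints.
#' @slot stimulusStrength numeric, per-step drive added to stimulus
#'   target genes at every timepoint after the first.
#' @slot stimulusTargets character, genes receiving the stimulus; empty
#'   means "the root regulators of the network" (genes with children but
#'   no parents), mirroring an upstream cause such as serum withdrawal.
#' @slot baselineMean,baselineSd numeric, log2-scale baseline expression
#'   is drawn i.i.d. N(baselineMean, baselineSd^2) per gene.
#' @slot seed integer RNG seed; fixed seed gives bit-identical output.
#'
#' @export
setClass("SimulationConfig",
  representation(timepoints = "numeric", nReplicates = "integer",
                 noiseSd = "numeric", knockdownFactor = "numeric",
                 decay = "numeric", stimulusStrength = "numeric",
                 stimulusTargets = "character", baselineMean = "numeric",
                 baselineSd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  tp <- object@timepoints
  if (length(tp) < 2 || any(diff(tp) <= 0))
    msg <- c(msg, "timepoints must be >= 2 values, strictly increasing")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  kf <- object@knockdownFactor
  if (kf <= 0 || kf > 1) msg <- c(msg, "knockdownFactor must lie in (0, 1]")
  if (object@decay < 0 || object@decay >= 1)
    msg <- c(msg, "decay must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class Constructor with study-design defaults.
#' @param timepoints,nReplicates,noiseSd,knockdownFactor,decay,stimulusStrength,stimulusTargets,baselineMean,baselineSd,seed
#'   see the corresponding slots.
#' @return A validated \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(noiseSd = 0.1, seed = 7)
#' cfg@timepoints
#' @export
simulationConfig <- function(timepoints = c(0, 0.5, 1.5, 3, 6, 9, 12, 24),
                             nReplicates = 3L, noiseSd = 0.2,
                             knockdownFactor = 0.2, decay = 0.7,
                             stimulusStrength = 1, stimulusTargets = character(),
                             baselineMean = 8, baselineSd = 1, seed = 1L) {
  new("SimulationConfig", timepoints = as.numeric(timepoints),
      nReplicates = as.integer(nReplicates), noiseSd = as.numeric(noiseSd),
      knockdownFactor = as.numeric(knockdownFactor), decay = as.numeric(decay),
      stimulusStrength = as.numeric(stimulusStrength),
      stimulusTargets = as.character(stimulusTargets),
      baselineMean = as.numeric(baselineMean),
      baselineSd = as.numeric(baselineSd), seed = as.integer(seed))
}

#' Build a planted ground-truth network with designated hubs
#'
#' Constructs a random signed DAG over \code{nGenes} genes in which each
#' requested hub has exactly its prescribed number of distinct direct
#' children, plus \code{extraEdgeCount} additional random edges. Hubs are
#' placed first in the topological order so that large out-degrees are
#' feasible; the remaining gene order is shuffled. A fixed
#' \code{edgeSignFraction} of all edges carry a negative (repressive) sign;
#' edge weights are drawn uniformly from [0.5, 1].
#'
#' @param nGenes total number of genes.
#' @param hubSpec named integer vector: names are hub gene identifiers,
#'   values their prescribed children counts (e.g. \code{c(HUB1 = 20)}).
#' @param edgeSignFraction fraction of edges given sign -1 (default 0.25).
#' @param extraEdgeCount additional non-hub forward edges (default 0).
#' @param seed RNG seed; the same call with the same seed returns an
#'   identical network.
#' @param genePrefix prefix for auto-generated filler gene names.
#' @return A \linkS4class{GroundTruthNetwork}.
#' @examples
#' gt <- makeGroundTruth(20, c(HUB = 8), extraEdgeCount = 5, seed = 1)
#' countChildren(gt)[["HUB"]]
#' @export
makeGroundTruth <- function(nGenes, hubSpec, edgeSignFraction = 0.25,
                            extraEdgeCount = 0L, seed = 1L,
                            genePrefix = "g") {
  stopifnot(nGenes >= 1, length(hubSpec) >= 0)
  hubIds <- names(hubSpec)
  if (length(hubSpec) && (is.null(hubIds) || any(hubIds == "")))
    stop("hubSpec must be a named vector: names are hub identifiers")
  nFill <- nGenes - length(hubIds)
  if (nFill < 0) stop("more hubs than genes")
  withSeed(seed, {
    fill <- sprintf("%s%03d", genePrefix, seq_len(nFill))
    # hubs head the topological order; filler genes are shuffled behind them
    order <- c(hubIds, sample(fill))
    pos <- stats::setNames(seq_along(order), order)
    parent <- character(); child <- character()
    for (h in hubIds) {
      pool <- order[seq.int(pos[[h]] + 1L, length.out = nGenes - pos[[h]])]
      if (length(pool) < hubSpec[[h]])
        stop(sprintf(
          "infeasible hub spec: hub '%s' requests %d children but only %d genes follow it",
          h, hubSpec[[h]], length(pool)))
      kids <- sample(pool, hubSpec[[h]])
      parent <- c(parent, rep(h, length(kids)))
      child <- c(child, kids)
    }
    have <- paste(parent, child)
    added <- 0L
    guard <- 0L
    while (added < extraEdgeCount) {
      guard <- guard + 1L
      if (guard > 200L * max(1L, extraEdgeCount))
        stop("could not place the requested number of extra edges")
      ij <- sort(sample.int(nGenes, 2L))      # forward edge keeps the DAG
      p <- order[ij[1L]]; c2 <- order[ij[2L]]
      key <- paste(p, c2)
      if (key %in% have) next
      have <- c(have, key)
      parent <- c(parent, p); child <- c(child, c2)
      added <- added + 1L
    }
    nE <- length(parent)
    sign <- rep(1, nE)
    nNeg <- round(edgeSignFraction * nE)
    if (nNeg > 0) sign[sample.int(nE, nNeg)] <- -1
    weight <- stats::runif(nE, 0.5, 1)
    new("GroundTruthNetwork", genes = order,
        edges = data.frame(parent = parent, child = child, sign = sign,
                           weight = weight, stringsAsFactors = FALSE),
        hubs = hubIds)
  })
}

# Parent x child signed-weight matrix of a ground truth.
truthWeightMatrix <- function(truth) {
  g <- truth@genes
  W <- matrix(0, length(g), length(g), dimnames = list(g, g))
  ed <- truth@edges
  if (nrow(ed)) W[cbind(ed$parent, ed$child)] <- ed$sign * ed$weight
  W
}

stimulusVector <- function(truth, config) {
  g <- truth@genes
  s <- stats::setNames(numeric(length(g)), g)
  targets <- config@stimulusTargets
  if (!length(targets)) {           # default: root regulators of the DAG
    targets <- setdiff(unique(truth@edges$parent), unique(truth@edges$child))
  }
  bad <- setdiff(targets, g)
  if (length(bad))
    stop("unknown stimulus target gene(s): ", paste(bad, collapse = ", "))
  s[targets] <- config@stimulusStrength
  s
}

#' Simulate a replicated time course from a planted network
#'
#' Each replicate evolves per-gene log2 deviations from baseline through a
#' first-order linear system evaluated at successive timepoints: a gene's
#' deviation at step k+1 is \code{decay} times its own deviation at step k,
#' plus the signed weighted sum of its parents' deviations at step k, plus
#' the stimulus drive (for stimulus target genes) and Gaussian noise. At
#' the first timepoint the deviation is pure measurement noise (each
#' replicate's t=0 array is an independent hybridization), so with no
#' noise and no stimulus the output equals the baseline everywhere.
#' Genes downstream of the
#' stimulus are concordantly regulated relative to the first timepoint when
#' the noise is small.
#'
#' Stimulus targets are assigned onset delays of 0-3 steps in rotation
#' (first target immediate, second delayed one step, and so on; shared
#' across replicates and stored in \code{metadata()$stimulusOnset}).
#' Staggered onsets mimic
#' immediate-early versus late responders in a deprivation time course,
#' and they keep the stimulated genes' trajectories linearly
#' distinguishable — under a common instantaneous drive every stimulated
#' root would trace the same curve and no time-course model could tell
#' them apart.
#'
#' @param truth a \linkS4class{GroundTruthNetwork} (must be a DAG).
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{TimecourseExperiment}; columns are named
#'   \code{rep<k>_t<hours>}, \code{metadata()} stores baseline and config.
#' @examples
#' gt <- makeGroundTruth(10, c(H = 4), seed = 1)
#' tc <- simulateTimecourse(gt, simulationConfig(noiseSd = 0, seed = 1))
#' dim(tc)   # 10 genes x (3 replicates * 8 timepoints)
#' @export
simulateTimecourse <- function(truth, config = simulationConfig()) {
  validObject(truth); validObject(config)
  g <- truth@genes
  nG <- length(g)
  tp <- config@timepoints
  nT <- length(tp)
  nR <- config@nReplicates
  W <- truthWeightMatrix(truth)
  stim <- stimulusVector(truth, config)
  withSeed(config@seed, {
    baseline <- stats::setNames(
      stats::rnorm(nG, config@baselineMean, config@baselineSd), g)
    onset <- stats::setNames(integer(nG), g)
    stimGenes <- names(stim)[stim != 0]
    onset[stimGenes] <- rep(0:3, length.out = length(stimGenes))
    vals <- matrix(NA_real_, nG, nR * nT,
                   dimnames = list(g, NULL))
    cn <- character(nR * nT)
    repv <- integer(nR * nT); hrs <- numeric(nR * nT)
    col <- 0L
    for (r in seq_len(nR)) {
      d <- numeric(nG)                       # log2 deviation from baseline
      for (k in seq_len(nT)) {
        noise <- if (config@noiseSd > 0)
          stats::rnorm(nG, 0, config@noiseSd) else numeric(nG)
        if (k == 1L) {
          d <- noise        # measurement noise: t=0 arrays are still
        } else {            # independent hybridizations per replicate
          d <- config@decay * d + drop(crossprod(W, d)) +
            stim * (k - 1L > onset) + noise
        }
        col <- col + 1L
        vals[, col] <- baseline + d
        cn[col] <- sprintf("rep%d_t%g", r, tp[k])
        repv[col] <- r; hrs[col] <- tp[k]
      }
    }
    colnames(vals) <- cn
    se <- SummarizedExperiment(
      assays = list(log2 = vals),
      colData = DataFrame(replicate = repv, hours = hrs, row.names = cn))
    out <- new("TimecourseExperiment", se)
    metadata(out)$baseline <- baseline
    metadata(out)$config <- config
    metadata(out)$stimulusOnset <- onset[stimGenes]
    out
  })
}

#' Simulate an siRNA disruptant panel from a planted network
#'
#' Produces one array per target gene. On each array the target's
#' expression is multiplied by \code{knockdownFactor} (i.e. its log2 value
#' drops by \code{log2(knockdownFactor)}), and the perturbation propagates
#' to the target's descendants in topological order through the same signed
#' linear rule used by [simulateTimecourse()]: a child's log2 deviation is
#' the signed weighted sum of its parents' deviations. Non-descendants are
#' unchanged up to noise. The noise-free unperturbed baseline is stored in
#' \code{metadata()$baseline} for ratio computation.
#'
#' @param truth a \linkS4class{GroundTruthNetwork}.
#' @param targets character vector of genes to knock down (one array each).
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SummarizedExperiment} with assay \code{"log2"}
#'   and \code{colData$target}; pass through [toZPanel()] to obtain a
#'   \linkS4class{DisruptantPanel}.
#' @examples
#' gt <- makeGroundTruth(10, c(H = 4), seed = 1)
#' raw <- simulateDisruptants(gt, targets = gt@genes[1:5],
#'                            config = simulationConfig(noiseSd = 0))
#' SummarizedExperiment::colData(raw)$target
#' @export
simulateDisruptants <- function(truth, targets,
                                config = simulationConfig()) {
  validObject(truth); validObject(config)
  g <- truth@genes
  bad <- setdiff(targets, g)
  if (length(bad))
    stop("unknown target gene(s): ", paste(bad, collapse = ", "))
  ed <- truth@edges
  ord <- topoOrder(ed, g)
  parentsOf <- split(seq_len(nrow(ed)), ed$child)
  kdLog2 <- log2(config@knockdownFactor)
  withSeed(config@seed, {
    baseline <- stats::setNames(
      stats::rnorm(length(g), config@baselineMean, config@baselineSd), g)
    vals <- matrix(NA_real_, length(g), length(targets),
                   dimnames = list(g, paste0("kd_", targets)))
    for (a in seq_along(targets)) {
      tgt <- targets[a]
      d <- stats::setNames(numeric(length(g)), g)
      d[tgt] <- kdLog2
      for (v in ord) {
        if (v == tgt) next                 # siRNA clamps the target itself
        rows <- parentsOf[[v]]
        if (length(rows))
          d[v] <- sum(ed$sign[rows] * ed$weight[rows] * d[ed$parent[rows]])
      }
      noise <- if (config@noiseSd > 0)
        stats::rnorm(length(g), 0, config@noiseSd) else 0
      vals[, a] <- baseline + d + noise
    }
    se <- SummarizedExperiment(
      assays = list(log2 = vals),
      colData = DataFrame(target = targets, row.names = colnames(vals)))
    metadata(se)$baseline <- baseline
    metadata(se)$config <- config
    se
  })
}

#' Embed a network in a background probe universe
#'
#' Appends \code{n} unregulated background genes (no edges) to a ground
#' truth. Simulated arrays then contain the regulatory network plus the
#' unresponsive majority of probes a real microarray measures — which is
#' what makes within-array and across-gene z-scores meaningful: both are
#' standardized against a pool dominated by null genes.
#'
#' @param truth a \linkS4class{GroundTruthNetwork}.
#' @param n number of background genes to append.
#' @param prefix name prefix for the background genes.
#' @return A \linkS4class{GroundTruthNetwork} over the enlarged universe;
#'   edges and hubs unchanged.
#' @export
addBackgroundGenes <- function(truth, n, prefix = "bg") {
  if (n < 1) return(truth)
  new("GroundTruthNetwork",
      genes = c(truth@genes, sprintf("%s%04d", prefix, seq_len(n))),
      edges = truth@edges, hubs = truth@hubs)
}

#' Generate a quality-flag matrix for an expression matrix
#'
#' Emits an all-\code{"Good"} flag matrix matching the expression matrix,
#' optionally corrupting a fraction of entries to \code{"Bad"} so that the
#' flag filter can be exercised.
#'
#' @param values genes x arrays matrix (dimnames used for the flags).
#' @param badFraction fraction of entries flagged \code{"Bad"}.
#' @param seed RNG seed for the corrupted positions.
#' @return character matrix of \code{"Good"}/\code{"Bad"}, same shape.
#' @export
makeFlags <- function(values, badFraction = 0, seed = 1L) {
  flags <- matrix("Good", nrow(values), ncol(values),
                  dimnames = dimnames(values))
  if (badFraction > 0) {
    withSeed(seed, {
      n <- length(flags)
      k <- round(badFraction * n)
      if (k > 0) flags[sample.int(n, k)] <- "Bad"
    })
  }
  flags
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so simulation calls do not disturb user code.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
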