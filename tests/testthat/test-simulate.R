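test_that("makeGroundTruth wires hubs exactly and is a reproducible DAG", {
  # forced star: 5 genes, one hub with 4 children
  star <- makeGroundTruth(5, c(H = 4), extraEdgeCount = 0, seed = 1)
  expect_s4_class(star, "GroundTruthNetwork")
  expect_identical(unname(countChildren(star)[["H"]]), 4L)
  expect_setequal(star@edges$parent, "H")

  # a hub wired like the study's 9th-ranked hub: 31 children in 50 genes
  big <- makeGroundTruth(50, c(`VASH1-like` = 31), seed = 7)
  expect_identical(unname(countChildren(big)[["VASH1-like"]]), 31L)

  # determinism
  a <- makeGroundTruth(30, c(H = 10), extraEdgeCount = 8, seed = 11)
  b <- makeGroundTruth(30, c(H = 10), extraEdgeCount = 8, seed = 11)
  expect_identical(a@edges, b@edges)
  c2 <- makeGroundTruth(30, c(H = 10), extraEdgeCount = 8, seed = 12)
  expect_false(identical(a@edges, c2@edges))

  # requested sign fraction is honoured
  d <- makeGroundTruth(40, c(H = 10), edgeSignFraction = 0.5,
                       extraEdgeCount = 10, seed = 2)
  expect_equal(sum(d@edges$sign == -1), round(0.5 * nrow(d@edges)))

  # infeasible spec errors, naming the hub
  expect_error(makeGroundTruth(5, c(H = 10), seed = 1), "H")
})

test_that("simulateTimecourse has the right shape, baseline and dynamics", {
  gt <- makeGroundTruth(10, c(H = 4), seed = 3)
  cfg0 <- simulationConfig(noiseSd = 0, stimulusStrength = 0, seed = 5)
  tc0 <- simulateTimecourse(gt, cfg0)
  cube <- timecourseCube(tc0)
  expect_identical(dim(cube), c(10L, 3L, 8L))
  # no noise, no stimulus: every timepoint equals baseline
  for (k in 1:8)
    expect_equal(cube[, , k], cube[, , 1], tolerance = 1e-12)

  # fixed seed: bit-identical cube on repeat
  tcA <- simulateTimecourse(gt, simulationConfig(noiseSd = 0.2, seed = 9))
  tcB <- simulateTimecourse(gt, simulationConfig(noiseSd = 0.2, seed = 9))
  expect_identical(SummarizedExperiment::assay(tcA),
                   SummarizedExperiment::assay(tcB))
})

test_that("noise-free 2-gene chain follows the hand-computed recursion", {
  # H -> C, weight w, sign +1; stimulus s on H (immediate onset), decay a.
  gt <- new("GroundTruthNetwork", genes = c("H", "C"),
            edges = data.frame(parent = "H", child = "C", sign = 1,
                               weight = 0.6),
            hubs = "H")
  cfg <- simulationConfig(noiseSd = 0, stimulusStrength = 0.5, decay = 0.7,
                          stimulusTargets = "H", seed = 1)
  tc <- simulateTimecourse(gt, cfg)
  cube <- timecourseCube(tc)
  # closed-form recursion by hand
  a <- 0.7; s <- 0.5; w <- 0.6
  dH <- 0; dC <- 0
  for (k in 2:8) {
    dNew <- a * dC + w * dH
    dH <- a * dH + s
    dC <- dNew
  }
  expect_equal(unname(cube["H", 1, 8] - cube["H", 1, 1]), dH,
               tolerance = 1e-10)
  expect_equal(unname(cube["C", 1, 8] - cube["C", 1, 1]), dC,
               tolerance = 1e-10)
  # child's |log2 ratio vs t0| grows monotonically
  ratios <- cube["C", 1, ] - cube["C", 1, 1]
  expect_true(all(diff(abs(ratios)) > -1e-12))
})

test_that("simulateDisruptants propagates knockdowns with the signed rule", {
  gt <- makeGroundTruth(12, c(H = 5), seed = 4)
  cfg <- simulationConfig(noiseSd = 0, knockdownFactor = 0.2, seed = 2)
  raw <- simulateDisruptants(gt, targets = gt@genes, config = cfg)
  vals <- SummarizedExperiment::assay(raw, "log2")
  base <- S4Vectors::metadata(raw)$baseline

  # leaf knockdown: only the leaf differs from baseline
  leaf <- setdiff(gt@genes, gt@edges$parent)[1]
  col <- vals[, paste0("kd_", leaf)]
  expect_equal(unname(col[leaf] - base[leaf]), log2(0.2), tolerance = 1e-12)
  others <- setdiff(gt@genes, leaf)
  expect_equal(unname(col[others]), unname(base[others]), tolerance = 1e-12)

  # hub knockdown: one-step propagation by hand for each direct child
  kd <- vals[, "kd_H"]
  hubEdges <- gt@edges[gt@edges$parent == "H", ]
  onlyChildOfH <- setdiff(hubEdges$child, gt@edges$child[gt@edges$parent != "H"])
  for (i in which(hubEdges$child %in% onlyChildOfH)) {
    ch <- hubEdges$child[i]
    expect_equal(unname(kd[ch] - base[ch]),
                 hubEdges$sign[i] * hubEdges$weight[i] * log2(0.2),
                 tolerance = 1e-10)
    if (hubEdges$sign[i] == 1) expect_lt(kd[ch], base[ch])
    else expect_gt(kd[ch], base[ch])
  }

  # knockdownFactor = 1: the panel equals baseline everywhere
  cfg1 <- simulationConfig(noiseSd = 0, knockdownFactor = 1, seed = 2)
  raw1 <- simulateDisruptants(gt, gt@genes[1:3], cfg1)
  v1 <- SummarizedExperiment::assay(raw1, "log2")
  for (j in seq_len(ncol(v1)))
    expect_equal(unname(v1[, j]),
                 unname(S4Vectors::metadata(raw1)$baseline),
                 tolerance = 1e-12)

  expect_error(simulateDisruptants(gt, c("H", "nope"), cfg), "nope")
})

test_that("flags, background genes and class validity behave", {
  v <- matrix(0, 10, 6, dimnames = list(paste0("g", 1:10), paste0("a", 1:6)))
  f0 <- makeFlags(v)
  expect_true(all(f0 == "Good"))
  f1 <- makeFlags(v, badFraction = 0.25, seed = 3)
  expect_equal(sum(f1 == "Bad"), round(0.25 * length(v)))
  expect_identical(makeFlags(v, 0.25, seed = 3), f1)

  gt <- makeGroundTruth(6, c(H = 3), seed = 1)
  bg <- addBackgroundGenes(gt, 4)
  expect_length(bg@genes, 10)
  expect_identical(bg@edges, gt@edges)

  # validity: cycles and self-edges are rejected
  expect_error(new("GroundTruthNetwork", genes = c("a", "b"),
                   edges = data.frame(parent = c("a", "b"),
                                      child = c("b", "a"),
                                      sign = 1, weight = 1),
                   hubs = character(0)),
               "cycle")
  expect_error(new("GroundTruthNetwork", genes = "a",
                   edges = data.frame(parent = "a", child = "a",
                                      sign = 1, weight = 1),
                   hubs = character(0)),
               "[Ss]elf")
})

test_that("knockdown response direction opposes the edge sign", {
  # knockdown lowers the parent, so a positive-sign child drops and a
  # negative-sign child rises
  for (seed in 1:5) {
    gt <- makeGroundTruth(15, c(H = 6), edgeSignFraction = 0.5, seed = seed)
    cfg <- simulationConfig(noiseSd = 0, seed = seed)
    raw <- simulateDisruptants(gt, "H", cfg)
    kd <- SummarizedExperiment::assay(raw, "log2")[, 1]
    base <- S4Vectors::metadata(raw)$baseline
    ed <- gt@edges[gt@edges$parent == "H", ]
    expect_true(all(sign(kd[ed$child] - base[ed$child]) == -ed$sign))
  }
})
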