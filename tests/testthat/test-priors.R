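test_that("the combinatorial scheme reproduces the study arithmetic", {
  gt <- makeGroundTruth(5, c(H = 2), seed = 1)
  tc <- simulateTimecourse(gt, simulationConfig(seed = 1))
  # 3 replicates x 8 timepoints -> 3^8 = 6561 combination time courses
  expect_identical(combinationCount(tc), 6561)
  # 25 draws of 8 timepoints each: 8 x 25 = 200 arrays per bootstrap
  ser <- resampleTimecourses(tc, bootstrapScheme(nDraws = 25, seed = 2))
  expect_length(ser, 25)
  expect_true(all(vapply(ser, ncol, 0L) == 8))
  expect_identical(sum(vapply(ser, ncol, 0L)), 200L)
})

test_that("resampling is seed-deterministic and degenerate for 1 replicate", {
  gt <- makeGroundTruth(4, c(H = 2), seed = 1)
  tc1 <- simulateTimecourse(gt, simulationConfig(nReplicates = 1, seed = 3))
  ser <- resampleTimecourses(tc1, bootstrapScheme(nDraws = 5, seed = 4))
  # with one replicate every combination is the single replicate
  for (s in ser[-1]) expect_identical(s, ser[[1]])

  tc3 <- simulateTimecourse(gt, simulationConfig(seed = 3))
  a <- resampleTimecourses(tc3, bootstrapScheme(seed = 10))
  b <- resampleTimecourses(tc3, bootstrapScheme(seed = 10))
  expect_identical(a, b)
  c2 <- resampleTimecourses(tc3, bootstrapScheme(seed = 11))
  expect_false(identical(a, c2))
})

test_that("enumeration covers toy designs and refuses real ones", {
  gt <- makeGroundTruth(3, c(H = 1), seed = 1)
  tc <- simulateTimecourse(gt, simulationConfig(
    timepoints = c(0, 1, 2, 3), nReplicates = 2, seed = 1))
  combos <- enumerateCombinations(tc)          # 2^4 = 16
  expect_length(combos, 16)
  expect_identical(anyDuplicated(combos), 0L)
  tc8 <- simulateTimecourse(gt, simulationConfig(seed = 1))
  expect_error(enumerateCombinations(tc8), "6561")
})

test_that("dynamic fits recover a noise-free chain and ignore flat data", {
  gt <- chainTruth(3)
  cfg <- simulationConfig(noiseSd = 0, stimulusStrength = 0.5,
                          stimulusTargets = "g1", seed = 1)
  tc <- simulateTimecourse(gt, cfg)
  ser <- resampleTimecourses(tc, bootstrapScheme(nDraws = 10, seed = 2))
  ed <- fitDynamicNetwork(ser, scorerConfig("linear"), maxParents = 1)
  # brute-force oracle: for each child compare all single-parent scores
  genes <- rownames(ser[[1]])
  nT <- ncol(ser[[1]])
  X <- do.call(cbind, lapply(ser, function(s) s[, -nT]))
  Y <- do.call(cbind, lapply(ser, function(s) s[, -1]))
  for (ch in c("g2", "g3")) {
    want <- gt@edges$parent[gt@edges$child == ch]
    got <- ed$parent[ed$child == ch]
    expect_identical(got, want)
  }

  # all-constant series: no parents anywhere
  flat <- lapply(1:5, function(i)
    matrix(5, 3, 8, dimnames = list(genes, NULL)))
  expect_identical(nrow(fitDynamicNetwork(flat, scorerConfig("linear"))), 0L)
})

test_that("time-prior confidences are bootstrap fractions and Z1 thresholds them", {
  gt <- chainTruth(4)
  cfg <- simulationConfig(noiseSd = 0, stimulusStrength = 0.5,
                          stimulusTargets = "g1", seed = 2)
  tc <- simulateTimecourse(gt, cfg)
  tp <- timePrior(tc, bootstrapScheme(nDraws = 10, nBootstraps = 25,
                                      seed = 3),
                  config = scorerConfig("linear"), maxParents = 1)
  conf <- edgeConfidence(tp$confidence)
  # every confidence is an exact multiple of 1/25
  expect_lt(max(abs(conf * 25 - round(conf * 25))), 1e-12)
  expect_true(all(diag(conf) == 0))
  # Z1 is exactly the thresholded confidence matrix
  expect_identical(tp$Z1, (conf >= 0.8) * 1)
  # on noise-free, identifiable structure the planted edges are near-certain
  planted <- conf[cbind(gt@edges$parent, gt@edges$child)]
  expect_true(all(planted >= 0.9))
  # and reproducible
  tp2 <- timePrior(tc, bootstrapScheme(nDraws = 10, nBootstraps = 25,
                                       seed = 3),
                   config = scorerConfig("linear"), maxParents = 1)
  expect_identical(conf, edgeConfidence(tp2$confidence))
})

test_that("the array prior records |z| above the cutoff with its sign", {
  z <- matrix(0, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                       c("kdA", "kdC")))
  z[, 1] <- c(-3.0, -3.1, 1.5, 0.2)
  z[, 2] <- c(0.1, 2.4, -3.3, -1.9)
  # standardize columns so the panel passes validity
  z <- scale(z)
  panel <- DisruptantPanel(z, c("A", "C"))
  ap <- arrayPrior(panel, zCutoff = abs(z["B", 1]) - 1e-9)
  # B responds in A's knockdown: Z2[A,B] = |z|, negative sign
  expect_equal(ap$Z2["A", "B"], abs(z["B", 1]))
  expect_identical(unname(ap$sign["A", "B"]), -1)
  # sub-cutoff responses contribute nothing
  expect_identical(unname(ap$Z2["A", "D"]), 0)
  # untargeted genes have all-zero rows; no self-edges
  expect_true(all(ap$Z2["B", ] == 0) && all(ap$Z2["D", ] == 0))
  expect_true(all(diag(ap$Z2) == 0))

  # duplicate arrays for one target are rejected
  z3 <- scale(cbind(z, kdA2 = c(1, -2, 0.5, 0.5)))
  expect_error(arrayPrior(DisruptantPanel(z3, c("A", "C", "A"))), "A")
})
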