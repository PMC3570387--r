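test_that("countChildren counts distinct direct children", {
  ed <- data.frame(parent = c("H", rep("H", 9), "H", "x"),
                   child = c("a", paste0("c", 1:9), "a", "H"))
  cc <- countChildren(ed)
  expect_identical(unname(cc[["H"]]), 10L)     # duplicate H->a counts once
  expect_identical(unname(cc[["a"]]), 0L)
  # descendants mode counts the whole downstream set
  chain <- data.frame(parent = c("a", "b"), child = c("b", "c"))
  expect_identical(unname(countChildren(chain)[["a"]]), 1L)
  expect_identical(unname(countChildren(chain, descendants = TRUE)[["a"]]),
                   2L)
})

test_that("rankHubs sorts, ties share the min rank, filters apply", {
  ed <- data.frame(parent = c(rep("A", 5), rep("B", 3), rep("C", 3)),
                   child = c(paste0("x", 1:5), paste0("y", 1:3),
                             paste0("z", 1:3)))
  ht <- rankHubs(ed)
  expect_identical(ht$gene[1], "A")
  expect_identical(ht$rank[ht$gene == "A"], 1L)
  expect_identical(ht$rank[ht$gene == "B"], 2L)
  expect_identical(ht$rank[ht$gene == "C"], 2L)
  expect_identical(nrow(rankHubs(ed, minChildren = 5)), 1L)
  expect_identical(nrow(rankHubs(ed, topK = 2)), 2L)
  empty <- data.frame(parent = character(), child = character())
  expect_identical(nrow(rankHubs(empty)), 0L)
})

test_that("hubSubnetwork returns the incident neighbourhood only", {
  ed <- data.frame(parent = c("p1", "p2", "H", "H", "H", "q"),
                   child = c("H", "H", "c1", "c2", "c3", "r"))
  sub <- hubSubnetwork(ed, "H")
  expect_identical(sub$nParents, 2L)
  expect_identical(sub$nChildren, 3L)
  expect_identical(nrow(sub$edges), 5L)
  expect_error(hubSubnetwork(ed, "absent"), "absent")
})

test_that("hub-child correlations match hand-computed Pearson values", {
  z <- rbind(H = c(1, 2, 3, 4), up = c(2, 4, 6, 8), mix = c(1, 3, 2, 4),
             anti = -c(1, 2, 3, 4), flat = c(1, 1, 1, 1))
  colnames(z) <- paste0("a", 1:4)
  r <- hubChildCorrelations(z, "H", c("up", "mix", "anti", "flat"))
  expect_equal(unname(r["up"]), 1)
  expect_equal(unname(r["mix"]), 0.8)    # hand Pearson: 4/5
  expect_equal(unname(r["anti"]), -1)
  expect_true(is.na(r["flat"]))
  expect_error(hubChildCorrelations(z, "H", "missing"), "missing")

  dir <- predictKnockdownDirection(r)
  expect_identical(unname(dir["up"]), "down")
  expect_identical(unname(dir["anti"]), "up")
  expect_identical(unname(dir["flat"]), "none")
  expect_identical(unname(predictKnockdownDirection(c(x = 0))["x"]), "none")
})

test_that("hypergeometric enrichment matches the exact combinatorial oracle", {
  universe <- letters[1:20]
  query <- letters[1:5]
  sets <- list(perfect = letters[1:5], half = letters[4:9],
               none = letters[11:15], big = letters[1:12])
  res <- hypergeometricEnrichment(query, sets, universe)
  for (i in seq_len(nrow(res))) {
    o <- enumHyperP(res$overlap_count[i], res$set_size[i], 20, 5)
    expect_equal(res$p_value[i], o, tolerance = 1e-12)
  }
  # the fully-overlapping set has p = 1 / C(20, 5)
  expect_equal(res$p_value[res$gene_set_name == "perfect"],
               1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap means P(X >= 0) = 1
  expect_equal(res$p_value[res$gene_set_name == "none"], 1)
  # BH with a single set leaves q = p
  one <- hypergeometricEnrichment(query, sets["half"], universe)
  expect_equal(one$q_value, one$p_value)
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  expect_error(hypergeometricEnrichment(query, sets, character(0)), "empty")
  expect_error(hypergeometricEnrichment(c("zzz"), sets, universe), "zzz")
})

test_that("the children-count histogram tabulates out-degrees", {
  ed <- data.frame(parent = c(rep("A", 3), "B"), child = c("x", "y", "z", "x"))
  h <- childrenCountHistogram(ed)
  # nodes: A(3), B(1), x/y/z(0)
  expect_identical(h$n_children, c(0L, 1L, 3L))
  expect_identical(h$frequency, c(3L, 1L, 1L))
  expect_identical(sum(h$frequency), length(networkNodes(ed)))
})

test_that("edge recovery follows the documented conventions", {
  truth <- data.frame(parent = paste0("p", 1:10), child = paste0("c", 1:10))
  inferred <- rbind(truth[1:6, ],
                    data.frame(parent = c("a", "b"), child = c("x", "y")))
  er <- edgeRecovery(inferred, truth)
  expect_equal(er$precision, 0.75)
  expect_equal(er$recall, 0.6)
  expect_equal(er$f1, 2 * 0.75 * 0.6 / 1.35)
  perfect <- edgeRecovery(truth, truth)
  expect_equal(unlist(perfect[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))
  none <- edgeRecovery(truth[0, ], truth)
  expect_equal(unlist(none[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("planted-hub ranks and sentinels are reported", {
  ed <- data.frame(parent = c(rep("A", 4), rep("B", 4), rep("C", 2)),
                   child = c(paste0("x", 1:4), paste0("y", 1:4),
                             paste0("z", 1:2)))
  ht <- rankHubs(ed)
  rk <- hubRecoveryRank(ht, c("A", "B", "C", "ghost"))
  expect_equal(unname(rk[c("A", "B")]), c(1, 1))   # tied min-rank
  expect_equal(unname(rk[["C"]]), 3)
  expect_identical(unname(rk[["ghost"]]), Inf)
})
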