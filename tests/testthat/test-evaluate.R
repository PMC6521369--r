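toy_truth <- function(keys) {
  groundTruthEdges(do.call(rbind, strsplit(keys, "")))
}

test_that("confusion counts follow the TP/FP/FN definitions", {
  u <- letters[1:4]
  net <- coexpressionNetwork(u, rbind(c("a", "b"), c("a", "c"), c("b", "d")))
  # identical edge sets: no errors
  same <- groundTruthEdges(edges(net))
  expect_identical(confusionCounts(net, same), c(tp = 3L, fp = 0L, fn = 0L))
  # edges {ab, ac, bd} vs truth {ab}
  gt <- toy_truth("ab")
  expect_identical(confusionCounts(net, gt), c(tp = 1L, fp = 2L, fn = 0L))
  # pair orientation never matters
  rev_net <- coexpressionNetwork(u, rbind(c("b", "a"), c("c", "a"),
                                          c("d", "b")))
  expect_identical(confusionCounts(rev_net, gt), confusionCounts(net, gt))
})

test_that("truth is restricted to the universe before counting FN", {
  u <- c("a", "b", "c")
  net <- coexpressionNetwork(u, rbind(c("a", "b")))
  gt <- groundTruthEdges(rbind(c("a", "b"), c("a", "z"), c("y", "z")))
  cm <- confusionCounts(net, gt, u)
  expect_identical(cm, c(tp = 1L, fp = 0L, fn = 0L))  # z-pairs excluded
  expect_error(confusionCounts(net, gt, c("a", "b")), "universe")
})

test_that("confusion matches the pair-by-pair oracle on random networks", {
  set.seed(60)
  u <- sprintf("G%02d", 1:50)
  all_pairs <- t(combn(u, 2))
  net <- coexpressionNetwork(u, all_pairs[sample(nrow(all_pairs), 120), ])
  gt <- groundTruthEdges(all_pairs[sample(nrow(all_pairs), 200), ])
  expect_identical(confusionCounts(net, gt), oracle_confusion(net, gt, u))
})

test_that("FDR and FNR arithmetic, including undefined sentinels", {
  expect_equal(edgeFDR(1, 2), 2 / 3)
  expect_equal(edgeFDR(5, 0), 0)
  expect_true(is.nan(edgeFDR(0, 0)))
  expect_error(edgeFDR(-1, 0), "non-negative")

  expect_equal(edgeFNR(3, 1), 0.25)
  expect_equal(edgeFNR(3, 0), 0)
  expect_true(is.nan(edgeFNR(0, 0)))
  expect_error(edgeFNR(0, -2), "non-negative")
})

test_that("shared-truth restriction is a monotone projection", {
  gt <- groundTruthEdges(rbind(c("a", "b"), c("a", "c"), c("b", "c")),
                         dbCount = c(1L, 2L, 3L))
  expect_identical(sharedTruth(gt, 1), gt)                  # no-op
  s2 <- sharedTruth(gt, 2)
  expect_identical(.pcnet_keys(truthPairs(s2)), c("a|c", "b|c"))
  expect_identical(dbCount(s2), c(2L, 3L))                  # counts preserved
  s3 <- sharedTruth(gt, 3)
  expect_true(all(.pcnet_keys(truthPairs(s3)) %in%
                  .pcnet_keys(truthPairs(s2))))             # shrinks with k
  expect_error(sharedTruth(gt, 0), ">= 1")
})

test_that("density covers its closed forms", {
  u <- letters[1:5]
  full <- coexpressionNetwork(u, t(combn(u, 2)))
  expect_equal(networkDensity(full), 1)
  expect_equal(networkDensity(coexpressionNetwork(u)), 0)
  four <- coexpressionNetwork(u, rbind(c("a", "b"), c("b", "c"),
                                       c("c", "d"), c("d", "e")))
  expect_equal(networkDensity(four), 0.4)
})

test_that("clustering coefficient and hubs match closed forms and the oracle", {
  u <- c("a", "b", "c")
  tri <- coexpressionNetwork(u, rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(clusteringStats(tri)$meanClusteringCoefficient, 1)

  star <- coexpressionNetwork(letters[1:5],
    cbind(rep("a", 4), letters[2:5]))
  cs <- clusteringStats(star)
  expect_equal(cs$meanClusteringCoefficient, 0)  # centre 0, leaves excluded

  # random graph vs the triple loop
  set.seed(61)
  u40 <- sprintf("n%02d", 1:40)
  pairs <- t(combn(u40, 2))
  net <- coexpressionNetwork(u40, pairs[sample(nrow(pairs), 80), ])
  adj <- matrix(0, 40, 40, dimnames = list(u40, u40))
  e <- edges(net)
  adj[cbind(e[, 1], e[, 2])] <- 1
  adj[cbind(e[, 2], e[, 1])] <- 1
  expect_equal(clusteringStats(net)$meanClusteringCoefficient,
               oracle_clustering(adj), tolerance = 1e-12)

  # hub threshold is reported and respected
  cs2 <- clusteringStats(star, hubDegree = 3)
  expect_identical(cs2$hubCount, 1L)  # only the centre exceeds degree 3
  expect_identical(cs2$hubThreshold, 3)
})

test_that("module size summaries handle modules, grey genes and boundaries", {
  labels <- c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 2L, g5 = 2L, g6 = 2L,
              g7 = 2L, g8 = 2L, g9 = 0L, g10 = 0L)
  asg <- new("ModuleAssignment", labels = labels, cutHeight = 0.9,
             minModuleSize = 3L)
  ms <- moduleSizeStats(asg)
  expect_equal(ms$meanModuleSize, 4)
  expect_identical(ms$nUnassigned, 2L)

  all_grey <- new("ModuleAssignment",
                  labels = setNames(rep(0L, 5), paste0("g", 1:5)),
                  cutHeight = 0.2, minModuleSize = 3L)
  ms2 <- moduleSizeStats(all_grey)
  expect_true(is.nan(ms2$meanModuleSize))
  expect_identical(ms2$nUnassigned, 5L)

  one <- new("ModuleAssignment",
             labels = setNames(rep(1L, 6), paste0("g", 1:6)),
             cutHeight = 0.9, minModuleSize = 3L)
  expect_equal(moduleSizeStats(one)$meanModuleSize, 6)
  expect_identical(moduleSizeStats(one)$nUnassigned, 0L)
})

test_that("evaluateNetwork assembles a coherent report", {
  u <- letters[1:5]
  net <- coexpressionNetwork(u, rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                                      c("d", "e")))
  gt <- groundTruthEdges(rbind(c("a", "b"), c("d", "e"), c("a", "d")))
  rep <- evaluateNetwork(net, gt)
  df <- as.data.frame(rep)
  expect_identical(df$tp, 2L)
  expect_identical(df$fp, 2L)
  expect_identical(df$fn, 1L)
  expect_equal(df$fdr, 0.5)
  expect_equal(df$fnr, 1 / 3)
  expect_identical(df$n_edges, 4L)
  expect_equal(df$density, 0.4)
})
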