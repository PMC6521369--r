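test_that("glasso is empty above the correlation threshold and exact at lambda -> 0", {
  x <- rand_expr(5, 1000, seed = 50)
  S <- cor(t(x))
  lam_max <- max(abs(S[upper.tri(S)]))
  net <- glassoNetwork(x, lam_max + 0.01)
  expect_identical(nEdges(net), 0L)

  fit <- glassoPrecision(S, 1e-4, convergenceTol = 1e-7)
  expect_lt(max(abs(fit$theta - solve(S))), 5e-3)
})

test_that("glasso matches brute-force numerical optimization on 3-variable instances", {
  set.seed(51)
  worst <- 0
  for (k in 1:5) {
    S <- cor(t(matrix(rnorm(3 * 40), 3, 40)))
    for (rho in c(0.02, 0.1, 0.3)) {
      fit <- glassoPrecision(S, rho, convergenceTol = 1e-7)
      worst <- max(worst, max(abs(fit$theta - oracle_glasso3(S, rho))))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("glasso solutions are symmetric, positive definite, and optimal", {
  x <- rand_expr(8, 200, seed = 52)
  S <- cor(t(x))
  for (rho in c(0.1, 0.3, 0.6)) {
    fit <- glassoPrecision(S, rho, convergenceTol = 1e-6)
    th <- fit$theta
    expect_lt(max(abs(th - t(th))), 1e-12)
    expect_gt(min(eigen(th, symmetric = TRUE, only.values = TRUE)$values), 0)
    # penalized likelihood at the estimate beats the unpenalized MLE point
    expect_lte(glasso_objective(th, S, rho),
               glasso_objective(solve(S), S, rho) + 1e-6)
  }
})

test_that("penalty path: monotone edge counts, endpoints, warm-start consistency", {
  truth <- simulateScaleFree(nGenes = 60, nSamples = 80, nConfounders = 1,
                             affectedFraction = 0.5, confounderSd = 2,
                             seed = 53)
  x <- confoundedExpr(truth)
  S <- cor(t(x))
  lam_max <- max(abs(S[upper.tri(S)]))
  lams <- c(lam_max + 0.01, 0.7, 0.5, 0.3, 0.15)
  path <- glassoPath(x, lams)
  counts <- vapply(path, nEdges, 1L)
  expect_true(all(diff(counts) >= 0))         # decreasing lambda adds edges
  expect_identical(counts[[1]], 0L)           # empty at the top
  expect_gt(counts[[length(counts)]], 0L)     # dense at the bottom

  # warm-started path point equals a cold solve within 10x the tolerance
  cold <- glassoNetwork(x, 0.3)
  warm <- path[["lambda=0.3"]]
  expect_lt(max(abs(attr(warm, "fit")$theta - attr(cold, "fit")$theta)),
            10 * 1e-4)
  expect_identical(.pcnet_keys(edges(warm)), .pcnet_keys(edges(cold)))

  # a single-lambda path is a single call
  single <- glassoPath(x, 0.5)[[1]]
  expect_identical(edges(single), edges(glassoNetwork(x, 0.5)))
})

test_that("signed adjacency hits its closed-form anchors", {
  set.seed(54)
  base <- rnorm(30)
  x <- rbind(g1 = base, g2 = base, g3 = -base,
             g4 = rnorm(30))
  colnames(x) <- paste0("s", 1:30)
  a <- signedAdjacency(x, beta = 6)
  expect_equal(a["g1", "g2"], 1, tolerance = 1e-12)          # cor = 1
  expect_equal(a["g1", "g3"], 0, tolerance = 1e-12)          # cor = -1
  expect_true(all(a >= 0 & a <= 1))
  expect_true(isSymmetric(unname(a)))
  expect_true(all(diag(a) == 1))

  # beta = 1 equals the hand formula on a random 4-gene toy
  y <- rand_expr(4, 25, seed = 55)
  a1 <- signedAdjacency(y, beta = 1)
  expect_equal(unname(a1), unname((1 + cor(t(y))) / 2), tolerance = 1e-12)
  # cor = 0 anchor: adjacency 0.5^beta
  expect_equal(((1 + 0) / 2)^6, 0.5^6)
})

test_that("TOM similarity matches its closed forms and the triple-loop oracle", {
  # 2 genes: no shared neighbours, tom = a_12
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2,
               dimnames = list(c("g1", "g2"), c("g1", "g2")))
  expect_equal(tomSimilarity(a2)["g1", "g2"], 0.4, tolerance = 1e-12)

  # identical binary rows with a_ij = 1 -> maximal overlap, tom = 1
  a3 <- matrix(0, 4, 4); diag(a3) <- 1
  a3[1, 2] <- a3[2, 1] <- 1          # the pair itself
  a3[1, 3] <- a3[3, 1] <- a3[2, 3] <- a3[3, 2] <- 1  # shared neighbour
  dimnames(a3) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(tomSimilarity(a3)["g1", "g2"], 1, tolerance = 1e-12)

  # random matrices vs the literal triple loop
  for (s in 1:3) {
    set.seed(56 + s)
    r <- matrix(runif(36), 6, 6)
    a <- (r + t(r)) / 2; diag(a) <- 1
    dimnames(a) <- list(paste0("g", 1:6), paste0("g", 1:6))
    tom <- tomSimilarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
  }
})

make_block_expr <- function(sizes, ns = 60, noise = 0.1, seed = 57) {
  set.seed(seed)
  rows <- lapply(seq_along(sizes), function(b) {
    base <- rnorm(ns)
    t(vapply(seq_len(sizes[b]), function(i) base + rnorm(ns, sd = noise),
             numeric(ns)))
  })
  x <- do.call(rbind, rows)
  dimnames(x) <- list(paste0("g", seq_len(nrow(x))), paste0("s", 1:ns))
  x
}

test_that("module detection: perfect blocks, boundary cuts, and the merge oracle", {
  # two perfect blocks: within-tom 1, between 0
  tom <- matrix(0, 8, 8)
  tom[1:4, 1:4] <- 1; tom[5:8, 5:8] <- 1
  dimnames(tom) <- list(paste0("g", 1:8), paste0("g", 1:8))
  asg <- detectModules(tom, cutHeight = 0.5, minModuleSize = 3)
  expect_identical(length(unique(moduleLabels(asg)[moduleLabels(asg) > 0])), 2L)
  expect_identical(sum(moduleLabels(asg) == 0), 0L)

  # cut below all merge heights: all singletons -> all unassigned
  x <- make_block_expr(c(10, 10, 10))
  tom2 <- tomSimilarity(signedAdjacency(x, beta = 2))
  tree <- hclust(as.dist(1 - tom2), method = "average")
  low <- min(tree$height) / 2
  asg2 <- detectModules(tom2, cutHeight = low, minModuleSize = 5)
  expect_identical(sum(moduleLabels(asg2) == 0), 30L)

  # static cut equals the independent union-find over merges <= h
  for (h in c(0.3, 0.6, 0.9)) {
    asg3 <- detectModules(tom2, cutHeight = h, minModuleSize = 1)
    oracle <- oracle_static_cut(tree, h)
    # same partition up to label permutation
    expect_identical(unname(table(table(moduleLabels(asg3)))),
                     unname(table(table(oracle))))
    cross <- table(moduleLabels(asg3), oracle[names(moduleLabels(asg3))])
    expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))
  }
})

test_that("modules become cliques; unassigned genes contribute nothing", {
  labels <- c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 2L, g5 = 2L, g6 = 2L,
              g7 = 2L, g8 = 0L)
  asg <- new("ModuleAssignment", labels = labels, cutHeight = 0.9,
             minModuleSize = 3L)
  net <- modulesToNetwork(asg)
  expect_identical(nEdges(net), 3L + 6L)  # sizes {3, 4} -> 3 + 6 edges

  none <- new("ModuleAssignment",
              labels = setNames(rep(0L, 4), paste0("g", 1:4)),
              cutHeight = 0.1, minModuleSize = 3L)
  expect_identical(nEdges(modulesToNetwork(none)), 0L)
})

test_that("cut-height path reuses one clustering and grows monotonically", {
  x <- make_block_expr(c(12, 12, 12), seed = 58)
  path <- wgcnaPath(x, beta = 4, cutHeights = c(0.3, 0.6, 0.9, 1),
                    minModuleSize = 5)
  counts <- vapply(path, function(pt) nEdges(pt$network), 1L)
  expect_true(all(diff(counts) >= 0))

  # recomputing a single cut gives identical modules
  tom <- tomSimilarity(signedAdjacency(x, beta = 4))
  asg <- detectModules(tom, cutHeight = 0.6, minModuleSize = 5)
  expect_identical(moduleLabels(asg),
                   moduleLabels(path[["cut=0.6"]]$assignment))

  # the dendrogram root merges everything: cut at 1 spans all blocks
  top <- path[["cut=1"]]$assignment
  expect_identical(length(unique(moduleLabels(top))), 1L)
  expect_true(all(moduleLabels(top) == 1L))
})
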