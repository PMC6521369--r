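# Independent brute-force oracles and shared fixtures. Oracles deliberately
# use a different computational route than the package implementation.

.pcnet_keys <- function(pairs) {
  if (nrow(pairs)) paste(pairs[, 1L], pairs[, 2L], sep = "|") else character()
}

rand_expr <- function(ng, ns, seed = 1L, prefix = "g") {
  set.seed(seed)
  matrix(rnorm(ng * ns), ng, ns,
         dimnames = list(paste0(prefix, seq_len(ng)),
                         paste0("s", seq_len(ns))))
}

# penalized negative log-likelihood (to MINIMIZE), off-diagonal penalty
glasso_objective <- function(theta, S, rho) {
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(1e12)  # infeasible; finite so optimize() stays quiet
  as.numeric(-determinant(theta, logarithm = TRUE)$modulus) +
    sum(S * theta) + rho * (sum(abs(theta)) - sum(abs(diag(theta))))
}

# brute-force solver for 3-variable instances: cyclic one-dimensional
# numerical minimization over the 6 free entries of the symmetric matrix
oracle_glasso3 <- function(S, rho) {
  p <- nrow(S)
  theta <- diag(1 / diag(S))
  idx <- rbind(cbind(seq_len(p), seq_len(p)), t(combn(p, 2L)))
  for (it in 1:300) {
    old <- theta
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      f <- function(v) {
        t2 <- theta
        t2[i, j] <- v; t2[j, i] <- v
        glasso_objective(t2, S, rho)
      }
      opt <- optimize(f, lower = theta[i, j] - 2, upper = theta[i, j] + 2,
                      tol = 1e-12)
      theta[i, j] <- opt$minimum; theta[j, i] <- opt$minimum
    }
    if (max(abs(theta - old)) < 1e-11) break
  }
  theta
}

# triple-loop TOM, following the formula literally
oracle_tom <- function(a) {
  p <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# triple-loop local clustering coefficients (nodes with degree >= 2)
oracle_clustering <- function(adj) {
  p <- nrow(adj)
  deg <- rowSums(adj)
  vals <- c()
  for (i in seq_len(p)) {
    if (deg[i] < 2) next
    tri <- 0
    for (u in seq_len(p)) for (v in seq_len(p)) {
      if (u < v && adj[i, u] == 1 && adj[i, v] == 1 && adj[u, v] == 1)
        tri <- tri + 1
    }
    vals <- c(vals, tri / choose(deg[i], 2))
  }
  if (length(vals)) mean(vals) else NaN
}

# double-loop confusion counting over all pairs in the universe
oracle_confusion <- function(net, truth, universe) {
  e <- edges(net); tpp <- truthPairs(truth)
  ekeys <- if (nrow(e)) paste(e[, 1], e[, 2]) else character()
  tkeys <- if (nrow(tpp)) paste(tpp[, 1], tpp[, 2]) else character()
  u <- sort(universe)
  tp <- fp <- fn <- 0L
  for (i in seq_along(u)) for (j in seq_along(u)) {
    if (i >= j) next
    key <- paste(u[i], u[j])
    ine <- key %in% ekeys
    int <- key %in% tkeys
    if (ine && int) tp <- tp + 1L
    if (ine && !int) fp <- fp + 1L
    if (!ine && int) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

# static dendrogram cut re-implemented independently: union-find over the
# hclust merge list, keeping only merges at height <= h
oracle_static_cut <- function(tree, h) {
  n <- length(tree$order)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  rep_obs <- integer(nrow(tree$merge))  # one observation inside each cluster
  for (m in seq_len(nrow(tree$merge))) {
    ch <- tree$merge[m, ]
    obs <- vapply(ch, function(v) if (v < 0L) -v else rep_obs[v], 1L)
    rep_obs[m] <- obs[1L]
    if (tree$height[m] <= h) {
      parent[find(obs[2L])] <- find(obs[1L])
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  out <- match(comp, unique(comp))
  names(out) <- tree$labels
  out
}

# ---- shared heavy computations (memoized across test files) ----

.pcnet_test_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .pcnet_test_cache)) {
    assign(key, fn(), envir = .pcnet_test_cache)
  }
  get(key, envir = .pcnet_test_cache)
}

# zero rate of the PC-count estimator on 100 iid-noise replicates
null_calibration_rate <- function() memo("nullcal", function() {
  zeros <- vapply(1:100, function(s) {
    x <- rand_expr(100, 60, seed = 4000 + s)
    estimateNumPC(x, seed = 5000 + s) == 0L
  }, logical(1L))
  mean(zeros)
})

# planted-factor recovery: fraction of 50 replicates within +/-1 of k,
# factor sd 10x noise sd, 200 genes x 80 samples
factor_recovery_rates <- function() memo("recovery", function() {
  vapply(c(1L, 3L, 5L), function(k) {
    hits <- vapply(1:50, function(s) {
      set.seed(60000 + 997L * k + s)
      g <- 200L; n <- 80L
      x <- matrix(rnorm(g * k), g, k) %*% t(matrix(rnorm(n * k), n, k)) * 10 +
        matrix(rnorm(g * n), g, n)
      dimnames(x) <- list(paste0("g", 1:g), paste0("s", 1:n))
      abs(estimateNumPC(x, seed = s) - k) <= 1L
    }, logical(1L))
    mean(hits)
  }, numeric(1L))
})

# benchmark comparison: 20 seeds at the study conditions (300 genes x 200
# samples, 5 confounders, 30% affected, confounder sd 3), graphical lasso
# FDR and edge counts per penalty for the uncorrected and PC-corrected arms
headline_experiment <- function() memo("headline", function() {
  lambdas <- seq(0.8, 0.3, by = -0.1)
  lapply(1:20, function(s) {
    truth <- simulateScaleFree(seed = 7000 + s)
    gt <- truthEdges(truth)
    unc <- confoundedExpr(truth)
    pc <- residuals(correctExpression(unc, seed = 7100 + s))
    measure <- function(x) {
      path <- glassoPath(x, lambdas)
      t(vapply(path, function(net) {
        cm <- confusionCounts(net, gt)
        c(fdr = edgeFDR(cm[["tp"]], cm[["fp"]]), edges = nEdges(net))
      }, numeric(2L)))
    }
    list(lambdas = lambdas, uncorrected = measure(unc),
         pc_corrected = measure(pc))
  })
})
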