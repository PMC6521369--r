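test_that("standardizeExpression yields exact row means 0 and sds 1", {
  x <- rand_expr(50, 20, seed = 10)
  z <- standardizeExpression(x)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  # idempotence
  expect_equal(standardizeExpression(z), z, tolerance = 1e-12)
  # simple row
  z3 <- standardizeExpression(matrix(c(1, 2, 3), 1, 3,
    dimnames = list("g1", paste0("s", 1:3))))
  expect_equal(as.numeric(z3), c(-1, 0, 1))
  # zero-variance gene is refused by name
  x[3, ] <- 5
  expect_error(standardizeExpression(x), "g3")
})

test_that("pcResidualize: centering at p = 0, saturation at max p", {
  x <- rand_expr(30, 20, seed = 11)
  r0 <- pcResidualize(x, 0)
  expect_equal(residuals(r0), x - rowMeans(x), tolerance = 1e-12)
  expect_identical(numComponents(r0), 0L)

  rmax <- pcResidualize(x, min(dim(x)) - 1L)
  expect_lt(norm(residuals(rmax), "F"), 1e-6 * norm(x, "F"))
})

test_that("pcResidualize matches an independent per-gene least squares", {
  x <- rand_expr(30, 20, seed = 12)
  p <- 4L
  # independent route: eigen-decompose the standardized Gram matrix for the
  # scores, then lm() per gene
  z <- t(scale(t(x)))
  eg <- eigen(crossprod(z), symmetric = TRUE)
  scores <- eg$vectors[, seq_len(p)]
  res <- pcResidualize(x, p)
  expected <- t(apply(x, 1, function(e) residuals(lm(e ~ scores))))
  expect_equal(unname(residuals(res)), unname(expected), tolerance = 1e-8)

  # orthogonality of residuals to every retained score
  ortho <- abs(crossprod(t(residuals(res)), componentScores(res)))
  expect_lt(max(ortho) / norm(x, "F"), 1e-8)

  # variance explained sums to one over the full component set
  expect_equal(sum(varianceExplained(res)), 1, tolerance = 1e-12)
})

test_that("residual variance is non-increasing in p and re-residualizing is a no-op", {
  x <- rand_expr(40, 25, seed = 13)
  vars <- sapply(0:10, function(p) apply(residuals(pcResidualize(x, p)), 1, var))
  expect_true(all(diff(t(vars)) <= 1e-12))  # per gene, decreasing across p

  # regressing the residuals on the same scores again changes nothing
  res <- pcResidualize(x, 5)
  sc <- componentScores(res)
  again <- residuals(res) -
    tcrossprod(residuals(res) %*% sc, sc) -
    rowMeans(residuals(res))
  expect_equal(again, residuals(res), tolerance = 1e-9)
})

test_that("a single dominant component is always detected", {
  set.seed(14)
  base <- rnorm(40)
  x <- matrix(rep(base, each = 100), 100, 40) + rnorm(4000, sd = 0.01)
  dimnames(x) <- list(paste0("g", 1:100), paste0("s", 1:40))
  expect_gte(estimateNumPC(x, seed = 3), 1L)
})

test_that("PC-count estimation is deterministic and calibrated on noise", {
  x <- rand_expr(80, 40, seed = 15)
  expect_identical(estimateNumPC(x, seed = 7), estimateNumPC(x, seed = 7))
  # null calibration: zero rate >= 1 - alpha - 0.05 over 100 replicates
  expect_gte(null_calibration_rate(), 0.85)
})

test_that("planted orthogonal factors are recovered within +/-1", {
  rates <- factor_recovery_rates()  # k = 1, 3, 5 at SNR 10
  expect_true(all(rates >= 0.9))
})

test_that("estimates agree with the sva reference implementation on planted factors", {
  skip_if_not_installed("sva")
  set.seed(16)
  g <- 150L; n <- 60L; k <- 3L
  x <- matrix(rnorm(g * k), g, k) %*% t(matrix(rnorm(n * k), n, k)) * 8 +
    matrix(rnorm(g * n), g, n)
  dimnames(x) <- list(paste0("g", 1:g), paste0("s", 1:n))
  ours <- estimateNumPC(x, seed = 2)
  ref <- sva::num.sv(x, mod = matrix(1, n, 1), method = "be", B = 20,
                     seed = 2)
  expect_lte(abs(ours - ref), 1L)
  expect_identical(ours, k)
})

test_that("correctExpression composes estimation and residualization", {
  # strong single confounder: the removed score matches it almost exactly
  truth <- simulateScaleFree(nGenes = 100, nSamples = 80, nConfounders = 1,
                             affectedFraction = 1, confounderSd = 10,
                             seed = 17)
  corr <- correctExpression(confoundedExpr(truth), seed = 18)
  expect_gte(numComponents(corr), 1L)
  r1 <- abs(cor(componentScores(corr)[, 1], confounderValues(truth)[, 1]))
  expect_gt(r1, 0.9)

  # several confounders: the removed subspace captures them all
  truth2 <- simulateScaleFree(nGenes = 200, nSamples = 150,
                              nConfounders = 3, affectedFraction = 0.5,
                              confounderSd = 5, seed = 19)
  corr2 <- correctExpression(confoundedExpr(truth2), seed = 20)
  expect_gte(numComponents(corr2), 3L)
  resid_cor <- abs(cor(t(residuals(corr2)), confounderValues(truth2)))
  expect_lt(max(resid_cor), 0.05)
})

test_that("covariate residualization matches lm() and validates inputs", {
  x <- rand_expr(40, 25, seed = 21)
  set.seed(22)
  cov <- cbind(RIN = rnorm(25), exonic_rate = rnorm(25))
  rownames(cov) <- colnames(x)

  res <- covariateResidualize(x, cov)
  expected <- t(apply(x, 1, function(e) residuals(lm(e ~ cov))))
  expect_equal(unname(res), unname(expected), tolerance = 1e-9)

  # a gene equal to a covariate is annihilated
  x2 <- x; x2[1, ] <- cov[, "RIN"]
  expect_lt(max(abs(covariateResidualize(x2, cov, "RIN")[1, ])), 1e-10)

  # covariate orthogonal to the intercept and all genes (possible only with
  # fewer genes than samples): residuals = centered input
  xs <- x[1:10, , drop = FALSE]
  ortho <- cbind(o = qr.resid(qr(cbind(1, t(xs))), rnorm(25)))
  rownames(ortho) <- colnames(x)
  expect_equal(covariateResidualize(xs, ortho), xs - rowMeans(xs),
               tolerance = 1e-9)

  # collinear design named, sample mismatch caught
  cov_bad <- cbind(cov, RIN2 = 2 * cov[, "RIN"])
  expect_error(covariateResidualize(x, cov_bad), "RIN2")
  expect_error(covariateResidualize(x, cov[-1, , drop = FALSE]), "missing")
})

test_that("covariate selection keeps signal and drops noise", {
  g <- 500L; n <- 40L
  # null: pure-noise covariate excluded at the 1% threshold (20 seeded runs)
  excl <- vapply(1:20, function(s) {
    x <- rand_expr(g, n, seed = 23000 + s)
    set.seed(24000 + s)
    cov <- cbind(noise = rnorm(n))
    rownames(cov) <- colnames(x)
    length(selectCovariates(x, cov)) == 0L
  }, logical(1L))
  expect_gte(mean(excl), 0.95)

  # signal: covariate injected into 50% of genes at effect sd = noise sd
  x <- rand_expr(g, n, seed = 25)
  set.seed(26)
  cc <- rnorm(n)
  hit <- sample(g, g / 2)
  x[hit, ] <- x[hit, ] + outer(rnorm(length(hit)), cc)
  cov <- cbind(batch = cc, noise = rnorm(n))
  rownames(cov) <- colnames(x)
  sel <- selectCovariates(x, cov)
  expect_identical(as.character(sel), "batch")
  expect_gte(attr(sel, "r2")[["batch"]], 0.01)

  # no filtering at the lower boundary
  expect_setequal(selectCovariates(x, cov, r2Threshold = -Inf),
                  c("batch", "noise"))
})
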