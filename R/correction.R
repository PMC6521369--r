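# Principal-component confounder correction.
#
# The premise: for sparse, scale-free co-expression networks, the broad
# components of an expression matrix capture latent artifacts (batch, RNA
# quality, mapping bias) rather than network signal, so regressing the top
# components out of every gene cleans the data without destroying sparse
# structure. The number of components is chosen by a permutation
# (parallel-analysis) scheme.

#' Standardize an expression matrix gene-wise
#'
#' Centres and scales every gene row to mean 0 and (n-1 denominator)
#' standard deviation 1. Component scores are always computed on this
#' standardized matrix.
#'
#' @param expr genes x samples matrix; every gene must have nonzero
#'   variance (filter constant genes first).
#' @return the standardized matrix.
#' @export
standardizeExpression <- function(expr) {
  expr <- .as_expr(expr)
  sds <- apply(expr, 1L, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[zero], 5L), collapse = ", "),
         if (sum(zero) > 5L) ", ..." else "", call. = FALSE)
  }
  (expr - rowMeans(expr)) / sds
}

# Proportion of total variance per component of the standardized matrix.
.pc_proportions <- function(z) {
  d <- svd(z, nu = 0L, nv = 0L)$d
  d^2 / sum(d^2)
}

#' Estimate the number of significant principal components by permutation
#'
#' Parallel analysis in the Buja–Eyuboglu style: the observed per-component
#' variance-explained proportions of the standardized matrix are compared
#' with proportions from matrices in which every gene row is independently
#' permuted across samples — breaking all gene–gene correlation while
#' preserving each gene's marginal distribution. Component `i` is called
#' significant when its permutation p-value
#' `(1 + #\{permuted_i >= observed_i\}) / (n_permutations + 1)` is at most
#' `alpha`; p-values are made monotone non-decreasing across components
#' before thresholding, and the returned count is the length of the longest
#' prefix of significant components. Deterministic given `seed`.
#'
#' @param expr genes x samples matrix (>= 2 genes, >= 3 samples).
#' @param nPermutations number of row-permuted replicates (default 20).
#' @param alpha significance level in (0,1) (default 0.10).
#' @param seed integer seed; replicate `b` uses `seed + b` so permutations
#'   are reproducible individually.
#' @return non-negative integer: the number of components to remove.
#' @export
estimateNumPC <- function(expr, nPermutations = 20L, alpha = 0.10,
                          seed = 1L) {
  expr <- .as_expr(expr)
  if (nrow(expr) < 2L || ncol(expr) < 3L) {
    stop("need at least 2 genes and 3 samples")
  }
  nPermutations <- as.integer(nPermutations)
  stopifnot(nPermutations >= 1L, alpha > 0, alpha < 1)
  z <- standardizeExpression(expr)
  obs <- .pc_proportions(z)
  if (sum(obs > 1e-12) < 2L) stop("matrix has rank < 2")
  exceed <- integer(length(obs))
  for (b in seq_len(nPermutations)) {
    zp <- .with_seed(.sub_seed(seed, b), t(apply(z, 1L, sample)))
    perm <- .pc_proportions(zp)
    exceed <- exceed + as.integer(perm >= obs)
  }
  pval <- cummax((exceed + 1) / (nPermutations + 1))
  sig <- pval <= alpha
  if (!sig[1L]) return(0L)
  as.integer(sum(sig))   # sig is a prefix after monotonization
}

#' Remove the top p principal components from every gene
#'
#' Component scores `L` are the first `p` right-singular vectors of the
#' standardized matrix (sample-space scores, orthonormal and orthogonal to
#' the intercept). Each gene's original-scale expression is regressed on
#' `[1, L]` by ordinary least squares and replaced by its residual, so the
#' residuals are exactly mean-centred and orthogonal to every removed
#' score. With `p = 0` this reduces to per-gene mean-centring.
#'
#' Components are extracted from the *standardized* matrix but the
#' regression is run on the *original* scale; set
#' `residualizeStandardized = TRUE` to residualize the standardized matrix
#' instead.
#'
#' @param expr genes x samples matrix.
#' @param p number of components to remove,
#'   `0 <= p <= min(genes, samples) - 1`.
#' @param residualizeStandardized regress the standardized rather than the
#'   original matrix (default `FALSE`).
#' @return a [PCCorrection-class].
#' @export
pcResidualize <- function(expr, p, residualizeStandardized = FALSE) {
  expr <- .as_expr(expr)
  p <- as.integer(p)
  pmax_allowed <- min(dim(expr)) - 1L
  if (length(p) != 1L || is.na(p) || p < 0L || p > pmax_allowed) {
    stop("`p` must be in [0, ", pmax_allowed, "]")
  }
  z <- standardizeExpression(expr)
  sv <- svd(z, nu = 0L, nv = p)
  ve <- sv$d^2 / sum(sv$d^2)
  target <- if (residualizeStandardized) z else expr
  mu <- rowMeans(target)
  centred <- target - mu
  if (p > 0L) {
    scores <- sv$v[, seq_len(p), drop = FALSE]
    # deterministic sign: largest-magnitude entry of each score positive
    for (j in seq_len(p)) {
      k <- which.max(abs(scores[, j]))
      if (scores[k, j] < 0) scores[, j] <- -scores[, j]
    }
    rownames(scores) <- colnames(expr)
    colnames(scores) <- paste0("PC", seq_len(p))
    beta <- centred %*% scores          # scores orthonormal, centred rows
    resid <- centred - beta %*% t(scores)
  } else {
    scores <- matrix(numeric(), nrow = ncol(expr), ncol = 0L,
                     dimnames = list(colnames(expr), NULL))
    beta <- matrix(numeric(), nrow = nrow(expr), ncol = 0L,
                   dimnames = list(rownames(expr), NULL))
    resid <- centred
  }
  dimnames(resid) <- dimnames(expr)
  if (p > 0L) dimnames(beta) <- list(rownames(expr), colnames(scores))
  methods::new("PCCorrection", residuals = resid, p = p, scores = scores,
               varianceExplained = ve, intercepts = mu,
               coefficients = beta)
}

#' Estimate and remove significant principal components
#'
#' Convenience composition: `p` from [estimateNumPC()], residuals from
#' [pcResidualize()], with `p` recorded in the result. This is the full
#' confounder-correction step to run before network reconstruction.
#'
#' @inheritParams estimateNumPC
#' @inheritParams pcResidualize
#' @return a [PCCorrection-class].
#' @export
correctExpression <- function(expr, nPermutations = 20L, alpha = 0.10,
                              seed = 1L, residualizeStandardized = FALSE) {
  p <- estimateNumPC(expr, nPermutations = nPermutations, alpha = alpha,
                     seed = seed)
  pcResidualize(expr, p,
                residualizeStandardized = residualizeStandardized)
}

# Align a covariate table to the expression samples and return the
# requested design columns.
.covariate_design <- function(expr, cov, names) {
  if (is.null(rownames(cov))) stop("covariate table must have sample rownames")
  missing_cov <- setdiff(names, colnames(cov))
  if (length(missing_cov)) {
    stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  missing_smp <- setdiff(colnames(expr), rownames(cov))
  if (length(missing_smp)) {
    stop("sample(s) missing from covariate table: ",
         paste(utils::head(missing_smp, 5L), collapse = ", "))
  }
  cov[colnames(expr), names, drop = FALSE]
}

#' Residualize expression on measured covariates
#'
#' Per-gene ordinary least squares of expression on the named covariates
#' jointly (with intercept); returns the residual matrix with the original
#' ids. This is the baseline correction route: e.g. regressing out RIN,
#' exonic rate, or GC bias, singly or as a multi-covariate set.
#'
#' @param expr genes x samples matrix.
#' @param cov samples x covariates numeric matrix (sample rownames), as
#'   from [readCovariates()].
#' @param names covariates to regress out (default: all columns of `cov`).
#' @return genes x samples residual matrix.
#' @export
covariateResidualize <- function(expr, cov, names = colnames(cov)) {
  expr <- .as_expr(expr)
  x <- .covariate_design(expr, cov, names)
  design <- cbind(`(Intercept)` = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("rank-deficient design; collinear covariate(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  resid <- t(qr.resid(qrd, t(expr)))
  dimnames(resid) <- dimnames(expr)
  resid
}

#' Select covariates that explain expression variance
#'
#' Each covariate is fit singly against every gene by simple linear
#' regression; the per-gene adjusted R-squared values are aggregated across
#' genes (mean by default) and covariates whose aggregate is at least
#' `r2Threshold` are returned, e.g. the "explains at least 1% of expression
#' variance" rule at the default threshold of 0.01.
#'
#' @inheritParams covariateResidualize
#' @param r2Threshold minimum aggregate adjusted R-squared (default 0.01).
#' @param aggregate `"mean"` (default) or `"median"` across genes.
#' @return character vector of selected covariate names (possibly empty),
#'   with the aggregate adjusted R-squared as a `"r2"` attribute.
#' @export
selectCovariates <- function(expr, cov, r2Threshold = 0.01,
                             aggregate = c("mean", "median")) {
  expr <- .as_expr(expr)
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  x <- .covariate_design(expr, cov, colnames(cov))
  n <- ncol(expr)
  if (n < 3L) stop("need at least 3 samples")
  gene_sd <- apply(expr, 1L, stats::sd)
  usable <- gene_sd > 0
  r2 <- vapply(seq_len(ncol(x)), function(j) {
    cj <- x[, j]
    if (stats::sd(cj) == 0) return(-Inf)  # constant covariate explains nothing
    r <- stats::cor(t(expr[usable, , drop = FALSE]), cj)
    adj <- 1 - (1 - r^2) * (n - 1) / (n - 2)
    agg_fun(adj)
  }, numeric(1L))
  names(r2) <- colnames(x)
  keep <- colnames(x)[r2 >= r2Threshold]
  attr(keep, "r2") <- r2
  keep
}
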