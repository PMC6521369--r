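# Scale-free Gaussian graphical model simulator with injected confounders.
#
# The generative model mirrors the benchmark setting: (1) a Barabasi-Albert
# preferential-attachment graph supplies a scale-free conditional-dependence
# structure; (2) a precision matrix is built on exactly that support with
# random edge weights and a diagonal-dominance repair guaranteeing positive
# definiteness; (3) expression is drawn iid from the corresponding
# multivariate Gaussian; (4) latent confounders are added as a low-rank
# term loadings %*% t(confounders) touching a random subset of genes.

#' Generate a scale-free gene network
#'
#' Barabasi-Albert preferential attachment via [igraph::sample_pa()]
#' (undirected, no multi-edges); the result is connected by construction
#' and its degree distribution follows a power law. Deterministic given
#' `seed`.
#'
#' @param nGenes number of nodes; must exceed `attachmentEdges`.
#' @param attachmentEdges edges added per new node (`m` of the BA model).
#' @param seed integer seed.
#' @param geneIds optional node names (default `gene0001`, ...).
#' @return symmetric binary adjacency matrix with zero diagonal.
#' @export
scaleFreeGraph <- function(nGenes, attachmentEdges = 1L, seed = 1L,
                           geneIds = NULL) {
  nGenes <- as.integer(nGenes)
  attachmentEdges <- as.integer(attachmentEdges)
  if (nGenes < attachmentEdges + 1L) {
    stop("`nGenes` must be at least `attachmentEdges` + 1")
  }
  g <- .with_seed(seed,
    igraph::sample_pa(nGenes, m = attachmentEdges, directed = FALSE))
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- (adj != 0) * 1L
  if (is.null(geneIds)) {
    geneIds <- sprintf("gene%04d", seq_len(nGenes))
  }
  dimnames(adj) <- list(geneIds, geneIds)
  adj
}

#' Build a positive-definite precision matrix on a given support
#'
#' Off-diagonal entries are drawn uniformly in magnitude from
#' `edgeWeightRange` with random sign, exactly on the adjacency support;
#' the diagonal is then set to the row sum of absolute off-diagonal
#' entries plus `delta` (strict diagonal dominance), which guarantees
#' positive definiteness while preserving the support.
#'
#' @param adjacency symmetric binary matrix, zero diagonal.
#' @param edgeWeightRange interval of positive weight magnitudes
#'   (default `c(0.3, 1)`).
#' @param seed integer seed.
#' @param delta diagonal-dominance margin (default 0.1).
#' @return symmetric positive-definite matrix with the same dimnames.
#' @export
graphToPrecision <- function(adjacency, edgeWeightRange = c(0.3, 1),
                             seed = 1L, delta = 0.1) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency)) || any(diag(adjacency) != 0)) {
    stop("adjacency must be symmetric with zero diagonal")
  }
  stopifnot(length(edgeWeightRange) == 2L, all(edgeWeightRange > 0),
            edgeWeightRange[1L] <= edgeWeightRange[2L])
  p <- nrow(adjacency)
  up <- which(upper.tri(adjacency) & adjacency != 0)
  omega <- matrix(0, p, p, dimnames = dimnames(adjacency))
  if (length(up)) {
    w <- .with_seed(seed, {
      mag <- stats::runif(length(up), edgeWeightRange[1L],
                          edgeWeightRange[2L])
      mag * sample(c(-1, 1), length(up), replace = TRUE)
    })
    omega[up] <- w
    omega <- omega + t(omega)
  }
  diag(omega) <- rowSums(abs(omega)) + delta
  omega
}

#' Draw expression from a Gaussian graphical model
#'
#' `nSamples` iid draws from the zero-mean multivariate normal whose
#' precision (inverse covariance) matrix is given, via the Cholesky factor
#' of the precision. Deterministic given `seed`.
#'
#' @param precision symmetric positive-definite genes x genes matrix.
#' @param nSamples number of samples.
#' @param geneIds gene names (default: rownames of `precision`).
#' @param seed integer seed.
#' @return genes x samples expression matrix.
#' @export
sampleExpression <- function(precision, nSamples, geneIds = NULL,
                             seed = 1L) {
  precision <- as.matrix(precision)
  nSamples <- as.integer(nSamples)
  p <- nrow(precision)
  ch <- tryCatch(chol(precision),
                 error = function(e) stop("precision matrix is not positive definite",
                                          call. = FALSE))
  z <- .with_seed(seed, matrix(stats::rnorm(p * nSamples), p, nSamples))
  x <- backsolve(ch, z)  # cov(x) = solve(precision)
  if (is.null(geneIds)) geneIds <- rownames(precision)
  if (is.null(geneIds)) geneIds <- sprintf("gene%04d", seq_len(p))
  dimnames(x) <- list(geneIds, sprintf("sample%04d", seq_len(nSamples)))
  x
}

#' Inject latent confounders into clean expression
#'
#' For each confounder: per-sample values are drawn Normal(0,
#' `confounderSd`^2); a uniformly random subset of
#' `round(affectedFraction * nGenes)` genes is affected, with per-gene
#' loadings drawn Normal(0, 1) (zero for unaffected genes). The confounded
#' matrix is `clean + loadings %*% t(confounders)`. Affected subsets are
#' drawn independently per confounder and may overlap.
#'
#' @param clean genes x samples expression matrix.
#' @param nConfounders number of latent confounders (0 returns `clean`
#'   unchanged).
#' @param affectedFraction fraction of genes each confounder touches, in
#'   `[0, 1]`.
#' @param confounderSd standard deviation of confounder values across
#'   samples.
#' @param seed integer seed.
#' @param adjacency,precision optional true network structure carried
#'   through into the returned truth object.
#' @return a [SimulationTruth-class].
#' @export
injectConfounders <- function(clean, nConfounders, affectedFraction,
                              confounderSd = 1, seed = 1L,
                              adjacency = NULL, precision = NULL) {
  clean <- .as_expr(clean, arg = "clean")
  nConfounders <- as.integer(nConfounders)
  stopifnot(nConfounders >= 0L,
            affectedFraction >= 0, affectedFraction <= 1,
            confounderSd > 0)
  ng <- nrow(clean)
  ns <- ncol(clean)
  n_aff <- as.integer(round(affectedFraction * ng))
  if (nConfounders > 0L && n_aff < 1L) {
    stop("affectedFraction * nGenes must be >= 1 when confounders are injected")
  }
  conf <- matrix(0, ns, nConfounders,
                 dimnames = list(colnames(clean),
                                 if (nConfounders) paste0("conf", seq_len(nConfounders))))
  load <- matrix(0, ng, nConfounders,
                 dimnames = list(rownames(clean), colnames(conf)))
  if (nConfounders > 0L) {
    .with_seed(seed, {
      for (k in seq_len(nConfounders)) {
        conf[, k] <- stats::rnorm(ns, sd = confounderSd)
        aff <- sample.int(ng, n_aff)
        load[aff, k] <- stats::rnorm(n_aff)
      }
    })
  }
  confounded <- clean + load %*% t(conf)
  methods::new("SimulationTruth",
               adjacency = if (is.null(adjacency)) matrix(0, 0, 0) else as.matrix(adjacency),
               precision = if (is.null(precision)) matrix(0, 0, 0) else as.matrix(precision),
               confounders = conf, loadings = load,
               cleanExpr = clean, confoundedExpr = confounded)
}

#' Simulate confounded expression from a scale-free network
#'
#' Full generative pipeline: scale-free graph, precision construction,
#' Gaussian sampling, confounder injection. One master seed drives all
#' stages through fixed offsets (graph +1, weights +2, samples +3,
#' confounders +4), so each stage is independently reproducible.
#'
#' The defaults are the benchmark study conditions: 300 genes, 200
#' samples, 5 confounders each touching 30% of genes with confounder sd 3.
#'
#' @param nGenes,nSamples dimensions of the expression matrix.
#' @param attachmentEdges preferential-attachment edges per node.
#' @param edgeWeightRange precision edge-weight magnitude interval.
#' @param nConfounders,affectedFraction,confounderSd confounder model; see
#'   [injectConfounders()].
#' @param seed master integer seed.
#' @return a [SimulationTruth-class].
#' @export
simulateScaleFree <- function(nGenes = 300L, nSamples = 200L,
                              attachmentEdges = 1L,
                              edgeWeightRange = c(0.3, 1),
                              nConfounders = 5L, affectedFraction = 0.3,
                              confounderSd = 3, seed = 1L) {
  adj <- scaleFreeGraph(nGenes, attachmentEdges, seed = .sub_seed(seed, 1))
  omega <- graphToPrecision(adj, edgeWeightRange, seed = .sub_seed(seed, 2))
  clean <- sampleExpression(omega, nSamples, seed = .sub_seed(seed, 3))
  injectConfounders(clean, nConfounders, affectedFraction, confounderSd,
                    seed = .sub_seed(seed, 4),
                    adjacency = adj, precision = omega)
}

#' Small fixed simulation instance for examples and tests
#'
#' 20 genes x 50 samples from a preferential-attachment tree, with one
#' confounder touching half the genes at sd 3. Byte-identical across runs
#' for a fixed seed.
#'
#' @param seed integer seed (default 1).
#' @return a [SimulationTruth-class].
#' @export
toyExample <- function(seed = 1L) {
  simulateScaleFree(nGenes = 20L, nSamples = 50L, attachmentEdges = 1L,
                    edgeWeightRange = c(0.5, 1), nConfounders = 1L,
                    affectedFraction = 0.5, confounderSd = 3, seed = seed)
}

#' True network edges of a simulation as ground truth
#'
#' @param truth a [SimulationTruth-class] with a non-empty adjacency.
#' @return a [GroundTruthEdges-class] over the simulated genes
#'   (`dbCount = 1` throughout).
#' @export
truthEdges <- function(truth) {
  stopifnot(methods::is(truth, "SimulationTruth"))
  adj <- trueAdjacency(truth)
  if (length(adj) == 0L) stop("simulation truth has no adjacency")
  ids <- rownames(adj)
  up <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  groundTruthEdges(cbind(ids[up[, 1L]], ids[up[, 2L]]))
}
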