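# Scoring inferred networks against ground truth and computing topology
# diagnostics.
#
# An inferred edge present in the ground-truth pair list is a true
# positive; an inferred edge absent from it is a false positive; a
# ground-truth pair not inferred is a false negative. The truth set is
# restricted to the network's gene universe BEFORE counting, matching the
# convention that all counts are computed over the genes actually used for
# reconstruction.

#' Confusion counts of a network against ground truth
#'
#' @param net a [CoexpressionNetwork-class].
#' @param truth a [GroundTruthEdges-class].
#' @param universe gene ids over which to score (default: the network's
#'   universe). The network's universe must be contained in it.
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
confusionCounts <- function(net, truth, universe = geneUniverse(net)) {
  stopifnot(methods::is(net, "CoexpressionNetwork"),
            methods::is(truth, "GroundTruthEdges"))
  universe <- unique(as.character(universe))
  if (!all(geneUniverse(net) %in% universe)) {
    stop("network gene universe is not contained in `universe`")
  }
  tp_keys <- .pair_keys(truthPairs(truth))
  in_universe <- truthPairs(truth)[, 1L] %in% universe &
    truthPairs(truth)[, 2L] %in% universe
  tp_keys <- tp_keys[in_universe]
  e_keys <- .pair_keys(edges(net))
  tp <- sum(e_keys %in% tp_keys)
  c(tp = tp, fp = length(e_keys) - tp,
    fn = sum(!(tp_keys %in% e_keys)))
}

#' Edge-level false discovery rate
#'
#' `FDR = FP / (TP + FP)`. When no edges were inferred (`TP + FP = 0`) the
#' rate is undefined and `NaN` is returned; such points should be excluded
#' from summary curves, never treated as zero.
#'
#' @param tp,fp non-negative counts.
#' @return numeric scalar in `[0, 1]`, or `NaN` when undefined.
#' @export
edgeFDR <- function(tp, fp) {
  if (tp < 0 || fp < 0) stop("counts must be non-negative")
  if (tp + fp == 0) return(NaN)
  fp / (tp + fp)
}

#' Edge-level false negative rate
#'
#' `FNR = FN / (TP + FN)`; `NaN` when the (restricted) truth set is empty.
#'
#' @param tp,fn non-negative counts.
#' @return numeric scalar in `[0, 1]`, or `NaN` when undefined.
#' @export
edgeFNR <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fn == 0) return(NaN)
  fn / (tp + fn)
}

#' Restrict ground truth to pairs shared across databases
#'
#' Keeps pairs supported by at least `minDatabases` distinct pathway
#' databases — the refined "shared true positive" truth set
#' (default 2).
#'
#' @param truth a [GroundTruthEdges-class].
#' @param minDatabases minimum database support (>= 1).
#' @return a [GroundTruthEdges-class]; db counts of surviving pairs are
#'   preserved.
#' @export
sharedTruth <- function(truth, minDatabases = 2L) {
  stopifnot(methods::is(truth, "GroundTruthEdges"))
  minDatabases <- as.integer(minDatabases)
  if (minDatabases < 1L) stop("`minDatabases` must be >= 1")
  keep <- dbCount(truth) >= minDatabases
  methods::new("GroundTruthEdges",
               pairs = truthPairs(truth)[keep, , drop = FALSE],
               dbCount = dbCount(truth)[keep])
}

#' Network density
#'
#' Edge count over the number of possible pairs in the universe.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param universe gene universe (default: the network's); needs >= 2
#'   genes.
#' @return numeric scalar in `[0, 1]`.
#' @export
networkDensity <- function(net, universe = geneUniverse(net)) {
  stopifnot(methods::is(net, "CoexpressionNetwork"))
  n <- length(unique(as.character(universe)))
  if (n < 2L) stop("universe must contain at least 2 genes")
  nEdges(net) / (n * (n - 1) / 2)
}

#' Clustering coefficient and hub count
#'
#' The local clustering coefficient of a node is its number of closed
#' triangles over `choose(degree, 2)`; nodes of degree < 2 are excluded
#' from the mean (reported as `NaN` when no node qualifies). Hubs are
#' nodes with degree strictly above a threshold: by default the top-5%
#' quantile of the degree distribution over the universe, or an absolute
#' cutoff via `hubDegree`.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param hubQuantile degree quantile defining hubs (default 0.95).
#' @param hubDegree absolute degree cutoff overriding `hubQuantile`.
#' @return list with `meanClusteringCoefficient`, `hubCount`,
#'   `hubThreshold`.
#' @export
clusteringStats <- function(net, hubQuantile = 0.95, hubDegree = NULL) {
  stopifnot(methods::is(net, "CoexpressionNetwork"))
  ids <- geneUniverse(net)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- edges(net)
  if (nrow(e)) {
    A[cbind(e[, 1L], e[, 2L])] <- 1
    A[cbind(e[, 2L], e[, 1L])] <- 1
  }
  deg <- rowSums(A)
  elig <- deg >= 2
  cc <- if (any(elig)) {
    tri <- diag(A %*% A %*% A) / 2            # closed triangles per node
    mean(tri[elig] / choose(deg[elig], 2))
  } else NaN
  thr <- if (!is.null(hubDegree)) as.numeric(hubDegree)
         else as.numeric(stats::quantile(deg, hubQuantile))
  list(meanClusteringCoefficient = cc,
       hubCount = sum(deg > thr),
       hubThreshold = thr)
}

#' Module size summary
#'
#' Mean module size over real modules (excluding unassigned genes) and the
#' number of unassigned (grey-module) genes.
#'
#' @param assignment a [ModuleAssignment-class].
#' @return list with `meanModuleSize` (`NaN` when there are no modules)
#'   and `nUnassigned`.
#' @export
moduleSizeStats <- function(assignment) {
  stopifnot(methods::is(assignment, "ModuleAssignment"))
  labels <- moduleLabels(assignment)
  sizes <- table(labels[labels > 0L])
  list(meanModuleSize = if (length(sizes)) mean(as.numeric(sizes)) else NaN,
       nUnassigned = sum(labels == 0L))
}

#' Full evaluation of one network against one ground truth
#'
#' Combines confusion counts, FDR/FNR, density, and clustering/hub
#' diagnostics into a single report.
#'
#' @inheritParams confusionCounts
#' @inheritParams clusteringStats
#' @return a [NetworkEvalReport-class].
#' @export
evaluateNetwork <- function(net, truth, universe = geneUniverse(net),
                            hubQuantile = 0.95, hubDegree = NULL) {
  cm <- confusionCounts(net, truth, universe)
  cs <- clusteringStats(net, hubQuantile = hubQuantile,
                        hubDegree = hubDegree)
  methods::new("NetworkEvalReport",
               tp = as.integer(cm[["tp"]]), fp = as.integer(cm[["fp"]]),
               fn = as.integer(cm[["fn"]]),
               fdr = edgeFDR(cm[["tp"]], cm[["fp"]]),
               fnr = edgeFNR(cm[["tp"]], cm[["fn"]]),
               nEdges = nEdges(net),
               density = networkDensity(net, universe),
               meanClusteringCoefficient = cs$meanClusteringCoefficient,
               hubCount = as.integer(cs$hubCount),
               params = list(hubThreshold = cs$hubThreshold,
                             hubQuantile = if (is.null(hubDegree)) hubQuantile else NA_real_,
                             clusteringMinDegree = 2L))
}
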