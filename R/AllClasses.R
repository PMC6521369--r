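#' Co-expression network over a declared gene universe
#'
#' An undirected graph whose vertices are gene identifiers and whose edges
#' are unordered gene pairs, stored canonically (lexicographically ordered
#' within each pair, no self-edges). Edges may carry weights, e.g. the
#' estimated precision entries from the graphical lasso.
#'
#' @slot universe character vector of gene ids the network is defined over.
#' @slot edges two-column character matrix of canonical gene pairs.
#' @slot weights numeric vector parallel to the rows of `edges`
#'   (length zero for an unweighted network).
#'
#' @seealso [coexpressionNetwork()], [edges()], [geneUniverse()],
#'   [edgeWeights()]
#' @export
setClass("CoexpressionNetwork",
  representation(universe = "character", edges = "matrix",
                 weights = "numeric"),
  prototype(universe = character(),
            edges = matrix(character(), ncol = 2L,
                           dimnames = list(NULL, c("gene1", "gene2"))),
            weights = numeric())
)

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@universe))
    msg <- c(msg, "gene universe contains duplicates")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-edges are not allowed")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edges must be canonically ordered within pairs")
    if (anyDuplicated(.pair_keys(e))) msg <- c(msg, "duplicate edges")
    if (!all(c(e) %in% object@universe))
      msg <- c(msg, "edge endpoints outside the gene universe")
  }
  if (length(object@weights) > 0L && length(object@weights) != nrow(e))
    msg <- c(msg, "weights length must match edge count")
  if (length(msg)) msg else TRUE
})

#' Ground-truth gene pairs derived from pathway co-membership
#'
#' The set of unordered gene pairs assumed to be true functional
#' relationships:
#' any two genes annotated to at least one common pathway. Each pair records
#' how many distinct source databases support it, so the truth set can be
#' restricted to pairs shared across databases.
#'
#' @slot pairs two-column character matrix of canonical gene pairs.
#' @slot dbCount integer vector, per-pair number of distinct supporting
#'   databases (always >= 1).
#'
#' @seealso [pathwayPairs()], [sharedTruth()]
#' @export
setClass("GroundTruthEdges",
  representation(pairs = "matrix", dbCount = "integer"),
  prototype(pairs = matrix(character(), ncol = 2L,
                           dimnames = list(NULL, c("gene1", "gene2"))),
            dbCount = integer())
)

setValidity("GroundTruthEdges", function(object) {
  msg <- character()
  p <- object@pairs
  if (ncol(p) != 2L) msg <- c(msg, "pairs must have two columns")
  if (nrow(p) > 0L) {
    if (any(p[, 1L] == p[, 2L])) msg <- c(msg, "self-pairs are not allowed")
    if (any(p[, 1L] > p[, 2L]))
      msg <- c(msg, "pairs must be canonically ordered")
    if (anyDuplicated(.pair_keys(p))) msg <- c(msg, "duplicate pairs")
  }
  if (length(object@dbCount) != nrow(p))
    msg <- c(msg, "dbCount length must equal pair count")
  if (length(object@dbCount) && any(object@dbCount < 1L))
    msg <- c(msg, "dbCount must be >= 1 for every stored pair")
  if (length(msg)) msg else TRUE
})

#' Collection of pathway gene sets
#'
#' Named gene sets (pathways) with a database label per set, as parsed from
#' GMT files. Used to build [GroundTruthEdges-class] via [pathwayPairs()].
#'
#' @slot sets named list of character vectors (gene ids per pathway).
#' @slot sourceDb named character vector, database label per pathway.
#'
#' @seealso [readGMT()]
#' @export
setClass("PathwayCollection",
  representation(sets = "list", sourceDb = "character"),
  prototype(sets = list(), sourceDb = character())
)

setValidity("PathwayCollection", function(object) {
  msg <- character()
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "pathway names must be unique")
  if (!identical(names(object@sets), names(object@sourceDb)))
    msg <- c(msg, "sets and sourceDb must share names")
  if (any(vapply(object@sets, anyDuplicated, 1L) > 0L))
    msg <- c(msg, "gene sets must not contain duplicate genes")
  if (length(msg)) msg else TRUE
})

#' Result of principal-component residualization
#'
#' Holds the residual expression matrix after regressing the top `p`
#' principal component scores out of every gene, together with the scores,
#' per-gene regression coefficients, and the per-component proportion of
#' variance explained in the standardized matrix.
#'
#' @slot residuals genes x samples numeric matrix of residuals (original
#'   expression scale, each gene mean-centred).
#' @slot p integer, number of components removed.
#' @slot scores samples x p matrix of component scores used as regressors.
#' @slot varianceExplained numeric vector of length `min(genes, samples)`,
#'   proportion of total (standardized) variance per component.
#' @slot intercepts per-gene fitted intercepts (the gene means).
#' @slot coefficients genes x p matrix of per-gene regression coefficients.
#'
#' @seealso [pcResidualize()], [correctExpression()]
#' @export
setClass("PCCorrection",
  representation(residuals = "matrix", p = "integer", scores = "matrix",
                 varianceExplained = "numeric", intercepts = "numeric",
                 coefficients = "matrix")
)

setValidity("PCCorrection", function(object) {
  msg <- character()
  if (length(object@p) != 1L || object@p < 0L)
    msg <- c(msg, "p must be a single non-negative integer")
  if (ncol(object@scores) != object@p)
    msg <- c(msg, "scores must have p columns")
  if (nrow(object@coefficients) != nrow(object@residuals) ||
      ncol(object@coefficients) != object@p)
    msg <- c(msg, "coefficients must be genes x p")
  if (length(object@intercepts) != nrow(object@residuals))
    msg <- c(msg, "one intercept per gene required")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated confounded expression dataset
#'
#' Captures everything the simulator knows: the true network adjacency, the
#' precision matrix the Gaussian data were drawn from, per-sample confounder
#' values, per-gene confounder loadings (zero rows for unaffected genes),
#' and the clean and confounded expression matrices.
#'
#' @slot adjacency symmetric binary genes x genes matrix of true edges.
#' @slot precision symmetric positive-definite genes x genes matrix.
#' @slot confounders samples x k matrix of confounder values.
#' @slot loadings genes x k matrix of confounder effects per gene.
#' @slot cleanExpr,confoundedExpr genes x samples expression matrices
#'   sharing ids and shape.
#'
#' @seealso [simulateScaleFree()], [injectConfounders()], [toyExample()]
#' @export
setClass("SimulationTruth",
  representation(adjacency = "matrix", precision = "matrix",
                 confounders = "matrix", loadings = "matrix",
                 cleanExpr = "matrix", confoundedExpr = "matrix")
)

setValidity("SimulationTruth", function(object) {
  msg <- character()
  if (!identical(dim(object@cleanExpr), dim(object@confoundedExpr)) ||
      !identical(dimnames(object@cleanExpr), dimnames(object@confoundedExpr)))
    msg <- c(msg, "clean and confounded matrices must share ids and shape")
  ng <- nrow(object@cleanExpr)
  ns <- ncol(object@cleanExpr)
  if (length(object@adjacency) > 0L) {
    if (!isSymmetric(unname(object@adjacency)))
      msg <- c(msg, "adjacency must be symmetric")
    if (length(object@precision) > 0L) {
      supp <- object@precision != 0
      diag(supp) <- FALSE
      if (!identical(unname(supp), unname(object@adjacency != 0)))
        msg <- c(msg, "precision off-diagonal support must equal adjacency")
    }
  }
  if (length(object@confounders) > 0L && nrow(object@confounders) != ns)
    msg <- c(msg, "confounders must have one row per sample")
  if (length(object@loadings) > 0L &&
      (nrow(object@loadings) != ng ||
       ncol(object@loadings) != ncol(object@confounders)))
    msg <- c(msg, "loadings must be genes x n_confounders")
  if (length(msg)) msg else TRUE
})

#' Gene-to-module assignment from a dendrogram cut
#'
#' Labels every gene with a module id (positive integers, numbered by
#' decreasing module size) or 0 for unassigned genes — the "grey module" of
#' weighted co-expression analysis: genes whose cluster at the chosen cut
#' height is smaller than the minimum module size.
#'
#' @slot labels named integer vector over genes; 0 means unassigned.
#' @slot cutHeight the dissimilarity cut height used.
#' @slot minModuleSize minimum cluster size to qualify as a module.
#'
#' @seealso [detectModules()], [modulesToNetwork()], [moduleSizeStats()]
#' @export
setClass("ModuleAssignment",
  representation(labels = "integer", cutHeight = "numeric",
                 minModuleSize = "integer")
)

setValidity("ModuleAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by gene id")
  if (length(object@labels) && any(object@labels < 0L))
    msg <- c(msg, "labels must be >= 0 (0 = unassigned)")
  sizes <- table(object@labels[object@labels > 0L])
  if (length(sizes) && any(sizes < object@minModuleSize))
    msg <- c(msg, "module smaller than minModuleSize")
  if (length(msg)) msg else TRUE
})

#' Evaluation report for one network against one ground truth
#'
#' Confusion counts and derived rates for an inferred network scored
#' against ground-truth gene pairs, plus topology diagnostics. `fdr` and
#' `fnr` are `NaN` (an explicit undefined sentinel) when their denominator
#' is zero; such points are excluded from summary curves rather than being
#' treated as zero.
#'
#' @slot tp,fp,fn confusion counts.
#' @slot fdr false discovery rate FP/(TP+FP), `NaN` when TP+FP = 0.
#' @slot fnr false negative rate FN/(TP+FN), `NaN` when TP+FN = 0.
#' @slot nEdges number of inferred edges.
#' @slot density edge count over possible pairs in the universe.
#' @slot meanClusteringCoefficient mean local clustering coefficient over
#'   nodes of degree >= 2 (`NaN` if there are none).
#' @slot hubCount number of nodes with degree above the hub threshold.
#' @slot params list of thresholds/conventions used.
#'
#' @seealso [evaluateNetwork()], [confusionCounts()], [clusteringStats()]
#' @export
setClass("NetworkEvalReport",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 fdr = "numeric", fnr = "numeric", nEdges = "integer",
                 density = "numeric",
                 meanClusteringCoefficient = "numeric",
                 hubCount = "integer", params = "list")
)
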