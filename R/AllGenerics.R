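#' Accessors for pcnet S4 objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param object a pcnet S4 object.
#' @name pcnet-accessors
NULL

#' @rdname pcnet-accessors
#' @export
setGeneric("geneUniverse", function(object) standardGeneric("geneUniverse"))

#' @rdname pcnet-accessors
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname pcnet-accessors
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))

#' @rdname pcnet-accessors
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' @rdname pcnet-accessors
#' @export
setGeneric("truthPairs", function(object) standardGeneric("truthPairs"))

#' @rdname pcnet-accessors
#' @export
setGeneric("dbCount", function(object) standardGeneric("dbCount"))

#' @rdname pcnet-accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname pcnet-accessors
#' @export
setGeneric("sourceDb", function(object) standardGeneric("sourceDb"))

#' @rdname pcnet-accessors
#' @export
setGeneric("numComponents", function(object) standardGeneric("numComponents"))

#' @rdname pcnet-accessors
#' @export
setGeneric("componentScores",
           function(object) standardGeneric("componentScores"))

#' @rdname pcnet-accessors
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))

#' @rdname pcnet-accessors
#' @export
setGeneric("cleanExpr", function(object) standardGeneric("cleanExpr"))

#' @rdname pcnet-accessors
#' @export
setGeneric("confoundedExpr",
           function(object) standardGeneric("confoundedExpr"))

#' @rdname pcnet-accessors
#' @export
setGeneric("trueAdjacency", function(object) standardGeneric("trueAdjacency"))

#' @rdname pcnet-accessors
#' @export
setGeneric("truePrecision", function(object) standardGeneric("truePrecision"))

#' @rdname pcnet-accessors
#' @export
setGeneric("confounderValues",
           function(object) standardGeneric("confounderValues"))

#' @rdname pcnet-accessors
#' @export
setGeneric("confounderLoadings",
           function(object) standardGeneric("confounderLoadings"))

#' @rdname pcnet-accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname pcnet-accessors
#' @export
setGeneric("cutHeight", function(object) standardGeneric("cutHeight"))

# ---- CoexpressionNetwork ----

#' @rdname pcnet-accessors
setMethod("geneUniverse", "CoexpressionNetwork",
          function(object) object@universe)

#' @rdname pcnet-accessors
setMethod("edges", "CoexpressionNetwork", function(object) object@edges)

#' @rdname pcnet-accessors
setMethod("edgeWeights", "CoexpressionNetwork",
          function(object) object@weights)

#' @rdname pcnet-accessors
setMethod("nEdges", "CoexpressionNetwork",
          function(object) nrow(object@edges))

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", length(object@universe), "genes,",
      nrow(object@edges), "edges",
      if (length(object@weights)) "(weighted)" else "(unweighted)", "\n")
})

# ---- GroundTruthEdges ----

#' @rdname pcnet-accessors
setMethod("truthPairs", "GroundTruthEdges", function(object) object@pairs)

#' @rdname pcnet-accessors
setMethod("dbCount", "GroundTruthEdges", function(object) object@dbCount)

#' @rdname pcnet-accessors
setMethod("nEdges", "GroundTruthEdges",
          function(object) nrow(object@pairs))

setMethod("show", "GroundTruthEdges", function(object) {
  cat("GroundTruthEdges:", nrow(object@pairs), "pairs;",
      sum(object@dbCount >= 2L), "supported by >= 2 databases\n")
})

# ---- PathwayCollection ----

#' @rdname pcnet-accessors
setMethod("geneSets", "PathwayCollection", function(object) object@sets)

#' @rdname pcnet-accessors
setMethod("sourceDb", "PathwayCollection", function(object) object@sourceDb)

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection:", length(object@sets), "gene sets from",
      length(unique(object@sourceDb)), "database(s)\n")
})

# ---- PCCorrection ----

#' @rdname pcnet-accessors
setMethod("numComponents", "PCCorrection", function(object) object@p)

#' @rdname pcnet-accessors
setMethod("componentScores", "PCCorrection", function(object) object@scores)

#' @rdname pcnet-accessors
setMethod("varianceExplained", "PCCorrection",
          function(object) object@varianceExplained)

#' Residual expression matrix of a correction result
#'
#' @param object a [PCCorrection-class].
#' @return genes x samples numeric matrix of residuals.
#' @export
setMethod("residuals", "PCCorrection", function(object) object@residuals)

#' @rdname pcnet-accessors
#' @export
setGeneric("coefficients")

#' @rdname pcnet-accessors
setMethod("coefficients", "PCCorrection",
          function(object) object@coefficients)

setMethod("show", "PCCorrection", function(object) {
  ve <- if (object@p > 0L)
    paste0(" (", paste(sprintf("%.1f%%",
      100 * object@varianceExplained[seq_len(object@p)]), collapse = ", "),
      " of standardized variance)") else ""
  cat("PCCorrection:", nrow(object@residuals), "genes x",
      ncol(object@residuals), "samples;", object@p,
      "component(s) removed", ve, "\n")
})

# ---- SimulationTruth ----

#' @rdname pcnet-accessors
setMethod("cleanExpr", "SimulationTruth", function(object) object@cleanExpr)

#' @rdname pcnet-accessors
setMethod("confoundedExpr", "SimulationTruth",
          function(object) object@confoundedExpr)

#' @rdname pcnet-accessors
setMethod("trueAdjacency", "SimulationTruth",
          function(object) object@adjacency)

#' @rdname pcnet-accessors
setMethod("truePrecision", "SimulationTruth",
          function(object) object@precision)

#' @rdname pcnet-accessors
setMethod("confounderValues", "SimulationTruth",
          function(object) object@confounders)

#' @rdname pcnet-accessors
setMethod("confounderLoadings", "SimulationTruth",
          function(object) object@loadings)

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@cleanExpr), "genes x",
      ncol(object@cleanExpr), "samples;",
      sum(object@adjacency != 0) / 2, "true edges;",
      ncol(object@confounders), "confounder(s)\n")
})

# ---- ModuleAssignment ----

#' @rdname pcnet-accessors
setMethod("moduleLabels", "ModuleAssignment", function(object) object@labels)

#' @rdname pcnet-accessors
setMethod("cutHeight", "ModuleAssignment", function(object) object@cutHeight)

setMethod("show", "ModuleAssignment", function(object) {
  n_mod <- length(unique(object@labels[object@labels > 0L]))
  cat("ModuleAssignment: cut height", object@cutHeight, "->", n_mod,
      "module(s),", sum(object@labels == 0L), "unassigned gene(s)\n")
})

# ---- NetworkEvalReport ----

setMethod("show", "NetworkEvalReport", function(object) {
  cat("NetworkEvalReport: TP", object@tp, "FP", object@fp, "FN", object@fn,
      sprintf("| FDR %.4g FNR %.4g | %d edges, density %.4g\n",
              object@fdr, object@fnr, object@nEdges, object@density))
})

#' Flatten an evaluation report to a one-row data frame
#'
#' @param x a [NetworkEvalReport-class].
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return one-row `data.frame` with the counts, rates and diagnostics.
#' @export
as.data.frame.NetworkEvalReport <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(tp = x@tp, fp = x@fp, fn = x@fn, fdr = x@fdr, fnr = x@fnr,
             n_edges = x@nEdges, density = x@density,
             mean_clustering_coefficient = x@meanClusteringCoefficient,
             hub_count = x@hubCount)
}
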