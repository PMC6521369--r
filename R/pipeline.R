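# End-to-end demonstration pipeline: simulate -> correct -> reconstruct ->
# evaluate, comparing correction arms over a penalty or cut-height path.

#' Version, configuration hash and seed for provenance
#'
#' The hash is the MD5 of the canonical JSON serialisation of the full
#' configuration (every parameter, including defaults the user did not
#' set), so any parameter change — including the seed — changes the hash.
#'
#' @param config named list of run parameters.
#' @return list with `tool`, `version`, `configHash`, `seed`, `config`.
#' @export
versionAndProvenance <- function(config) {
  config <- config[order(names(config))]
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  list(tool = "pcnet",
       version = as.character(utils::packageVersion("pcnet")),
       configHash = unname(tools::md5sum(tmp)),
       seed = config$seed,
       config = config)
}

.eval_row <- function(report, method, arm, param) {
  cbind(data.frame(method = method, arm = arm, param = param,
                   stringsAsFactors = FALSE),
        as.data.frame(report))
}

#' Run the simulation benchmark pipeline
#'
#' Simulates confounded scale-free expression, corrects it (PC correction,
#' optionally also residualization on the true confounder values as a
#' measured-covariate baseline), reconstructs networks for every arm over
#' the full penalty path (graphical lasso) and/or cut-height path (signed
#' co-expression modules), and scores every network against the simulated
#' true edges.
#'
#' @param nGenes,nSamples,attachmentEdges,edgeWeightRange,nConfounders,affectedFraction,confounderSd
#'   simulator settings; see [simulateScaleFree()]. Defaults are the
#'   benchmark study conditions (300 genes x 200 samples, 5 confounders,
#'   30% affected, confounder sd 3).
#' @param method reconstruction route(s): `"glasso"`, `"wgcna"` or both.
#' @param lambdas decreasing graphical lasso penalty path.
#' @param beta,cutHeights,minModuleSize module pipeline settings.
#' @param nPermutations,alpha PC-count estimation settings; see
#'   [estimateNumPC()].
#' @param includeCovariateArm also evaluate residuals on the true
#'   confounder values (the measured-covariate baseline).
#' @param seed master seed.
#' @param outDir optional output directory; when given, writes
#'   `results.tsv`, `summary.tsv` and a `config.json` echo carrying the
#'   tool version, config hash and seed.
#' @return (invisibly when `outDir` is given) list with `results` (tidy
#'   data frame, one row per method x arm x path point), `summary` (per
#'   method x arm medians over defined points), `p` (components removed),
#'   `varianceExplained`, `truth`, `provenance`.
#' @export
runPipeline <- function(nGenes = 300L, nSamples = 200L,
                        attachmentEdges = 1L, edgeWeightRange = c(0.3, 1),
                        nConfounders = 5L, affectedFraction = 0.3,
                        confounderSd = 3,
                        method = "glasso",
                        lambdas = seq(0.8, 0.3, by = -0.1),
                        beta = 6, cutHeights = c(0.9, 0.95, 0.98, 0.99, 0.995),
                        minModuleSize = 30L,
                        nPermutations = 20L, alpha = 0.10,
                        includeCovariateArm = FALSE,
                        seed = 1L, outDir = NULL) {
  method <- match.arg(method, c("glasso", "wgcna"), several.ok = TRUE)
  config <- list(nGenes = nGenes, nSamples = nSamples,
                 attachmentEdges = attachmentEdges,
                 edgeWeightRange = edgeWeightRange,
                 nConfounders = nConfounders,
                 affectedFraction = affectedFraction,
                 confounderSd = confounderSd, method = method,
                 lambdas = lambdas, beta = beta, cutHeights = cutHeights,
                 minModuleSize = minModuleSize,
                 nPermutations = nPermutations, alpha = alpha,
                 includeCovariateArm = includeCovariateArm, seed = seed)
  prov <- versionAndProvenance(config)

  truth <- simulateScaleFree(nGenes = nGenes, nSamples = nSamples,
                             attachmentEdges = attachmentEdges,
                             edgeWeightRange = edgeWeightRange,
                             nConfounders = nConfounders,
                             affectedFraction = affectedFraction,
                             confounderSd = confounderSd, seed = seed)
  gt <- truthEdges(truth)
  confounded <- confoundedExpr(truth)

  corr <- correctExpression(confounded, nPermutations = nPermutations,
                            alpha = alpha, seed = .sub_seed(seed, 101))
  arms <- list(uncorrected = confounded,
               pc_corrected = residuals(corr))
  if (includeCovariateArm && nConfounders > 0L) {
    arms$covariate_corrected <-
      covariateResidualize(confounded, confounderValues(truth))
  }

  rows <- list()
  for (arm in names(arms)) {
    x <- arms[[arm]]
    if ("glasso" %in% method) {
      path <- glassoPath(x, lambdas)
      for (net in path) {
        rows[[length(rows) + 1L]] <-
          .eval_row(evaluateNetwork(net, gt), "glasso", arm,
                    attr(net, "lambda"))
      }
    }
    if ("wgcna" %in% method) {
      path <- wgcnaPath(x, beta = beta, cutHeights = cutHeights,
                        minModuleSize = minModuleSize)
      for (pt in path) {
        rows[[length(rows) + 1L]] <-
          .eval_row(evaluateNetwork(pt$network, gt), "wgcna", arm,
                    pt$cutHeight)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  agg <- split(results, interaction(results$method, results$arm, drop = TRUE))
  summary <- do.call(rbind, lapply(agg, function(d) {
    data.frame(method = d$method[1L], arm = d$arm[1L],
               median_fdr = stats::median(d$fdr[is.finite(d$fdr)]),
               median_fnr = stats::median(d$fnr[is.finite(d$fnr)]),
               total_edges = sum(d$n_edges),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  out <- list(results = results, summary = summary,
              p = numComponents(corr),
              varianceExplained = varianceExplained(corr),
              truth = truth, provenance = prov)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# pcnet %s config=%s seed=%s", prov$version,
                     prov$configHash, seed)
    for (nm in c("results", "summary")) {
      f <- file.path(outDir, paste0(nm, ".tsv"))
      writeLines(stamp, f)
      suppressWarnings(utils::write.table(out[[nm]], f, sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          append = TRUE))
    }
    jsonlite::write_json(
      c(prov[c("tool", "version", "configHash", "seed")],
        list(p = out$p,
             varianceExplainedRemoved =
               out$varianceExplained[seq_len(out$p)],
             config = config)),
      file.path(outDir, "config.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
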