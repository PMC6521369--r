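# Signed weighted co-expression modules: signed adjacency, topological
# overlap, average-linkage clustering with a static dendrogram cut, and
# module-as-clique network interpretation.

#' Signed weighted adjacency
#'
#' `a_ij = ((1 + cor(i, j)) / 2)^beta` with unit diagonal, so perfectly
#' anti-correlated genes get adjacency 0 and perfectly correlated genes 1.
#' Pearson correlation across samples is used throughout.
#'
#' @param expr genes x samples matrix; no zero-variance genes.
#' @param beta positive soft-threshold power (conventional signed-network
#'   default 6).
#' @return symmetric genes x genes matrix with values in `[0, 1]` and unit
#'   diagonal.
#' @export
signedAdjacency <- function(expr, beta = 6) {
  expr <- .as_expr(expr)
  if (beta <= 0) stop("`beta` must be positive")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  a <- ((1 + stats::cor(t(expr))) / 2)^beta
  a[a < 0] <- 0   # guard against rounding just below 0
  a[a > 1] <- 1
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' Unsigned TOM of a weighted adjacency:
#' `tom_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{u != i} a_iu` and `tom_ii = 1`. Two genes
#' are similar when they are directly connected and share neighbours.
#'
#' @param adjacency symmetric matrix with values in `[0, 1]` and unit
#'   diagonal, e.g. from [signedAdjacency()].
#' @return symmetric matrix with values in `[0, 1]` and unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-8)) stop("adjacency must be symmetric")
  if (any(a < 0) || any(a > 1 + 1e-12)) stop("adjacency values must be in [0, 1]")
  if (any(abs(diag(a) - 1) > 1e-12)) stop("adjacency must have unit diagonal")
  a <- (a + t(a)) / 2
  diag(a) <- 1
  p <- nrow(a)
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a            # removes u = i and u = j terms (unit diag)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by a static dendrogram cut
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - tom`;
#' the tree is cut at a fixed height and clusters of at least
#' `minModuleSize` genes become modules (numbered by decreasing size).
#' All other genes are unassigned (label 0) — the grey module. Merge ties
#' are resolved by `hclust`'s deterministic ordering, so results are
#' reproducible.
#'
#' @param tom topological overlap (or any similarity in `[0, 1]`) matrix
#'   with gene dimnames.
#' @param cutHeight dissimilarity cut height in `(0, 1]`.
#' @param minModuleSize minimum genes per module (default 30).
#' @return a [ModuleAssignment-class].
#' @export
detectModules <- function(tom, cutHeight, minModuleSize = 30L) {
  tom <- as.matrix(tom)
  if (is.null(rownames(tom))) stop("`tom` must have gene dimnames")
  if (cutHeight <= 0 || cutHeight > 1) stop("`cutHeight` must be in (0, 1]")
  tree <- hclust(as.dist(1 - tom), method = "average")
  .cut_modules(tree, cutHeight, as.integer(minModuleSize))
}

.cut_modules <- function(tree, cutHeight, minModuleSize) {
  cl <- cutree(tree, h = cutHeight)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  # number surviving modules by decreasing size (ties: first occurrence)
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  labels <- integer(length(cl))
  names(labels) <- names(cl)
  for (i in seq_along(keep)) {
    labels[cl == as.integer(keep[i])] <- i
  }
  methods::new("ModuleAssignment", labels = labels,
               cutHeight = cutHeight,
               minModuleSize = as.integer(minModuleSize))
}

#' Interpret modules as fully connected subgraphs
#'
#' Every within-module gene pair becomes an edge, the standard clique
#' interpretation of co-expression modules; unassigned (grey) genes
#' contribute no edges.
#'
#' @param assignment a [ModuleAssignment-class].
#' @param universe gene universe of the resulting network (default: the
#'   assigned genes).
#' @return an unweighted [CoexpressionNetwork-class].
#' @export
modulesToNetwork <- function(assignment,
                             universe = names(moduleLabels(assignment))) {
  stopifnot(methods::is(assignment, "ModuleAssignment"))
  labels <- moduleLabels(assignment)
  pairs <- lapply(unique(labels[labels > 0L]), function(m) {
    genes <- sort(names(labels)[labels == m])
    t(utils::combn(genes, 2L))
  })
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  coexpressionNetwork(universe, pairs = pairs)
}

#' Module networks over a cut-height path
#'
#' Clusters once (signed adjacency at `beta`, TOM, average linkage) and
#' cuts the same dendrogram at every requested height, returning the
#' per-cut module assignment and clique network. Edge counts are
#' non-decreasing in cut height because static cuts are nested.
#'
#' @param expr genes x samples matrix.
#' @param beta soft-threshold power (default 6).
#' @param cutHeights increasing cut heights in `(0, 1]`.
#' @param minModuleSize minimum genes per module (default 30).
#' @return named list (names `cut=<height>`) of lists with elements
#'   `cutHeight`, `network`, `assignment`.
#' @export
wgcnaPath <- function(expr, beta = 6, cutHeights,
                      minModuleSize = 30L) {
  expr <- .as_expr(expr)
  cutHeights <- as.numeric(cutHeights)
  if (any(cutHeights <= 0 | cutHeights > 1)) {
    stop("`cutHeights` must lie in (0, 1]")
  }
  tom <- tomSimilarity(signedAdjacency(expr, beta = beta))
  tree <- hclust(as.dist(1 - tom), method = "average")
  out <- lapply(cutHeights, function(h) {
    asg <- .cut_modules(tree, h, as.integer(minModuleSize))
    list(cutHeight = h, network = modulesToNetwork(asg, rownames(expr)),
         assignment = asg)
  })
  names(out) <- paste0("cut=", cutHeights)
  out
}
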