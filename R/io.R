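# Reading and writing the formats the pipeline speaks: expression matrices
# (TSV/CSV), covariate tables, GMT gene sets, and edge lists. The dialect is
# fixed: "\t" for .tsv/.txt, "," for .csv, UTF-8 throughout.

#' Read a gene expression matrix from delimited text
#'
#' Expects one header row and one id column. With the default orientation
#' the id column holds gene ids and the header holds sample ids; with
#' `orientation = "samples_in_rows"` the file is transposed after reading so
#' the returned matrix is always genes x samples. The pipeline assumes
#' complete matrices: any missing or non-numeric cell is a hard error.
#'
#' @param path TSV (`.tsv`/`.txt`) or CSV (`.csv`) file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return numeric genes x samples matrix with gene rownames and sample
#'   colnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:2))), f)
#' readExpression(f)
#' @export
readExpression <- function(path,
                           orientation = c("genes_in_rows",
                                           "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- .delim_for(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("expression file needs an id column plus data")
  row_ids <- tab[[1L]]
  col_ids <- colnames(tab)[-1L]
  row_what <- if (orientation == "genes_in_rows") "gene" else "sample"
  col_what <- if (orientation == "genes_in_rows") "sample" else "gene"
  .check_ids(row_ids, row_what)
  .check_ids(col_ids, col_what)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing value at ", row_what, " '",
         row_ids[idx[1L]], "', ", col_what, " '", col_ids[idx[2L]],
         "' (was '", vals[idx[1L], idx[2L]], "')", call. = FALSE)
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "samples_in_rows") num <- t(num)
  .as_expr(num, arg = basename(path))
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [readExpression()] (genes in rows): header row of sample ids,
#' first column of gene ids.
#'
#' @param expr genes x samples numeric matrix.
#' @param path output file; `.csv` switches the delimiter to a comma.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path) {
  expr <- .as_expr(expr)
  sep <- .delim_for(path)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample covariate table
#'
#' First column sample id, remaining columns numeric covariates (e.g. RIN,
#' exonic rate, GC bias). Constant-valued covariates are kept but flagged
#' with a warning, since they cannot enter a regression design.
#'
#' @param path TSV/CSV file.
#' @return samples x covariates numeric matrix with sample rownames.
#' @export
readCovariates <- function(path) {
  sep <- .delim_for(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("covariate file needs an id column plus data")
  ids <- as.character(tab[[1L]])
  .check_ids(ids, "sample")
  .check_ids(colnames(tab)[-1L], "covariate")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("covariate columns must be numeric")
  if (anyNA(m)) stop("covariate table contains missing values")
  rownames(m) <- ids
  cons <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  if (any(cons)) {
    warning("constant covariate(s): ",
            paste(colnames(m)[cons], collapse = ", "))
  }
  m
}

#' Keep the most variable genes
#'
#' Ranks genes by (unbiased, n-1 denominator) sample variance and keeps the
#' top `k`, in decreasing-variance order; ties are broken by input gene
#' order, so the selection is deterministic. This is the standard filter
#' applied before network reconstruction (e.g. the 5000 most variable
#' genes).
#'
#' @param expr genes x samples matrix.
#' @param k number of genes to keep (`k <= nrow(expr)`).
#' @return the filtered, reordered matrix.
#' @export
selectMostVariable <- function(expr, k) {
  expr <- .as_expr(expr)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("`k` must be a positive integer")
  if (k > nrow(expr)) {
    stop("`k` (", k, ") exceeds the number of genes (", nrow(expr), ")")
  }
  v <- apply(expr, 1L, stats::var)
  ord <- order(-v, seq_along(v))  # decreasing variance, input order on ties
  expr[ord[seq_len(k)], , drop = FALSE]
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' `name`, `description`, then gene ids. Duplicate genes within a set are
#' deduplicated (set semantics); duplicate pathway names are an error.
#'
#' @param path GMT file.
#' @param db database label attached to every set in this file (one file =
#'   one database); defaults to the file name without extension.
#' @return a [PathwayCollection-class].
#' @export
readGMT <- function(path, db = NULL) {
  if (is.null(db)) db <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed GMT line ", which(nf < 3L)[1L],
         ": expected >= 3 tab-separated fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate pathway name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nm
  src <- rep(db, length(sets))
  names(src) <- nm
  methods::new("PathwayCollection", sets = sets, sourceDb = src)
}

#' Combine pathway collections from several databases
#'
#' @param ... [PathwayCollection-class] objects (e.g. one per GMT file).
#' @return a single [PathwayCollection-class]; pathway names must be unique
#'   across inputs.
#' @export
combinePathways <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, methods::is, TRUE, "PathwayCollection")))
  methods::new("PathwayCollection",
               sets = do.call(c, lapply(parts, geneSets)),
               sourceDb = do.call(c, lapply(parts, sourceDb)))
}

#' Ground-truth gene pairs from pathway co-membership
#'
#' Any pair of genes sharing at least one pathway is taken as a true
#' functional relationship. Pairs are restricted to a gene universe
#' (typically the most-variable genes used for reconstruction), and each
#' pair records the number of distinct source databases with at least one
#' shared pathway, enabling the "shared true positive" restriction.
#'
#' @param gsc a [PathwayCollection-class].
#' @param universe character vector of gene ids to restrict to.
#' @return a [GroundTruthEdges-class].
#' @export
pathwayPairs <- function(gsc, universe) {
  stopifnot(methods::is(gsc, "PathwayCollection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("`universe` must be non-empty")
  pair_db <- list()
  src <- sourceDb(gsc)
  for (i in seq_along(geneSets(gsc))) {
    genes <- sort(intersect(geneSets(gsc)[[i]], universe))
    if (length(genes) < 2L) next
    idx <- utils::combn(genes, 2L)
    keys <- paste(idx[1L, ], idx[2L, ], sep = "\x1f")
    pair_db[[length(pair_db) + 1L]] <-
      data.frame(key = keys, db = src[[i]], stringsAsFactors = FALSE)
  }
  if (length(pair_db) == 0L) {
    return(methods::new("GroundTruthEdges"))
  }
  all_pairs <- do.call(rbind, pair_db)
  all_pairs <- unique(all_pairs)
  counts <- tapply(all_pairs$db, all_pairs$key,
                   function(d) length(unique(d)))
  keys <- names(counts)
  methods::new("GroundTruthEdges",
               pairs = .keys_to_pairs(keys),
               dbCount = as.integer(counts))
}

#' Build a ground-truth edge set from explicit pairs
#'
#' @param pairs two-column character matrix/data frame of gene pairs.
#' @param dbCount per-pair database support count (default 1).
#' @return a [GroundTruthEdges-class].
#' @export
groundTruthEdges <- function(pairs, dbCount = NULL) {
  pairs <- .canonical_pairs(pairs)
  keys <- .pair_keys(pairs)
  if (anyDuplicated(keys)) {
    keep <- !duplicated(keys)
    if (is.null(dbCount)) pairs <- pairs[keep, , drop = FALSE]
    else stop("duplicate pairs with explicit dbCount")
  }
  if (is.null(dbCount)) dbCount <- rep(1L, nrow(pairs))
  methods::new("GroundTruthEdges", pairs = pairs,
               dbCount = as.integer(dbCount))
}

#' Construct a co-expression network object
#'
#' Pairs are canonicalized (sorted within pair); listing an edge in both
#' orientations collapses to a single edge. Weights, when present, follow
#' the first occurrence of each edge.
#'
#' @param universe gene ids the network is defined over.
#' @param pairs two-column character matrix of edges (may be empty).
#' @param weights optional numeric vector parallel to `pairs` rows.
#' @return a [CoexpressionNetwork-class].
#' @export
coexpressionNetwork <- function(universe, pairs = NULL, weights = NULL) {
  universe <- as.character(universe)
  .check_ids(universe, "gene")
  pairs <- .canonical_pairs(if (is.null(pairs)) character() else pairs)
  keys <- .pair_keys(pairs)
  keep <- !duplicated(keys)
  pairs <- pairs[keep, , drop = FALSE]
  if (!is.null(weights)) weights <- as.numeric(weights)[keep]
  if (nrow(pairs) && !all(c(pairs) %in% universe)) {
    missing <- setdiff(c(pairs), universe)
    stop("edge endpoint(s) outside the gene universe: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  methods::new("CoexpressionNetwork", universe = universe, edges = pairs,
               weights = if (is.null(weights)) numeric() else weights)
}

#' Write / read a network edge list
#'
#' Three-column TSV `gene1, gene2, weight` (weight column empty for
#' unweighted networks). Reading canonicalizes pair order, so a round trip
#' reproduces the edge set exactly.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param path TSV file.
#' @return `writeEdges`: `path` invisibly; `readEdges`: a
#'   [CoexpressionNetwork-class].
#' @export
writeEdges <- function(net, path) {
  stopifnot(methods::is(net, "CoexpressionNetwork"))
  e <- edges(net)
  w <- edgeWeights(net)
  df <- data.frame(gene1 = e[, 1L], gene2 = e[, 2L],
                   weight = if (length(w)) w else rep("", nrow(e)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeEdges
#' @param universe gene universe for the read network; endpoints outside it
#'   are an error.
#' @export
readEdges <- function(path, universe) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("gene1", "gene2") %in% colnames(tab))) {
    stop("edge list must have columns gene1, gene2[, weight]")
  }
  w <- NULL
  if ("weight" %in% colnames(tab) && nrow(tab) &&
      any(nzchar(tab$weight))) {
    w <- suppressWarnings(as.numeric(tab$weight))
  }
  coexpressionNetwork(universe,
                      pairs = as.matrix(tab[, c("gene1", "gene2")]),
                      weights = w)
}

#' Write / read a one-column gene universe file
#'
#' @param universe character vector of gene ids.
#' @param path text file, one gene id per line.
#' @return `writeUniverse`: `path` invisibly; `readUniverse`: character
#'   vector.
#' @export
writeUniverse <- function(universe, path) {
  writeLines(as.character(universe), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeUniverse
#' @export
readUniverse <- function(path) {
  ids <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ids <- ids[nzchar(ids)]
  .check_ids(ids, "gene")
  ids
}
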