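# Internal helpers: input validation, seed handling, canonical edge keys.

#' @importFrom methods new validObject is slot
#' @importFrom stats cor quantile rnorm runif sd var median as.dist cutree hclust
NULL

# Coerce the expression input to a plain genes x samples numeric matrix.
# Accepts a numeric matrix with dimnames or a SummarizedExperiment (first
# assay). Every exported function funnels through here.
.as_expr <- function(expr, arg = "expr") {
  if (methods::is(expr, "SummarizedExperiment")) {
    expr <- SummarizedExperiment::assay(expr, 1L)
  }
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`", arg, "` must be a numeric genes x samples matrix ",
         "(or a SummarizedExperiment)", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("`", arg, "` must have gene rownames and sample colnames",
         call. = FALSE)
  }
  .check_ids(rownames(expr), "gene")
  .check_ids(colnames(expr), "sample")
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1L, ]
    stop("`", arg, "` contains missing or non-finite values, e.g. gene '",
         rownames(expr)[bad[1L]], "', sample '", colnames(expr)[bad[2L]],
         "'", call. = FALSE)
  }
  expr
}

.check_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate ", what, " ids: ",
         paste(utils::head(dup, 5L), collapse = ", "),
         if (length(dup) > 5L) ", ..." else "", call. = FALSE)
  }
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop("empty or NA ", what, " id", call. = FALSE)
  }
  invisible(ids)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. Sub-stages derive their own seeds by fixed offsets from a master
# seed so each stage is independently reproducible.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

.sub_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# Canonical (lexicographic) ordering of unordered gene pairs. `pairs` is an
# n x 2 character matrix; returns the matrix with each row sorted and no
# self-pairs allowed.
.canonical_pairs <- function(pairs, allow_self = FALSE) {
  if (length(pairs) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("gene1", "gene2"))))
  }
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "character"
  if (!allow_self && any(pairs[, 1L] == pairs[, 2L])) {
    stop("self-pairs are not allowed", call. = FALSE)
  }
  swap <- pairs[, 1L] > pairs[, 2L]
  if (any(swap)) {
    tmp <- pairs[swap, 1L]
    pairs[swap, 1L] <- pairs[swap, 2L]
    pairs[swap, 2L] <- tmp
  }
  colnames(pairs) <- c("gene1", "gene2")
  pairs
}

.pair_keys <- function(pairs) {
  if (nrow(pairs) == 0L) return(character())
  paste(pairs[, 1L], pairs[, 2L], sep = "\x1f")
}

.keys_to_pairs <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("gene1", "gene2"))))
  }
  parts <- strsplit(keys, "\x1f", fixed = TRUE)
  matrix(unlist(parts), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("gene1", "gene2")))
}

.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}
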