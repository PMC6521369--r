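# Sparse inverse covariance (graphical lasso) network reconstruction.

#' Graphical lasso precision estimate
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * sum_{i != j}
#' |Theta_ij|` over positive-definite matrices by block coordinate descent
#' (the diagonal is unpenalised, so `lambda` thresholds correlations
#' directly: the solution is diagonal whenever `lambda >=
#' max |S_ij|, i != j`).
#'
#' @param S symmetric sample correlation (or covariance) matrix.
#' @param lambda positive L1 penalty on off-diagonal precision entries.
#' @param maxIter maximum outer sweeps (default 200).
#' @param convergenceTol relative tolerance on the working covariance
#'   update (default 1e-4).
#' @param warmStart optional list with elements `w` and `b` from a
#'   previous solve (e.g. the neighbouring penalty on a path).
#' @return list with `theta` (estimated precision), `w` (estimated
#'   covariance), `b` (regression coefficients for warm starts),
#'   `iterations`, `converged`.
#' @export
glassoPrecision <- function(S, lambda, maxIter = 200L,
                            convergenceTol = 1e-4, warmStart = NULL) {
  S <- as.matrix(S)
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("S must be symmetric")
  if (lambda <= 0) stop("`lambda` must be positive")
  S <- (S + t(S)) / 2
  w0 <- if (!is.null(warmStart)) warmStart$w else NULL
  b0 <- if (!is.null(warmStart)) warmStart$b else NULL
  fit <- .glasso_cd(S, lambda, w0, b0, as.integer(maxIter),
                    convergenceTol, 10000L, convergenceTol * 1e-2)
  if (!fit$converged) {
    stop(sprintf(
      "graphical lasso did not converge at lambda = %g after %d iterations",
      lambda, fit$iterations), call. = FALSE)
  }
  dimnames(fit$theta) <- dimnames(S)
  dimnames(fit$w) <- dimnames(S)
  fit
}

#' Reconstruct a network with the graphical lasso
#'
#' Expression is standardized internally so the solver works on the sample
#' correlation matrix and `lambda` is scale-free. An edge is called
#' between genes i and j whenever the estimated precision entry exceeds
#' `edgeTolerance` in magnitude (separating numerical zeros from true
#' nonzeros); edge weights are the precision entries.
#'
#' @param expr genes x samples matrix (>= 3 samples).
#' @param lambda positive L1 penalty.
#' @param edgeTolerance magnitude below which a precision entry is treated
#'   as zero (default 1e-8).
#' @inheritParams glassoPrecision
#' @return a [CoexpressionNetwork-class] over the genes of `expr`.
#' @export
glassoNetwork <- function(expr, lambda, edgeTolerance = 1e-8,
                          maxIter = 200L, convergenceTol = 1e-4,
                          warmStart = NULL) {
  expr <- .as_expr(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  S <- stats::cor(t(expr))
  fit <- glassoPrecision(S, lambda, maxIter = maxIter,
                         convergenceTol = convergenceTol,
                         warmStart = warmStart)
  net <- .theta_to_network(fit$theta, rownames(expr), edgeTolerance)
  attr(net, "fit") <- fit
  net
}

.theta_to_network <- function(theta, ids, edgeTolerance) {
  up <- which(upper.tri(theta) & abs(theta) > edgeTolerance, arr.ind = TRUE)
  coexpressionNetwork(ids,
                      pairs = cbind(ids[up[, 1L]], ids[up[, 2L]]),
                      weights = theta[up])
}

#' Graphical lasso over a penalty path
#'
#' Solves at each penalty of a decreasing path, warm-starting every solve
#' from its predecessor. Warm starting changes only the iteration count:
#' per-penalty solutions agree with cold starts to within solver tolerance.
#'
#' @param expr genes x samples matrix.
#' @param lambdas decreasing positive penalties.
#' @inheritParams glassoNetwork
#' @return named list (one element per lambda, names `lambda=<value>`) of
#'   [CoexpressionNetwork-class] objects, with the penalty stored in each
#'   element's `"lambda"` attribute.
#' @export
glassoPath <- function(expr, lambdas, edgeTolerance = 1e-8,
                       maxIter = 200L, convergenceTol = 1e-4) {
  expr <- .as_expr(expr)
  lambdas <- as.numeric(lambdas)
  if (any(lambdas <= 0)) stop("`lambdas` must be positive")
  if (is.unsorted(rev(lambdas), strictly = FALSE)) {
    stop("`lambdas` must be sorted in decreasing order")
  }
  S <- stats::cor(t(expr))
  ids <- rownames(expr)
  warm <- NULL
  out <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fit <- glassoPrecision(S, lambdas[i], maxIter = maxIter,
                           convergenceTol = convergenceTol,
                           warmStart = warm)
    warm <- fit
    net <- .theta_to_network(fit$theta, ids, edgeTolerance)
    attr(net, "lambda") <- lambdas[i]
    attr(net, "fit") <- fit
    out[[i]] <- net
  }
  names(out) <- paste0("lambda=", lambdas)
  out
}
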