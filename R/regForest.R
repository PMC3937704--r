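#' Fit a regression random forest
#'
#' Bootstrap-aggregated CART regression trees with out-of-bag (OOB)
#' evaluation and, optionally, raw permutation importance. Each tree is grown
#' on one bootstrap sample of the data (so `nTrees` is the number of
#' bootstrap samples); the roughly one third of observations left out of a
#' tree's bootstrap sample form its OOB set and are the only observations
#' used to score that tree. Permutation importance of a predictor is the
#' mean over trees of the increase in OOB MSE after randomly permuting that
#' predictor's values within the tree's OOB set, one independent permutation
#' per tree and per predictor (the "raw" / unscaled importance).
#'
#' Randomness is driven entirely by `seed` through an internal generator, so
#' a fit is bit-reproducible regardless of R's RNG state.
#'
#' @param x numeric matrix of predictors (observations in rows).
#' @param y numeric response vector, `length(y) == nrow(x)`.
#' @param nTrees number of trees (= bootstrap samples).
#' @param mtry number of candidate predictors sampled at each split;
#'   default `max(1, floor(ncol(x)/3))`, the regression-forest convention.
#' @param nodeSize minimum node size below which nodes are not split
#'   (default 5, the regression default).
#' @param seed integer seed; required, no hidden global-RNG fallback.
#' @param importance compute raw permutation importance?
#' @param keepInbag return the n x nTrees matrix of bootstrap counts?
#' @param keepPerms return the per-tree, per-variable OOB permutations used
#'   for importance (for small fixtures / independent recomputation)?
#' @return object of class `regForest`: the flattened tree arrays, per-row
#'   OOB predictions (`oobPred`, `NA` for rows never OOB), forest-level
#'   `oobMse` computed from the aggregated OOB predictions, and (if
#'   requested) `importanceRaw`, `importanceSd`, `inbag`, `perms`.
#' @examples
#' x <- matrix(rnorm(600), ncol = 3)
#' y <- x[, 1] + rnorm(200, sd = 0.1)
#' rf <- regForest(x, y, nTrees = 100, seed = 1, importance = TRUE)
#' rf$importanceRaw
#' @export
regForest <- function(x, y, nTrees = 500, mtry = max(1L, floor(ncol(x) / 3)),
                      nodeSize = 5L, seed, importance = FALSE,
                      keepInbag = FALSE, keepPerms = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (missing(seed)) stop("'seed' is required")
  fit <- .rf_fit_cpp(x, y, as.integer(nTrees), as.integer(mtry),
                     as.integer(nodeSize), as.numeric(seed),
                     isTRUE(importance), isTRUE(keepInbag),
                     isTRUE(keepPerms) && isTRUE(importance))
  vn <- colnames(x)
  if (!is.null(vn)) {
    names(fit$importance_raw) <- vn
    names(fit$importance_sd) <- vn
  }
  out <- list(
    nodeVar = fit$node_var, nodeSplit = fit$node_split,
    nodeLeft = fit$node_left, nodeRight = fit$node_right,
    nodePred = fit$node_pred, treeOffset = fit$tree_offset,
    oobPred = fit$oob_pred, oobMse = fit$oob_mse,
    importanceRaw = fit$importance_raw, importanceSd = fit$importance_sd,
    inbag = fit$inbag, perms = fit$perms,
    nTrees = as.integer(nTrees), mtry = as.integer(mtry),
    nodeSize = as.integer(nodeSize), seed = seed,
    varNames = vn, n = nrow(x))
  class(out) <- "regForest"
  out
}

#' Predict from a regression forest
#'
#' Full-forest predictions (mean over all trees) for new observations.
#'
#' @param object a [regForest()] fit.
#' @param newdata numeric matrix with the same columns, in the same order,
#'   as the training matrix.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.regForest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$varNames)) {
    if (!is.null(colnames(newdata)) &&
        !identical(colnames(newdata), object$varNames)) {
      if (!all(object$varNames %in% colnames(newdata)))
        stop("newdata is missing training predictors")
      newdata <- newdata[, object$varNames, drop = FALSE]
    }
  }
  f <- list(node_var = object$nodeVar, node_split = object$nodeSplit,
            node_left = object$nodeLeft, node_right = object$nodeRight,
            node_pred = object$nodePred, tree_offset = object$treeOffset)
  .rf_predict_cpp(f, newdata)
}

#' @export
print.regForest <- function(x, ...) {
  cat("regForest: ", x$nTrees, " trees, mtry ", x$mtry,
      ", n = ", x$n, "\n", sep = "")
  cat("  OOB MSE: ", format(x$oobMse, digits = 4), "\n", sep = "")
  invisible(x)
}

# stable per-repetition seed derivation: linear-congruential style hash kept
# strictly below 2^31 so it is a valid R integer seed everywhere
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(index) * 104729 + 1) %% 2147483647)
}
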