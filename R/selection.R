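#' Build the nested top-k OOB MSE curve
#'
#' For each model size k = 1..m, fits `nRuns` independent forests on the
#' top-k ranked sMRI variables plus the covariates (always included, never
#' counted in k) and records each fit's out-of-bag MSE. The mean curve
#' typically decreases as informative regions enter and flattens or rises
#' once only noise is added; its minimum is the basis of the parsimonious
#' model choice.
#'
#' @param cohort an [HDCohort-class].
#' @param ranking an [ImportanceRanking-class] for the target outcome.
#' @param nRuns forest fits per k (default 200, the protocol value).
#' @param nTrees trees per fit (default the ranking's tree count).
#' @param rule parsimony rule used to set `kChosen` (see [chooseK()]).
#' @param nodeSize minimum node size.
#' @param seed master seed; each (k, run) pair derives its own seed.
#' @param mtry optional fixed number of split candidates for every k;
#'   default `NULL` applies the protocol rule `max(1, floor(p/3))` with p
#'   counting the k regions plus the covariates. A fixed value makes the
#'   curve compare information content at constant per-split capacity
#'   (useful for oracle checks at very small p, where the p/3 rule itself
#'   moves the curve).
#' @return a [SelectionCurve-class].
#' @export
buildCurve <- function(cohort, ranking, nRuns = 200L, nTrees = NULL,
                       rule = c("one_se", "strict_min"), nodeSize = 5L,
                       seed = 1L, mtry = NULL) {
  stopifnot(is(ranking, "ImportanceRanking"), nRuns >= 2)
  rule <- match.arg(rule)
  tb <- rankingTable(ranking)
  m <- nrow(tb)
  if (!m) stop("ranking contains no variables")
  if (is.null(nTrees)) nTrees <- ranking@config$nTrees
  d <- .mainDesign(cohort, ranking@outcome, tb$variable,
                   ranking@covariates)
  covCols <- d$covariates
  meanMse <- mseSe <- numeric(m)
  for (k in seq_len(m)) {
    vars <- c(tb$variable[seq_len(k)], covCols)
    xk <- d$x[, vars, drop = FALSE]
    mtryK <- if (is.null(mtry)) max(1L, floor(ncol(xk) / 3)) else
      min(as.integer(mtry), ncol(xk))
    mse <- numeric(nRuns)
    for (run in seq_len(nRuns)) {
      fit <- regForest(xk, d$y, nTrees = nTrees, mtry = mtryK,
                       nodeSize = nodeSize,
                       seed = deriveSeed(seed, k * 100003L + run))
      mse[run] <- fit$oobMse
    }
    meanMse[k] <- mean(mse)
    mseSe[k] <- stats::sd(mse) / sqrt(nRuns)
  }
  kMin <- which.min(meanMse)
  curve <- methods::new("SelectionCurve", k = seq_len(m),
                        meanMse = meanMse, mseSe = mseSe,
                        kMin = as.integer(kMin), kChosen = as.integer(kMin),
                        rule = rule, outcome = ranking@outcome)
  curve@kChosen <- chooseK(curve, rule)
  curve
}

#' Choose the parsimonious model size from an MSE curve
#'
#' `"strict_min"` returns the argmin of the mean OOB MSE. `"one_se"`
#' formalizes the "very close MSE, prefer the smaller model" judgement as
#' the one-standard-error rule: the smallest k whose mean MSE is within one
#' standard error of the minimum. `one_se` can never select a larger model
#' than `strict_min`.
#'
#' @param curve a [SelectionCurve-class].
#' @param rule parsimony rule.
#' @return integer model size.
#' @export
chooseK <- function(curve, rule = c("one_se", "strict_min")) {
  stopifnot(is(curve, "SelectionCurve"))
  rule <- match.arg(rule)
  kMin <- which.min(curve@meanMse)
  if (rule == "strict_min") return(as.integer(curve@k[kMin]))
  thr <- curve@meanMse[kMin] + curve@mseSe[kMin]
  as.integer(curve@k[which(curve@meanMse <= thr)[1]])
}

#' Report the selected top-k variables with direction checks
#'
#' Table of the top `kChosen` variables in mean-rank order. For each, the
#' Spearman rank correlation between its morphometry values and the outcome
#' in the case group is reported; since lower scores mean worse performance
#' and smaller values mean thinner cortex / smaller striatum, a positive
#' correlation is the expected "thinner/smaller goes with worse" direction
#' (`consistent`), a negative one is `inconsistent`, and `|rho|` below
#' `rhoThreshold` is `indeterminate`.
#'
#' @param cohort an [HDCohort-class].
#' @param ranking an [ImportanceRanking-class].
#' @param kChosen number of top variables to report (e.g.
#'   [chosenK()] of a [buildCurve()] result).
#' @param rhoThreshold magnitude below which the direction is flagged
#'   indeterminate (default 0.1).
#' @return data.frame with rank, variable, meanRank, meanImportance,
#'   spearmanRho, direction.
#' @export
reportSelected <- function(cohort, ranking, kChosen, rhoThreshold = 0.1) {
  stopifnot(is(ranking, "ImportanceRanking"), kChosen >= 1)
  tb <- rankingTable(ranking)
  kChosen <- min(kChosen, nrow(tb))
  tb <- tb[seq_len(kChosen), , drop = FALSE]
  cd <- SummarizedExperiment::colData(cohort)
  cases <- cohort[, cd$group == "case"]
  y <- SummarizedExperiment::colData(cases)[[ranking@outcome]]
  m <- morphometry(cases)
  rho <- vapply(tb$variable, function(v) {
    ok <- !is.na(y) & !is.na(m[v, ])
    suppressWarnings(stats::cor(m[v, ok], y[ok], method = "spearman"))
  }, numeric(1))
  direction <- ifelse(is.na(rho) | abs(rho) < rhoThreshold, "indeterminate",
                      ifelse(rho > 0, "consistent", "inconsistent"))
  data.frame(rank = seq_len(kChosen), variable = tb$variable,
             meanRank = tb$meanRank, meanImportance = tb$meanImportance,
             spearmanRho = unname(rho), direction = direction,
             row.names = NULL)
}

#' Plot a selection curve
#'
#' Mean OOB MSE against the number of top-ranked sMRI variables, with the
#' minimum marked by a dashed line and the chosen k by a dotted one.
#'
#' @param curve a [SelectionCurve-class].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the curve.
#' @export
plotSelectionCurve <- function(curve, ...) {
  stopifnot(is(curve, "SelectionCurve"))
  graphics::plot(curve@k, curve@meanMse, type = "b", pch = 19,
                 xlab = "number of top-ranked sMRI variables",
                 ylab = "mean OOB MSE",
                 main = paste0(curve@outcome, " (kMin = ", curve@kMin,
                               ", chosen = ", curve@kChosen, ")"), ...)
  graphics::abline(v = curve@kMin, lty = 2)
  graphics::abline(v = curve@kChosen, lty = 3)
  invisible(curve)
}
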