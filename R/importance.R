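#' Forest configuration for the main analyses
#'
#' Defaults follow the main-analysis protocol: forests of 5000 bootstrap
#' samples (one tree per bootstrap sample), mtry = `max(1, floor(p/3))`
#' counting *all* predictors (sMRI variables plus the four covariates),
#' raw (unscaled) OOB-MSE-increase permutation importance, and 1000
#' repetitions of the whole fit for a stable average ranking. Tests and
#' reduced-scale runs lower `nTrees`/`nRepetitions`.
#'
#' @param nTrees trees (bootstrap samples) per forest.
#' @param nRepetitions independent forest fits to aggregate over.
#' @param importanceMode `"raw_increase"` (mean OOB MSE increase, the
#'   default) or `"scaled"` (divided by its standard error across trees).
#' @param nodeSize minimum node size (default 5).
#' @param seed integer master seed; repetition r uses a seed derived
#'   deterministically from `(seed, r)`.
#' @return list of class `ForestConfig`.
#' @export
forestConfig <- function(nTrees = 5000L, nRepetitions = 1000L,
                         importanceMode = c("raw_increase", "scaled"),
                         nodeSize = 5L, seed = 1L) {
  stopifnot(nTrees >= 1, nRepetitions >= 1)
  structure(list(nTrees = as.integer(nTrees),
                 nRepetitions = as.integer(nRepetitions),
                 importanceMode = match.arg(importanceMode),
                 nodeSize = as.integer(nodeSize),
                 seed = as.integer(seed)),
            class = "ForestConfig")
}

.defaultCovariates <- c("age", "sex", "education_years", "visit_count")

# design matrix for the main analyses: case subjects only, sMRI predictors
# in canonical (name-sorted) order so results do not depend on the order
# in which predictor columns are supplied, then the covariates
.mainDesign <- function(cohort, outcome, predictors,
                        covariates = .defaultCovariates) {
  stopifnot(is(cohort, "HDCohort"))
  if (!length(predictors)) stop("predictor set is empty")
  if (!all(predictors %in% rownames(cohort)))
    stop("unknown predictor region(s): ",
         paste(setdiff(predictors, rownames(cohort)), collapse = ", "))
  cd <- SummarizedExperiment::colData(cohort)
  if (!outcome %in% names(cd)) stop("unknown outcome: ", outcome)
  cases <- cohort[, cd$group == "case"]
  cdc <- SummarizedExperiment::colData(cases)
  predictors <- sort(predictors)
  x <- t(morphometry(cases)[predictors, , drop = FALSE])
  cov <- data.frame(age = cdc$age,
                    sex = as.numeric(cdc$sex == "male"),
                    education_years = cdc$education_years,
                    visit_count = as.numeric(cdc$visit_count))
  cov <- cov[, covariates, drop = FALSE]
  y <- cdc[[outcome]]
  keep <- stats::complete.cases(x, cov, y)
  if (sum(!keep))
    message(sum(!keep), " case(s) with missing data excluded for '",
            outcome, "'")
  list(x = cbind(x, as.matrix(cov))[keep, , drop = FALSE],
       y = as.numeric(y)[keep],
       predictors = predictors, covariates = covariates)
}

#' Rank sMRI predictors by repeated permutation importance
#'
#' For one cognitive outcome, fits `nRepetitions` independent random
#' forests on the screened sMRI predictors plus the covariates (age, sex,
#' education, visit count) in the case group only, computes raw OOB
#' permutation importance in each fit, ranks the *sMRI variables only*
#' (covariates stay in the model but never in the ranking; rank 1 = most
#' important, ties within a repetition get midranks so every repetition's
#' ranks sum to m(m+1)/2), and averages ranks and importances over
#' repetitions. Output rows are ordered by mean rank, ties broken by higher
#' mean importance and then variable name.
#'
#' @param cohort an [HDCohort-class].
#' @param outcome one of the cognitive score columns.
#' @param predictors character vector of screened region names.
#' @param covariates covariate columns to include in every fit.
#' @param config a [forestConfig()].
#' @param keepRankMatrix keep the repetitions x variables rank matrix for
#'   diagnostics?
#' @return an [ImportanceRanking-class].
#' @export
rankVariables <- function(cohort, outcome, predictors,
                          covariates = .defaultCovariates,
                          config = forestConfig(), keepRankMatrix = FALSE) {
  stopifnot(inherits(config, "ForestConfig"))
  d <- .mainDesign(cohort, outcome, predictors, covariates)
  if (length(d$y) < 30)
    stop("main analysis requires at least 30 cases, got ", length(d$y))
  m <- length(d$predictors)
  pAll <- ncol(d$x)
  mtry <- max(1L, floor(pAll / 3))
  rankMat <- matrix(NA_real_, config$nRepetitions, m,
                    dimnames = list(NULL, d$predictors))
  impMat <- matrix(NA_real_, config$nRepetitions, m,
                   dimnames = list(NULL, d$predictors))
  for (r in seq_len(config$nRepetitions)) {
    fit <- tryCatch(
      regForest(d$x, d$y, nTrees = config$nTrees, mtry = mtry,
                nodeSize = config$nodeSize,
                seed = deriveSeed(config$seed, r), importance = TRUE),
      error = function(e)
        stop("repetition ", r, " failed: ", conditionMessage(e),
             call. = FALSE))
    imp <- fit$importanceRaw[d$predictors]
    if (config$importanceMode == "scaled") {
      sdv <- fit$importanceSd[d$predictors]
      imp <- ifelse(sdv > 0, imp / sdv, 0)
    }
    rankMat[r, ] <- rank(-imp, ties.method = "average")
    impMat[r, ] <- imp
  }
  meanRank <- colMeans(rankMat)
  meanImp <- colMeans(impMat)
  rankSd <- apply(rankMat, 2, stats::sd)
  ord <- order(meanRank, -meanImp, d$predictors)
  tb <- S4Vectors::DataFrame(
    variable = d$predictors[ord], meanRank = meanRank[ord],
    meanImportance = meanImp[ord], rankSd = rankSd[ord])
  methods::new("ImportanceRanking", table = tb, outcome = outcome,
               covariates = d$covariates, config = unclass(config),
               rankMatrix = if (keepRankMatrix) rankMat else NULL)
}
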