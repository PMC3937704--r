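#' Fit the normative age/sex model on controls
#'
#' One random-forest regressor per region, trained exclusively on the
#' control group with predictors age and sex (sex as a binary indicator).
#' Trees capture the nonlinear age effect and any age-by-sex interaction
#' without explicit terms. Control-group predictions later use out-of-bag
#' aggregation by default (`mode = "oob"`): in-sample forest predictions are
#' strongly shrunken toward the observations, which would bias control
#' residuals toward zero and inflate apparent group differences;
#' `"in_sample"` remains available.
#'
#' @param cohort an [HDCohort-class]; only its control columns are used.
#' @param nTrees trees per region (default 500).
#' @param seed integer master seed; per-region fits use seeds derived from
#'   it.
#' @param mode prediction mode for the training (control) group.
#' @param nodeSize minimum node size (default 5).
#' @return a [NormativeModel-class] with per-region OOB R-squared.
#' @export
fitNormative <- function(cohort, nTrees = 500, seed, mode = c("oob",
                                                              "in_sample"),
                         nodeSize = 5L) {
  stopifnot(is(cohort, "HDCohort"))
  mode <- match.arg(mode)
  if (missing(seed)) stop("'seed' is required")
  cd <- SummarizedExperiment::colData(cohort)
  ctrl <- cohort[, cd$group == "control"]
  cdc <- SummarizedExperiment::colData(ctrl)
  keep <- !is.na(cdc$age) & !is.na(cdc$sex)
  if (sum(keep) < nrow(cdc))
    message(sum(!keep), " control(s) with missing age/sex excluded")
  ctrl <- ctrl[, keep]
  cdc <- SummarizedExperiment::colData(ctrl)
  if (ncol(ctrl) < 20)
    stop("normative fitting requires at least 20 controls, got ",
         ncol(ctrl))
  x <- cbind(age = cdc$age, sex = as.numeric(cdc$sex == "male"))
  m <- morphometry(ctrl)
  forests <- vector("list", nrow(m))
  oobR2 <- numeric(nrow(m))
  for (r in seq_len(nrow(m))) {
    y <- m[r, ]
    # with only two predictors the p/3 rule would leave single-candidate
    # nodes that stall on the binary sex column; use both candidates
    fit <- regForest(x, y, nTrees = nTrees, mtry = ncol(x),
                     nodeSize = nodeSize, seed = deriveSeed(seed, r))
    forests[[r]] <- fit
    vy <- stats::var(y)
    oobR2[r] <- if (is.finite(vy) && vy > 0) 1 - fit$oobMse / vy else NA_real_
  }
  names(forests) <- rownames(m)
  names(oobR2) <- rownames(m)
  methods::new("NormativeModel", forests = forests, regions = rownames(m),
               trainingIds = colnames(ctrl), mode = mode,
               nTrees = as.integer(nTrees), seed = as.numeric(seed),
               ageRange = range(cdc$age), oobR2 = oobR2)
}

#' Residualize morphometry against the normative model
#'
#' Residual = observed - predicted, in the source units (mm or volume
#' ratio). For the training (control) set the prediction follows the
#' model's configured mode ("residual 1"); for a disjoint (case) set the
#' full forest predicts ("residual 2"). Mixed subject sets are rejected.
#' Subjects whose age falls outside the training range by more than
#' `extrapolationGuard` years trigger a warning, not an error.
#'
#' @param model a [NormativeModel-class].
#' @param cohort an [HDCohort-class] whose subjects are either exactly the
#'   training controls or disjoint from them.
#' @param extrapolationGuard years beyond the training age range tolerated
#'   silently (default 10).
#' @return a [ResidualSet-class].
#' @export
residualize <- function(model, cohort, extrapolationGuard = 10) {
  stopifnot(is(model, "NormativeModel"), is(cohort, "HDCohort"))
  if (!all(model@regions %in% rownames(cohort)))
    stop("cohort lacks regions covered by the model")
  cohort <- cohort[model@regions, ]
  cd <- SummarizedExperiment::colData(cohort)
  ids <- colnames(cohort)
  inTrain <- ids %in% model@trainingIds
  if (any(inTrain) && !all(inTrain))
    stop("subject set must be identical to, or disjoint from, the ",
         "training controls")
  training <- all(inTrain) && setequal(ids, model@trainingIds)
  if (any(inTrain) && !training)
    stop("subject set must be identical to, or disjoint from, the ",
         "training controls")
  lo <- model@ageRange[1] - extrapolationGuard
  hi <- model@ageRange[2] + extrapolationGuard
  nOut <- sum(cd$age < lo | cd$age > hi, na.rm = TRUE)
  if (nOut > 0)
    warning(nOut, " subject(s) outside the normative age range by more ",
            "than ", extrapolationGuard, " years; predictions extrapolate")
  m <- morphometry(cohort)
  res <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (training) {
    for (r in seq_len(nrow(m))) {
      f <- model@forests[[r]]
      pred <- if (model@mode == "oob") f$oobPred else
        predict(f, cbind(age = cd$age, sex = as.numeric(cd$sex == "male")))
      if (model@mode == "oob") {
        # oobPred is in training order; map back to this cohort's order
        pred <- pred[match(ids, model@trainingIds)]
        if (anyNA(pred)) {
          # rows never OOB (tiny forests): fall back to full-forest
          nai <- which(is.na(pred))
          xf <- cbind(age = cd$age[nai],
                      sex = as.numeric(cd$sex[nai] == "male"))
          pred[nai] <- predict(f, xf)
        }
      }
      res[r, ] <- m[r, ] - pred
    }
  } else {
    x <- cbind(age = cd$age, sex = as.numeric(cd$sex == "male"))
    for (r in seq_len(nrow(m)))
      res[r, ] <- m[r, ] - predict(model@forests[[r]], x)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(residuals = res),
    rowData = SummarizedExperiment::rowData(cohort),
    colData = cd)
  methods::new("ResidualSet", se)
}

#' Residualize both groups of a cohort
#'
#' Convenience wrapper: fits nothing, just applies [residualize()] to the
#' control columns (residual 1) and the case columns (residual 2) of
#' `cohort` and column-binds the results.
#'
#' @inheritParams residualize
#' @return a [ResidualSet-class] containing both groups.
#' @export
residualizeCohort <- function(model, cohort, extrapolationGuard = 10) {
  cd <- SummarizedExperiment::colData(cohort)
  res1 <- residualize(model, cohort[, cd$group == "control"],
                      extrapolationGuard)
  res2 <- residualize(model, cohort[, cd$group == "case"],
                      extrapolationGuard)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(residuals = base::cbind(residualsMatrix(res1),
                                          residualsMatrix(res2))),
    rowData = SummarizedExperiment::rowData(res1),
    colData = S4Vectors::rbind(SummarizedExperiment::colData(res1),
                               SummarizedExperiment::colData(res2)))
  methods::new("ResidualSet", se)
}
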