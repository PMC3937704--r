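#' @title Cohort container for morphometry, demographics and cognition
#'
#' @description `HDCohort` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with regions as rows and subjects as columns. The single assay
#' `"morphometry"` holds cortical thickness in mm and striatal volumes as
#' dimensionless volume/ICV ratios; `rowData()$kind` flags each region as
#' `"thickness"` or `"volume_ratio"`; `colData()` carries group, age, sex,
#' education, visit count, optional CAG length / motor score / ICV, and the
#' five cognitive scores.
#'
#' @details Validity enforces: positive finite thickness, volume ratios in
#' (0,1), unique subject ids and region names, `group` a factor with levels
#' `control`/`case`, `sex` a factor with levels `female`/`male`, positive
#' age and non-negative education where present. Missing covariates or
#' outcomes are tolerated in the container and handled (excluded, with a
#' logged count) by the analysis stages.
#'
#' @aliases HDCohort
#' @exportClass HDCohort
setClass("HDCohort", contains = "SummarizedExperiment")

.requiredSubjectCols <- c("group", "age", "sex", "education_years",
                          "visit_count")
.cognitionCols <- c("sdmt", "letter_number", "hvlt_immediate",
                    "negative_emotions", "timing_precision")

setValidity("HDCohort", function(object) {
  msgs <- character()
  if (!"morphometry" %in% SummarizedExperiment::assayNames(object))
    return("assay 'morphometry' is required")
  m <- SummarizedExperiment::assay(object, "morphometry")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msgs <- c(msgs, "region names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msgs <- c(msgs, "subject ids must be present and unique")
  if (!"kind" %in% names(rd)) {
    msgs <- c(msgs, "rowData must contain 'kind'")
  } else {
    if (!all(rd$kind %in% c("thickness", "volume_ratio")))
      msgs <- c(msgs, "kind must be 'thickness' or 'volume_ratio'")
    th <- m[rd$kind == "thickness", , drop = FALSE]
    vr <- m[rd$kind == "volume_ratio", , drop = FALSE]
    if (length(th) && (!all(is.finite(th)) || any(th <= 0)))
      msgs <- c(msgs, "thickness values must be finite and > 0")
    if (length(vr) && (!all(is.finite(vr)) || any(vr <= 0) || any(vr >= 1)))
      msgs <- c(msgs, "volume ratios must lie in (0, 1)")
  }
  miss <- setdiff(.requiredSubjectCols, names(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if ("group" %in% names(cd) &&
      !identical(levels(cd$group), c("control", "case")))
    msgs <- c(msgs, "group must be a factor with levels control, case")
  if ("sex" %in% names(cd) &&
      !identical(levels(cd$sex), c("female", "male")))
    msgs <- c(msgs, "sex must be a factor with levels female, male")
  if ("age" %in% names(cd) && any(cd$age <= 0, na.rm = TRUE))
    msgs <- c(msgs, "age must be positive")
  if ("education_years" %in% names(cd) &&
      any(cd$education_years < 0, na.rm = TRUE))
    msgs <- c(msgs, "education_years must be non-negative")
  if ("visit_count" %in% names(cd) &&
      any(cd$visit_count < 1, na.rm = TRUE))
    msgs <- c(msgs, "visit_count must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct an HDCohort
#'
#' @param morphometry numeric matrix, subjects in rows and regions in
#'   columns (the orientation of `morphometry.csv`); it is stored
#'   transposed, regions x subjects.
#' @param subjects data.frame/DataFrame of per-subject fields with a
#'   `subject_id` column (or rownames) matching `rownames(morphometry)`;
#'   must include group, age, sex, education_years, visit_count.
#' @param kind character vector, one of `"thickness"`/`"volume_ratio"` per
#'   region.
#' @param cognition optional data.frame keyed by `subject_id` with columns
#'   sdmt, letter_number, hvlt_immediate, negative_emotions,
#'   timing_precision; merged into `colData`.
#' @param metadata list stored in `metadata()` (e.g. ground truth).
#' @return validated [HDCohort-class] object.
#' @export
HDCohort <- function(morphometry, subjects, kind, cognition = NULL,
                     metadata = list()) {
  morphometry <- as.matrix(morphometry)
  subjects <- as.data.frame(subjects)
  if ("subject_id" %in% names(subjects)) {
    rownames(subjects) <- subjects$subject_id
    subjects$subject_id <- NULL
  }
  ids <- rownames(morphometry)
  if (is.null(ids)) stop("morphometry must have subject ids as rownames")
  if (!setequal(ids, rownames(subjects)))
    stop("subjects and morphometry cover different subject ids")
  subjects <- subjects[ids, , drop = FALSE]
  subjects$group <- factor(as.character(subjects$group),
                           levels = c("control", "case"))
  subjects$sex <- factor(as.character(subjects$sex),
                         levels = c("female", "male"))
  subjects$visit_count <- as.integer(subjects$visit_count)
  if (!is.null(cognition)) {
    cognition <- as.data.frame(cognition)
    if ("subject_id" %in% names(cognition)) {
      rownames(cognition) <- cognition$subject_id
      cognition$subject_id <- NULL
    }
    subjects[, names(cognition)] <- cognition[ids, , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(morphometry = t(morphometry)),
    rowData = S4Vectors::DataFrame(kind = kind,
                                   row.names = colnames(morphometry)),
    colData = S4Vectors::DataFrame(subjects),
    metadata = metadata)
  methods::new("HDCohort", se)
}

#' @title Residual container after normative adjustment
#' @description Regions x subjects matrix of observed-minus-predicted
#'   morphometry (assay `"residuals"`, same units as the source measures)
#'   with the group label of each subject in `colData()$group`. Residuals of
#'   the control (training) group are "residual 1", those of the case group
#'   "residual 2"; atrophy manifests as residual 1 stochastically larger
#'   than residual 2.
#' @aliases ResidualSet
#' @exportClass ResidualSet
setClass("ResidualSet", contains = "SummarizedExperiment")

setValidity("ResidualSet", function(object) {
  if (!"residuals" %in% SummarizedExperiment::assayNames(object))
    return("assay 'residuals' is required")
  if (!all(is.finite(SummarizedExperiment::assay(object, "residuals"))))
    return("residuals must be finite")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    return("colData must contain 'group'")
  TRUE
})

#' @title Normative age/sex model for regional morphometry
#' @description One random-forest regressor per region, trained exclusively
#'   on control subjects with predictors age and sex. Control predictions
#'   use the configured `mode` (out-of-bag by default); case predictions
#'   always use the full forest.
#' @slot forests list of per-region [regForest()] fits.
#' @slot regions character, region names in fit order.
#' @slot trainingIds character, control subject ids used for training.
#' @slot mode `"oob"` or `"in_sample"` prediction for the training group.
#' @slot nTrees,seed forest size and master seed.
#' @slot ageRange training age range, used for the extrapolation guard.
#' @slot oobR2 per-region out-of-bag R-squared.
#' @exportClass NormativeModel
setClass("NormativeModel",
         representation(forests = "list", regions = "character",
                        trainingIds = "character", mode = "character",
                        nTrees = "integer", seed = "numeric",
                        ageRange = "numeric", oobR2 = "numeric"))

#' @title Stability ranking of predictors by permutation importance
#' @description Per-variable mean importance (raw OOB MSE increase) and
#'   mean rank (1 = most important) aggregated over repeated forest fits;
#'   covariates take part in every fit but are excluded from the ranking.
#' @slot table `DataFrame` with columns variable, meanRank, meanImportance,
#'   rankSd, ordered by meanRank (ties broken by higher meanImportance then
#'   name).
#' @slot outcome name of the cognitive outcome.
#' @slot covariates covariate columns included in each fit.
#' @slot config the [forestConfig()] used.
#' @slot rankMatrix optional repetitions x variables matrix of ranks.
#' @exportClass ImportanceRanking
setClass("ImportanceRanking",
         representation(table = "DataFrame", outcome = "character",
                        covariates = "character", config = "list",
                        rankMatrix = "ANY"))

setValidity("ImportanceRanking", function(object) {
  tb <- object@table
  m <- nrow(tb)
  if (!all(c("variable", "meanRank", "meanImportance") %in% names(tb)))
    return("table must have variable, meanRank, meanImportance")
  if (m && (any(tb$meanRank < 1) || any(tb$meanRank > m)))
    return("meanRank must lie in [1, number of variables]")
  TRUE
})

#' @title Out-of-bag MSE curve over nested top-k models
#' @description For each k, the mean (over repeated fits) out-of-bag MSE of
#'   a forest using the top-k ranked regions plus the covariates. `kMin` is
#'   the argmin; `kChosen` applies the parsimony rule (`one_se` picks the
#'   smallest k whose mean MSE is within one standard error of the minimum,
#'   `strict_min` picks the argmin itself), so `kChosen <= kMin` always.
#' @slot k,meanMse,mseSe the curve (k = 1..m).
#' @slot kMin,kChosen argmin and selected model size.
#' @slot rule parsimony rule applied.
#' @slot outcome outcome name.
#' @exportClass SelectionCurve
setClass("SelectionCurve",
         representation(k = "integer", meanMse = "numeric",
                        mseSe = "numeric", kMin = "integer",
                        kChosen = "integer", rule = "character",
                        outcome = "character"))

setValidity("SelectionCurve", function(object) {
  if (length(object@meanMse) != length(object@k)) return("length mismatch")
  if (!all(is.finite(object@meanMse))) return("mean MSE must be finite")
  if (length(object@kChosen) && length(object@kMin) &&
      object@kChosen > object@kMin)
    return("kChosen must not exceed kMin")
  TRUE
})
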