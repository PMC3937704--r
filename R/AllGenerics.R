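#' @name accessors
#' @title Accessors for MorphoCog classes
#' @description Small accessor layer so downstream code never touches slots
#'   or assay names directly.
#' @param x an object.
#' @param ... passed on.
#' @return `morphometry()` the regions x subjects matrix; `regionKind()`
#'   per-region `"thickness"`/`"volume_ratio"`; `groupLabels()` the
#'   control/case factor; `residualsMatrix()` the regions x subjects residual
#'   matrix; `rankingTable()`/`curveTable()` plain `data.frame` views;
#'   `chosenK()` the selected model size.
NULL

#' @rdname accessors
#' @export
setGeneric("morphometry", function(x, ...) standardGeneric("morphometry"))
#' @rdname accessors
#' @export
setGeneric("regionKind", function(x, ...) standardGeneric("regionKind"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x, ...) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("residualsMatrix",
           function(x, ...) standardGeneric("residualsMatrix"))
#' @rdname accessors
#' @export
setGeneric("rankingTable", function(x, ...) standardGeneric("rankingTable"))
#' @rdname accessors
#' @export
setGeneric("curveTable", function(x, ...) standardGeneric("curveTable"))
#' @rdname accessors
#' @export
setGeneric("chosenK", function(x, ...) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setMethod("morphometry", "HDCohort", function(x, ...)
  SummarizedExperiment::assay(x, "morphometry"))

#' @rdname accessors
#' @export
setMethod("regionKind", "HDCohort", function(x, ...)
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$kind),
                  rownames(x)))

#' @rdname accessors
#' @export
setMethod("groupLabels", "HDCohort", function(x, ...)
  stats::setNames(SummarizedExperiment::colData(x)$group, colnames(x)))

#' @rdname accessors
#' @export
setMethod("groupLabels", "ResidualSet", function(x, ...)
  stats::setNames(SummarizedExperiment::colData(x)$group, colnames(x)))

#' @rdname accessors
#' @export
setMethod("residualsMatrix", "ResidualSet", function(x, ...)
  SummarizedExperiment::assay(x, "residuals"))

#' @rdname accessors
#' @export
setMethod("rankingTable", "ImportanceRanking", function(x, ...)
  as.data.frame(x@table))

#' @rdname accessors
#' @export
setMethod("curveTable", "SelectionCurve", function(x, ...)
  data.frame(k = x@k, mean_mse = x@meanMse, mse_se = x@mseSe))

#' @rdname accessors
#' @export
setMethod("chosenK", "SelectionCurve", function(x, ...) x@kChosen)

setMethod("show", "HDCohort", function(object) {
  g <- table(SummarizedExperiment::colData(object)$group)
  cat("HDCohort: ", nrow(object), " regions x ", ncol(object),
      " subjects (", g[["control"]], " control / ", g[["case"]],
      " case)\n", sep = "")
  k <- table(SummarizedExperiment::rowData(object)$kind)
  cat("  regions: ", paste(names(k), k, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (length(S4Vectors::metadata(object)$ground_truth))
    cat("  simulated cohort with ground truth attached\n")
})

setMethod("show", "NormativeModel", function(object) {
  cat("NormativeModel: ", length(object@forests), " per-region forests (",
      object@nTrees, " trees each), trained on ", length(object@trainingIds),
      " controls\n", sep = "")
  cat("  control prediction mode: ", object@mode, "; training ages ",
      round(object@ageRange[1], 1), "-", round(object@ageRange[2], 1),
      "\n", sep = "")
  cat("  median OOB R^2 across regions: ",
      round(stats::median(object@oobR2), 3), "\n", sep = "")
})

setMethod("show", "ImportanceRanking", function(object) {
  cat("ImportanceRanking for '", object@outcome, "': ",
      nrow(object@table), " sMRI variables, ",
      object@config$nRepetitions, " repetitions x ",
      object@config$nTrees, " trees\n", sep = "")
  print(utils::head(as.data.frame(object@table), 5))
})

setMethod("show", "SelectionCurve", function(object) {
  cat("SelectionCurve for '", object@outcome, "': k = 1..",
      max(object@k), ", kMin = ", object@kMin, ", kChosen = ",
      object@kChosen, " (", object@rule, ")\n", sep = "")
})
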