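#' Run configuration for the full pipeline
#'
#' Bundles everything a run needs: where the data come from (a
#' [simulationConfig()] or the three CSV paths), the output directory, the
#' master seed, screening alpha, parsimony rule, outcome list, and the
#' scale of the forest stages. `scale = "full"` uses the protocol values
#' (normative 500 trees; ranking 5000 trees x 1000 repetitions; selection
#' 200 runs); `scale = "reduced"` uses desk-scale values (200 trees;
#' 400 x 50; 50 runs) for tests and smoke runs — deviations from protocol
#' scale are recorded in the run metadata.
#'
#' @param outdir output directory.
#' @param seed master seed; every stage derives its seeds from it.
#' @param simulation a [simulationConfig()], or `NULL` to read CSVs.
#' @param subjectsPath,morphometryPath,cognitionPath input CSVs when
#'   `simulation` is `NULL`.
#' @param alpha screening FDR level.
#' @param rule parsimony rule for [chooseK()].
#' @param outcomes cognitive outcomes to analyze.
#' @param scale `"reduced"` or `"full"`.
#' @param normativeMode control prediction mode, see [fitNormative()].
#' @param scaleValues optional named list overriding the per-stage sizes
#'   implied by `scale` (`normTrees`, `rankTrees`, `nRepetitions`,
#'   `nRuns`), e.g. for smoke tests.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(outdir, seed = 1L, simulation = simulationConfig(),
                      subjectsPath = NULL, morphometryPath = NULL,
                      cognitionPath = NULL, alpha = 0.05,
                      rule = c("one_se", "strict_min"),
                      outcomes = .cognitionCols,
                      scale = c("reduced", "full"),
                      normativeMode = "oob", scaleValues = NULL) {
  scale <- match.arg(scale)
  sc <- if (scale == "full")
    list(normTrees = 500L, rankTrees = 5000L, nRepetitions = 1000L,
         nRuns = 200L)
  else
    list(normTrees = 200L, rankTrees = 400L, nRepetitions = 50L,
         nRuns = 50L)
  if (!is.null(scaleValues)) sc[names(scaleValues)] <- scaleValues
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulation = simulation, subjectsPath = subjectsPath,
                 morphometryPath = morphometryPath,
                 cognitionPath = cognitionPath, alpha = alpha,
                 rule = match.arg(rule), outcomes = outcomes,
                 scale = scale, scaleValues = sc,
                 normativeMode = normativeMode),
            class = "RunConfig")
}

.configHash <- function(config) {
  # hash the scientific configuration only: output location and input
  # paths must not change the recorded identity of the analysis
  cfg <- config[setdiff(names(config),
                        c("outdir", "subjectsPath", "morphometryPath",
                          "cognitionPath"))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full two-stage pipeline
#'
#' Orchestrates simulate/load, normative adjustment, region screening,
#' importance ranking, model selection and group comparison, writing each
#' stage's tables (CSV) and a JSON metadata sidecar before the next stage
#' begins. Outputs are pure functions of (inputs, config, seed): a rerun
#' with the same configuration produces byte-identical files.
#'
#' @param config a [runConfig()].
#' @param stages subset of
#'   `c("simulate", "normative", "screen", "rank", "select", "compare")` to
#'   execute, in pipeline order; later stages require earlier ones in the
#'   same call.
#' @return invisibly, a list with the run summary (selected k per outcome,
#'   predictor set, output paths).
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "normative", "screen",
                                   "rank", "select", "compare")) {
  stopifnot(inherits(config, "RunConfig"))
  allStages <- c("simulate", "normative", "screen", "rank", "select",
                 "compare")
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$scaleValues
  meta <- list(seed = config$seed, config_hash = .configHash(config),
               package_version = as.character(utils::packageVersion(
                 "MorphoCog")),
               scale = config$scale, scale_values = sc,
               deviations = if (config$scale == "reduced")
                 "forest sizes reduced from protocol scale (5000/1000/200)"
               else "none")
  summaryOut <- list()

  # --- data ---
  if ("simulate" %in% stages || !is.null(config$simulation)) {
    cohort <- simulateCohort(config$simulation)
    if ("simulate" %in% stages) {
      writeCohort(cohort, config$outdir)
      gt <- S4Vectors::metadata(cohort)$ground_truth
      jsonlite::write_json(
        gt[c("atrophy_regions", "outcome_regions", "n_floored")],
        file.path(config$outdir, "ground_truth.json"),
        auto_unbox = TRUE, digits = NA)
    }
  } else {
    cohort <- readCohort(config$subjectsPath, config$morphometryPath,
                         config$cognitionPath)
  }
  meta$n_control <- sum(groupLabels(cohort) == "control")
  meta$n_case <- sum(groupLabels(cohort) == "case")
  if (!"normative" %in% stages) {
    .writeMeta(meta, config$outdir)
    return(invisible(list(cohort = cohort, metadata = meta)))
  }

  # --- normative adjustment ---
  model <- fitNormative(cohort, nTrees = sc$normTrees,
                        seed = deriveSeed(config$seed, 1001L),
                        mode = config$normativeMode)
  res <- residualizeCohort(model, cohort)
  rdf <- as.data.frame(t(residualsMatrix(res)))
  rdf <- cbind(data.frame(subject_id = rownames(rdf),
                          group = as.character(groupLabels(res))), rdf)
  utils::write.csv(.fmtNumeric(rdf),
                   file.path(config$outdir, "residuals.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(mode = model@mode, n_trees = model@nTrees,
         seed = model@seed, oob_r2 = as.list(round(model@oobR2, 6))),
    file.path(config$outdir, "normative_meta.json"),
    auto_unbox = TRUE, digits = NA)
  if (!"screen" %in% stages) {
    .writeMeta(meta, config$outdir)
    return(invisible(list(cohort = cohort, model = model, metadata = meta)))
  }

  # --- screening ---
  screen <- screenRegions(res, alpha = config$alpha)
  utils::write.csv(.fmtNumeric(as.data.frame(screen)),
                   file.path(config$outdir, "screening.csv"),
                   row.names = FALSE, quote = FALSE)
  predictors <- S4Vectors::metadata(screen)$predictor_set
  jsonlite::write_json(list(alpha = config$alpha,
                            predictor_set = predictors),
                       file.path(config$outdir, "predictor_set.json"),
                       auto_unbox = TRUE, digits = NA)
  summaryOut$predictor_set <- predictors
  if (!length(predictors)) {
    meta$halted <- "empty predictor set after screening"
    .writeMeta(meta, config$outdir)
    warning("pipeline halted after screening: empty predictor set")
    return(invisible(list(cohort = cohort, screen = screen,
                          metadata = meta)))
  }
  if (!"rank" %in% stages) {
    .writeMeta(meta, config$outdir)
    return(invisible(list(cohort = cohort, screen = screen,
                          metadata = meta)))
  }

  # --- ranking / selection / report, per outcome ---
  selectedK <- list()
  for (o in config$outcomes) {
    fc <- forestConfig(nTrees = sc$rankTrees,
                       nRepetitions = sc$nRepetitions,
                       seed = deriveSeed(config$seed,
                                         2000L + match(o, .cognitionCols)))
    ranking <- rankVariables(cohort, o, predictors, config = fc)
    utils::write.csv(.fmtNumeric(rankingTable(ranking)),
                     file.path(config$outdir,
                               paste0("importance_", o, ".csv")),
                     row.names = FALSE, quote = FALSE)
    if ("select" %in% stages) {
      curve <- buildCurve(cohort, ranking, nRuns = sc$nRuns,
                          nTrees = sc$rankTrees, rule = config$rule,
                          seed = deriveSeed(config$seed,
                                            3000L + match(o,
                                                          .cognitionCols)))
      utils::write.csv(.fmtNumeric(curveTable(curve)),
                       file.path(config$outdir, paste0("curve_", o,
                                                       ".csv")),
                       row.names = FALSE, quote = FALSE)
      sel <- reportSelected(cohort, ranking, chosenK(curve))
      utils::write.csv(.fmtNumeric(sel),
                       file.path(config$outdir,
                                 paste0("selected_", o, ".csv")),
                       row.names = FALSE, quote = FALSE)
      selectedK[[o]] <- chosenK(curve)
    }
  }
  summaryOut$selected_k <- selectedK

  # --- group comparison ---
  if ("compare" %in% stages) {
    cmp <- compareGroups(cohort)
    utils::write.csv(.fmtNumeric(cmp),
                     file.path(config$outdir, "group_comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(.fmtNumeric(cognitiveSummary(cohort)),
                     file.path(config$outdir, "cognitive_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  meta$selected_k <- selectedK
  .writeMeta(meta, config$outdir)
  invisible(c(summaryOut, list(metadata = meta, outdir = config$outdir)))
}

.writeMeta <- function(meta, outdir) {
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(meta["selected_k"] ,
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
}
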