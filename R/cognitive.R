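#' Timing precision from intertap intervals
#'
#' Precision of unpaced (continuation-phase) tapping, defined as the
#' reciprocal of the within-subject standard deviation (denominator n - 1)
#' of the intertap intervals, in 1/ms.
#'
#' @param intertapIntervals numeric vector of intervals in ms, length >= 3.
#' @return precision in 1/ms.
#' @examples
#' timingPrecision(c(540, 550, 560))  # SD = 10 ms -> 0.1
#' @export
timingPrecision <- function(intertapIntervals) {
  x <- as.numeric(intertapIntervals)
  if (length(x) < 3) stop("need at least 3 intertap intervals")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: intertap intervals have zero variance")
  1 / s
}

#' Covariate-adjusted group comparison of a cognitive outcome
#'
#' Ordinary least squares ANCOVA `outcome ~ group + age + sex + education +
#' visit_count`; the reported effect is the case-minus-control group
#' coefficient with its t statistic and (unadjusted) p-value. With a single
#' two-level factor and continuous covariates the group test does not
#' depend on the sums-of-squares convention.
#'
#' @param outcome numeric vector.
#' @param group factor with levels control/case (control reference).
#' @param covariates data.frame with columns age, sex, education_years,
#'   visit_count (sex may be a factor; it enters as a binary indicator).
#' @return list: outcome name placeholder `effect` (case - control, outcome
#'   units), `t_statistic`, `p_value`, `n`, and `covariates` used.
#' @export
ancovaGroupTest <- function(outcome, group, covariates) {
  group <- factor(as.character(group), levels = c("control", "case"))
  cov <- as.data.frame(covariates)
  if ("sex" %in% names(cov) && !is.numeric(cov$sex))
    cov$sex <- as.numeric(factor(as.character(cov$sex),
                                 levels = c("female", "male")) == "male")
  df <- data.frame(.y = as.numeric(outcome), .grp = group, cov)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (length(unique(df$.grp)) < 2)
    stop("both groups must be represented")
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  row <- grep("^\\.grpcase$", rownames(sm))
  list(effect = unname(sm[row, "Estimate"]),
       t_statistic = unname(sm[row, "t value"]),
       p_value = unname(sm[row, "Pr(>|t|)"]),
       n = nrow(df),
       covariates = setdiff(names(cov), character(0)))
}

#' Pre-check of practice (visit) effects on an outcome
#'
#' ANCOVA with visit count, group and their interaction, covarying age, sex
#' and education. Returns the F-test p-values for the visit main effect
#' (added to the covariate model) and for the visit-by-group interaction
#' (added to the main-effects model), so callers can mirror the decision to
#' retain visit count as a covariate regardless of the outcome.
#'
#' @param outcome numeric vector.
#' @param group control/case factor.
#' @param visitCount integer vector with at least 2 distinct values.
#' @param covariates data.frame with age, sex, education_years.
#' @return list with `p_visit` and `p_interaction`; if only one visit level
#'   is present, both are `NA` with a notice.
#' @export
visitEffectCheck <- function(outcome, group, visitCount, covariates) {
  cov <- as.data.frame(covariates)
  if ("sex" %in% names(cov) && !is.numeric(cov$sex))
    cov$sex <- as.numeric(factor(as.character(cov$sex),
                                 levels = c("female", "male")) == "male")
  df <- data.frame(.y = as.numeric(outcome),
                   .grp = factor(as.character(group),
                                 levels = c("control", "case")),
                   .visit = as.numeric(visitCount), cov)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$.visit)) < 2) {
    message("single visit level; visit-effect check skipped")
    return(list(p_visit = NA_real_, p_interaction = NA_real_))
  }
  covTerms <- paste(setdiff(names(df), c(".y", ".grp", ".visit")),
                    collapse = " + ")
  base <- stats::lm(stats::as.formula(paste(".y ~ .grp +", covTerms)),
                    data = df)
  mainM <- stats::update(base, . ~ . + .visit)
  full <- stats::update(mainM, . ~ . + .visit:.grp)
  pVisit <- stats::anova(base, mainM)[2, "Pr(>F)"]
  pInt <- stats::anova(mainM, full)[2, "Pr(>F)"]
  list(p_visit = pVisit, p_interaction = pInt)
}

#' Per-group summary of the cognitive outcomes
#'
#' Mean and SD of every cognitive score in each group — the content of the
#' usual group-performance figure.
#'
#' @param cohort an [HDCohort-class].
#' @return data.frame with outcome, control_mean, control_sd, case_mean,
#'   case_sd, and per-group n (missing scores excluded per outcome).
#' @export
cognitiveSummary <- function(cohort) {
  cd <- SummarizedExperiment::colData(cohort)
  rows <- lapply(intersect(.cognitionCols, names(cd)), function(o) {
    y <- cd[[o]]
    ctrl <- y[cd$group == "control"]
    case <- y[cd$group == "case"]
    data.frame(outcome = o,
               control_mean = mean(ctrl, na.rm = TRUE),
               control_sd = stats::sd(ctrl[!is.na(ctrl)]),
               case_mean = mean(case, na.rm = TRUE),
               case_sd = stats::sd(case[!is.na(case)]),
               n_control = sum(!is.na(ctrl)), n_case = sum(!is.na(case)))
  })
  do.call(rbind, rows)
}

#' Group comparisons for all five cognitive outcomes
#'
#' Applies [ancovaGroupTest()] to each cognitive score of a cohort,
#' adjusting for age, sex, education and visit count; per the protocol the
#' five tests are reported unadjusted for multiplicity.
#'
#' @param cohort an [HDCohort-class].
#' @return data.frame with outcome, effect, t, p, n.
#' @export
compareGroups <- function(cohort) {
  cd <- SummarizedExperiment::colData(cohort)
  covs <- data.frame(age = cd$age, sex = cd$sex,
                     education_years = cd$education_years,
                     visit_count = as.numeric(cd$visit_count))
  rows <- lapply(intersect(.cognitionCols, names(cd)), function(o) {
    r <- ancovaGroupTest(cd[[o]], cd$group, covs)
    data.frame(outcome = o, effect = r$effect, t = r$t_statistic,
               p = r$p_value, n = r$n)
  })
  do.call(rbind, rows)
}
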