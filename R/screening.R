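#' Two-sample Wilcoxon rank-sum test
#'
#' Thin, contract-checked wrapper around the rank-sum test used for region
#' screening: exact enumeration when both samples have at most 10
#' observations and the pooled data are tie-free, otherwise the normal
#' approximation with continuity and midrank tie correction. One-sided
#' `side = "greater"` tests H1: values in `a` tend to be larger than in
#' `b`. The exact one-sided p is the standard `P(W >= w_obs)` under the
#' permutation null.
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @param side `"greater"`, `"less"` or `"two.sided"`.
#' @return list with `statistic` (Mann-Whitney U for `a`) and `p_value`.
#' @export
wilcoxonRankSum <- function(a, b, side = c("greater", "less",
                                           "two.sided")) {
  side <- match.arg(side)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  if (length(unique(c(a, b))) == 1L) {
    warning("degenerate data: all values identical across both samples")
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  exact <- length(a) <= 10 && length(b) <= 10 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = side,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pValues vector of p-values in `[0, 1]`.
#' @param alpha FDR target in `(0, 1)` (default 0.05).
#' @return list with `q_values` (monotone BH-adjusted values) and `reject`
#'   (`q <= alpha`). Empty input gives empty output.
#' @export
benjaminiHochberg <- function(pValues, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!length(pValues))
    return(list(q_values = numeric(0), reject = logical(0)))
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pValues, method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= alpha)
}

#' Screen regions for case-group atrophy
#'
#' Per region, a one-sided Wilcoxon rank-sum test of control residuals
#' ("residual 1") against case residuals ("residual 2") in the atrophy
#' direction (`control > case`: thinner cortex / smaller striatum in
#' cases), followed by Benjamini-Hochberg FDR adjustment across all tested
#' regions (cortical and striatal in one family). Significant regions, in
#' their original order, form the sMRI predictor set for the main analyses.
#'
#' @param residuals a [ResidualSet-class] containing both groups.
#' @param alpha FDR level (default 0.05).
#' @return `DataFrame` with columns region, statistic, p_value, q_value,
#'   significant, direction; the predictor set is in
#'   `metadata()$predictor_set`.
#' @export
screenRegions <- function(residuals, alpha = 0.05) {
  stopifnot(is(residuals, "ResidualSet"))
  grp <- groupLabels(residuals)
  if (!all(c("control", "case") %in% grp))
    stop("residuals must contain both groups")
  res <- residualsMatrix(residuals)
  ctrl <- res[, grp == "control", drop = FALSE]
  case <- res[, grp == "case", drop = FALSE]
  stat <- p <- numeric(nrow(res))
  for (r in seq_len(nrow(res))) {
    w <- wilcoxonRankSum(ctrl[r, ], case[r, ], side = "greater")
    stat[r] <- w$statistic
    p[r] <- w$p_value
  }
  bh <- benjaminiHochberg(p, alpha)
  out <- S4Vectors::DataFrame(
    region = rownames(res), statistic = stat, p_value = p,
    q_value = bh$q_values, significant = bh$reject,
    direction = ifelse(bh$reject, "atrophy", "none"))
  S4Vectors::metadata(out) <- list(alpha = alpha,
                                   predictor_set = rownames(res)[bh$reject])
  if (!any(bh$reject))
    warning("no region passed screening; predictor set is empty")
  out
}
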