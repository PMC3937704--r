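# Shared fixtures, all generated in code.

# a small, fast cohort configuration for smoke-level tests
tinyConfig <- function(seed = 1L, ...) {
  args <- list(n_control = 40L, n_case = 60L, n_regions = 12L,
               atrophy_region_indices = c(1:4, 9:12),
               outcome_region_indices = c(1L, 2L, 9L),
               atrophy_effect_sd = 0.8, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulationConfig, args)
}

# hand-built cohort: 6 regions, one of which is an exact duplicate of the
# signal region; outcome driven by the signal region only
duplicatedPredictorCohort <- function(n = 80L, seed = 7L) {
  set.seed(seed)
  r1 <- rnorm(n)
  m <- cbind(r_signal = r1, r_dup = r1,
             r_noise1 = rnorm(n), r_noise2 = rnorm(n),
             r_noise3 = rnorm(n), r_noise4 = rnorm(n))
  m <- 2.5 + 0.15 * m
  ids <- sprintf("D%03d", seq_len(n))
  rownames(m) <- ids
  subj <- data.frame(
    subject_id = ids,
    group = factor(rep("case", n), levels = c("control", "case")),
    age = runif(n, 25, 65),
    sex = factor(sample(c("female", "male"), n, TRUE),
                 levels = c("female", "male")),
    education_years = runif(n, 10, 18), visit_count = sample(c(1L, 3L), n,
                                                             TRUE),
    row.names = ids)
  cog <- data.frame(sdmt = round(50 + 10 * r1),
                    letter_number = round(runif(n, 5, 20)),
                    hvlt_immediate = round(runif(n, 15, 30)),
                    negative_emotions = round(runif(n, 10, 25)),
                    timing_precision = runif(n, 0.02, 0.05),
                    row.names = ids)
  HDCohort(m, subj, kind = rep("thickness", 6), cognition = cog)
}

# write a minimal valid trio of cohort CSVs and return their paths
writeToyCsvs <- function(dir, nSubj = 5L, dropFromMorph = character(0)) {
  ids <- sprintf("T%02d", seq_len(nSubj))
  subj <- data.frame(subject_id = ids,
                     group = rep(c("control", "case"), length.out = nSubj),
                     age = seq(30, 60, length.out = nSubj),
                     sex = rep(c("female", "male"), length.out = nSubj),
                     education_years = 12, visit_count = 1L,
                     cag_repeats = 20L, motor_score = 1.5)
  keep <- setdiff(ids, dropFromMorph)
  morph <- data.frame(subject_id = keep, icv_mm3 = 1.5e6,
                      lh_precentral = seq(2.1, 2.9,
                                          length.out = length(keep)),
                      rh_precentral = 2.5,
                      lh_caudate_vol_mm3 = 3700 + seq_along(keep))
  cog <- data.frame(subject_id = ids, sdmt = 50L, letter_number = 11L,
                    hvlt_immediate = 25L, negative_emotions = 18L,
                    timing_precision = 0.034)
  paths <- file.path(dir, c("subjects.csv", "morphometry.csv",
                            "cognition.csv"))
  write.csv(subj, paths[1], row.names = FALSE)
  write.csv(morph, paths[2], row.names = FALSE)
  write.csv(cog, paths[3], row.names = FALSE)
  paths
}
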