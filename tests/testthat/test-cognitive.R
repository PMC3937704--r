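test_that("timing precision is the reciprocal sample SD of intertap
           intervals", {
  # sd(540, 550, 560) = 10 ms exactly
  expect_equal(timingPrecision(c(540, 550, 560)), 0.1)
  expect_error(timingPrecision(c(550, 550, 550)), "zero variance")
  expect_error(timingPrecision(c(550, 560)), "at least 3")
  # SD homogeneity: doubling all intervals halves the precision
  x <- c(510, 543, 572, 591)
  expect_equal(timingPrecision(2 * x), timingPrecision(x) / 2)
  # strictly decreasing in the interval SD
  expect_gt(timingPrecision(c(545, 550, 555)),
            timingPrecision(c(500, 550, 600)))
})

test_that("ANCOVA group test: exact confound, invariances, errors", {
  set.seed(91)
  n <- 120
  covs <- data.frame(age = runif(n, 20, 70),
                     sex = sample(c("female", "male"), n, TRUE),
                     education_years = runif(n, 8, 20),
                     visit_count = sample(c(1, 3), n, TRUE))
  grp <- factor(rep(c("control", "case"), n / 2),
                levels = c("control", "case"))
  # outcome an exact covariate combination: group coefficient must be 0
  y <- 2 * covs$age - 0.5 * covs$education_years + 3 * covs$visit_count
  r <- ancovaGroupTest(y, grp, covs)
  expect_lt(abs(r$effect), 1e-10)
  # affine rescaling of a covariate leaves the group effect untouched
  y2 <- y + ifelse(grp == "case", -2, 0) + rnorm(n)
  r2 <- ancovaGroupTest(y2, grp, covs)
  covsScaled <- covs
  covsScaled$age <- (covs$age - 40) / 12
  r3 <- ancovaGroupTest(y2, grp, covsScaled)
  expect_equal(r2$effect, r3$effect, tolerance = 1e-10)
  expect_equal(r2$t_statistic, r3$t_statistic, tolerance = 1e-8)
  # collinear design names the offender
  covBad <- covs
  covBad$age2 <- covs$age * 2
  expect_error(ancovaGroupTest(y2, grp, covBad), "age2")
})

test_that("ANCOVA is calibrated under the null and powered at 0.5 SD", {
  set.seed(92)
  nSim <- 500
  n <- 100
  rej <- logical(nSim)
  for (i in seq_len(nSim)) {
    covs <- data.frame(age = runif(n, 20, 70),
                       sex = sample(c("female", "male"), n, TRUE),
                       education_years = runif(n, 8, 20),
                       visit_count = sample(c(1, 3), n, TRUE))
    y <- 0.05 * covs$age + rnorm(n)
    grp <- factor(sample(rep(c("control", "case"), n / 2)),
                  levels = c("control", "case"))
    rej[i] <- ancovaGroupTest(y, grp, covs)$p_value < 0.05
  }
  se <- sqrt(0.05 * 0.95 / nSim)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)

  # 0.5 SD deficit at 119/325: detected nearly always
  hits <- vapply(1:100, function(i) {
    grp <- factor(rep(c("control", "case"), c(119, 325)),
                  levels = c("control", "case"))
    nn <- length(grp)
    covs <- data.frame(age = runif(nn, 20, 70),
                       sex = sample(c("female", "male"), nn, TRUE),
                       education_years = runif(nn, 8, 20),
                       visit_count = sample(c(1, 3), nn, TRUE))
    y <- rnorm(nn) - 0.5 * (grp == "case")
    ancovaGroupTest(y, grp, covs)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("visit-effect pre-check returns both p-values and is calibrated", {
  set.seed(93)
  n <- 160
  grp <- factor(rep(c("control", "case"), n / 2),
                levels = c("control", "case"))
  covs <- data.frame(age = runif(n, 20, 70),
                     sex = sample(c("female", "male"), n, TRUE),
                     education_years = runif(n, 8, 20))
  visits <- sample(c(1, 3), n, TRUE)
  out <- visitEffectCheck(rnorm(n), grp, visits, covs)
  expect_named(out, c("p_visit", "p_interaction"))

  # deterministic practice effect at the third visit is detected
  y <- rnorm(n, sd = 0.3) + 1.5 * (visits == 3)
  expect_lt(visitEffectCheck(y, grp, visits, covs)$p_visit, 1e-6)

  # null interaction rejects at about the nominal rate
  rej <- vapply(1:200, function(i) {
    yy <- rnorm(n)
    vv <- sample(c(1, 3), n, TRUE)
    visitEffectCheck(yy, grp, vv, covs)$p_interaction < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)

  # single visit level: skipped with a notice
  expect_message(r1 <- visitEffectCheck(rnorm(n), grp, rep(1, n), covs),
                 "skipped")
  expect_true(is.na(r1$p_visit) && is.na(r1$p_interaction))
})

test_that("compareGroups reports an adjusted deficit on every outcome", {
  co <- simulateCohort(tinyConfig(seed = 94L, n_control = 60L,
                                  n_case = 90L, atrophy_effect_sd = 1.5,
                                  outcome_signal = 1.5))
  cmp <- compareGroups(co)
  expect_setequal(cmp$outcome,
                  c("sdmt", "letter_number", "hvlt_immediate",
                    "negative_emotions", "timing_precision"))
  # atrophy drives outcomes down through the outcome regions: case effect
  # should be negative for the strongly driven outcomes
  expect_true(all(cmp$effect < 0))
  sm <- cognitiveSummary(co)
  expect_equal(nrow(sm), 5L)
  expect_equal(sm$n_control[1], 60L)
  expect_true(all(sm$case_mean < sm$control_mean))
})
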