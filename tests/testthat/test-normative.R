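test_that("constant regions predict constantly and residuals vanish", {
  n <- 30
  ids <- sprintf("C%02d", 1:n)
  m <- matrix(2.5, n, 2, dimnames = list(ids, c("r1", "r2")))
  subj <- data.frame(subject_id = ids,
                     group = factor(rep("control", n),
                                    levels = c("control", "case")),
                     age = runif(n, 20, 70),
                     sex = factor(rep(c("female", "male"), n / 2),
                                  levels = c("female", "male")),
                     education_years = 14, visit_count = 1L)
  co <- HDCohort(m, subj, kind = c("thickness", "thickness"))
  mod <- fitNormative(co, nTrees = 30, seed = 1)
  res <- residualize(mod, co)
  expect_equal(max(abs(residualsMatrix(res))), 0)
})

test_that("forests capture a pure quadratic age effect (OOB R^2 >= 0.9)", {
  cfg <- simulationConfig(n_control = 500L, n_case = 10L, n_regions = 12L,
                          atrophy_region_indices = 1:4, noise_sd = 0,
                          outcome_region_indices = 1L, seed = 21L)
  co <- simulateCohort(cfg)
  mod <- fitNormative(co, nTrees = 200, seed = 2)
  # noiseless age/sex response: the forest should explain nearly all of it
  # (thickness regions only: volume ratios carry simulated ICV noise)
  thick <- names(regionKind(co))[regionKind(co) == "thickness"]
  expect_gte(min(mod@oobR2[thick]), 0.9)
})

test_that("fitNormative refuses fewer than 20 controls and records mode", {
  co <- simulateCohort(tinyConfig(seed = 3L))
  small <- co[, c(which(groupLabels(co) == "control")[1:10],
                  which(groupLabels(co) == "case"))]
  expect_error(fitNormative(small, nTrees = 20, seed = 1), "20 controls")
  mod <- fitNormative(co, nTrees = 20, seed = 1, mode = "in_sample")
  expect_equal(mod@mode, "in_sample")
  expect_identical(sort(mod@trainingIds),
                   sort(colnames(co)[groupLabels(co) == "control"]))
})

test_that("residualize is deterministic and unit-preserving", {
  co <- simulateCohort(tinyConfig(seed = 4L))
  m1 <- fitNormative(co, nTrees = 50, seed = 7)
  m2 <- fitNormative(co, nTrees = 50, seed = 7)
  r1 <- residualizeCohort(m1, co)
  r2 <- residualizeCohort(m2, co)
  expect_identical(residualsMatrix(r1), residualsMatrix(r2))
  # residual = observed - predicted in source units: adding 0.1 mm to one
  # region's observations shifts its residuals by exactly 0.1
  m <- t(morphometry(co))
  m[, "region_005"] <- m[, "region_005"] + 0.1
  co2 <- HDCohort(m, cbind(subject_id = colnames(co),
                           as.data.frame(SummarizedExperiment::colData(co))),
                  kind = unname(regionKind(co)))
  r3 <- residualize(m1, co2[, groupLabels(co2) == "case"])
  rc <- residualize(m1, co[, groupLabels(co) == "case"])
  expect_equal(residualsMatrix(r3)["region_005", ],
               residualsMatrix(rc)["region_005", ] + 0.1)
})

test_that("mixed training/non-training subject sets are rejected and
           out-of-range ages only warn", {
  co <- simulateCohort(tinyConfig(seed = 5L))
  mod <- fitNormative(co, nTrees = 30, seed = 2)
  expect_error(residualize(mod, co), "disjoint")
  cases <- co[, groupLabels(co) == "case"]
  SummarizedExperiment::colData(cases)$age[1] <- 99
  expect_warning(residualize(mod, cases), "extrapolate")
})

test_that("atrophy shows up as case residuals below control residuals", {
  # moderate effect; the gap should appear in the large majority of
  # replicates (Monte-Carlo check at reduced scale)
  hits <- vapply(1:20, function(i) {
    co <- simulateCohort(tinyConfig(seed = 200L + i,
                                    atrophy_effect_sd = 0.5))
    mod <- fitNormative(co, nTrees = 100, seed = i)
    res <- residualizeCohort(mod, co)
    g <- groupLabels(res)
    r <- residualsMatrix(res)["region_001", ]
    mean(r[g == "control"]) > mean(r[g == "case"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("oob mode avoids the in-sample shrinkage bias", {
  co <- simulateCohort(tinyConfig(seed = 6L, n_control = 80L))
  ctrl <- co[, groupLabels(co) == "control"]
  mOob <- fitNormative(co, nTrees = 150, seed = 3, mode = "oob")
  mIn <- fitNormative(co, nTrees = 150, seed = 3, mode = "in_sample")
  rOob <- residualsMatrix(residualize(mOob, ctrl))
  rIn <- residualsMatrix(residualize(mIn, ctrl))
  # in-sample forest predictions hug the training data
  expect_lt(mean(abs(rIn)), mean(abs(rOob)))
  # oob control residuals are centered: |mean| within 2 SE of 0 per region
  mu <- rowMeans(rOob)
  se <- apply(rOob, 1, sd) / sqrt(ncol(rOob))
  expect_gt(mean(abs(mu) <= 2 * se), 0.8)
})
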