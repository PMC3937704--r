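rankingFixture <- function(nRep = 10, nTrees = 60, seed = 1L) {
  co <- simulateCohort(tinyConfig(seed = 71L, outcome_signal = 2,
                                  noise_sd = 0.6))
  preds <- S4Vectors::metadata(co)$ground_truth$atrophy_regions
  list(cohort = co, preds = preds,
       cfg = forestConfig(nTrees = nTrees, nRepetitions = nRep,
                          seed = seed))
}

test_that("ranking recovers outcome-driving regions and conserves ranks", {
  fx <- rankingFixture()
  rk <- rankVariables(fx$cohort, "sdmt", fx$preds, config = fx$cfg)
  tb <- rankingTable(rk)
  m <- nrow(tb)
  expect_setequal(tb$variable, fx$preds)
  # rank conservation: midranks make each repetition sum to m(m+1)/2
  expect_equal(mean(tb$meanRank), (m + 1) / 2, tolerance = 1e-12)
  expect_true(all(tb$meanRank >= 1 & tb$meanRank <= m))
  # outcome regions (strong signal) should head the ranking
  truth <- S4Vectors::metadata(fx$cohort)$ground_truth$
    outcome_regions$sdmt
  expect_lte(max(tb$meanRank[tb$variable %in% truth]), m / 2)
})

test_that("rankings are deterministic and invariant to predictor order", {
  fx <- rankingFixture(nRep = 3, nTrees = 40)
  rk1 <- rankVariables(fx$cohort, "sdmt", fx$preds, config = fx$cfg)
  rk2 <- rankVariables(fx$cohort, "sdmt", rev(fx$preds), config = fx$cfg)
  expect_identical(rankingTable(rk1), rankingTable(rk2))
  rk3 <- rankVariables(fx$cohort, "sdmt", sample(fx$preds),
                       config = fx$cfg)
  expect_identical(rankingTable(rk1), rankingTable(rk3))
  # single repetition, run twice: identical (determinism contract)
  cfg1 <- forestConfig(nTrees = 40, nRepetitions = 1, seed = 5)
  a <- rankVariables(fx$cohort, "sdmt", fx$preds, config = cfg1)
  b <- rankVariables(fx$cohort, "sdmt", fx$preds, config = cfg1)
  expect_identical(rankingTable(a), rankingTable(b))
})

test_that("duplicated predictors share importance symmetrically", {
  co <- duplicatedPredictorCohort()
  rk <- rankVariables(co, "sdmt", rownames(co),
                      covariates = c("age", "sex"),
                      config = forestConfig(nTrees = 150,
                                            nRepetitions = 25, seed = 3),
                      keepRankMatrix = TRUE)
  tb <- rankingTable(rk)
  dup <- tb[tb$variable %in% c("r_signal", "r_dup"), ]
  # credit is split stochastically; mean ranks must not diverge by more
  # than the between-repetition rank variability
  expect_lt(abs(diff(dup$meanRank)), max(dup$rankSd))
  # and both duplicates still beat the pure-noise regions
  expect_lt(max(dup$meanRank),
            min(tb$meanRank[grepl("noise", tb$variable)]))
})

test_that("stronger generative signal never worsens the mean rank", {
  ranks <- vapply(c(0.5, 1.5, 3), function(bet) {
    rs <- vapply(1:3, function(i) {
      co <- simulateCohort(tinyConfig(seed = 300L + i,
                                      outcome_signal = bet))
      preds <- S4Vectors::metadata(co)$ground_truth$atrophy_regions
      rk <- rankVariables(co, "sdmt", preds,
                          config = forestConfig(nTrees = 50,
                                                nRepetitions = 5,
                                                seed = i))
      tb <- rankingTable(rk)
      mean(tb$meanRank[tb$variable %in%
                         S4Vectors::metadata(co)$ground_truth$
                           outcome_regions$sdmt])
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(ranks[1] >= ranks[2] && ranks[2] >= ranks[3])
})

test_that("contracts: sample size, unknown inputs, failing repetition", {
  fx <- rankingFixture(nRep = 2, nTrees = 20)
  small <- fx$cohort[, c(seq_len(20),
                         which(groupLabels(fx$cohort) == "case")[1:20])]
  expect_error(rankVariables(small, "sdmt", fx$preds, config = fx$cfg),
               "at least 30 cases")
  expect_error(rankVariables(fx$cohort, "sdmt", character(0),
                             config = fx$cfg), "empty")
  expect_error(rankVariables(fx$cohort, "sdmt", c("nope"),
                             config = fx$cfg), "nope")
  expect_error(rankVariables(fx$cohort, "not_an_outcome", fx$preds,
                             config = fx$cfg), "outcome")
})
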