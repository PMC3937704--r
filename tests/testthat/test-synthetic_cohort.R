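test_that("the generator is deterministic and leaves R's RNG untouched", {
  set.seed(123)
  before <- .Random.seed
  a <- simulateCohort(tinyConfig(seed = 5L))
  expect_identical(.Random.seed, before)
  b <- simulateCohort(tinyConfig(seed = 5L))
  expect_identical(morphometry(a), morphometry(b))
  expect_identical(SummarizedExperiment::colData(a),
                   SummarizedExperiment::colData(b))
  c <- simulateCohort(tinyConfig(seed = 6L))
  expect_false(identical(morphometry(a), morphometry(c)))
})

test_that("default configuration matches the intended cohort structure", {
  cfg <- simulationConfig()
  expect_equal(cfg$n_control, 119L)
  expect_equal(cfg$n_case, 325L)
  expect_equal(cfg$n_regions, 72L)
  expect_length(cfg$atrophy_region_indices, 40L)
  co <- simulateCohort(simulationConfig(seed = 2L))
  expect_equal(dim(co), c(72L, 444L))
  expect_equal(sum(regionKind(co) == "volume_ratio"), 4L)
  expect_true(all(c("lh_caudate", "rh_putamen", "lh_precentral",
                    "rh_insula") %in% rownames(co)))
  gt <- S4Vectors::metadata(co)$ground_truth
  expect_true(all(unlist(gt$outcome_regions) %in% gt$atrophy_regions))
  expect_true(validObject(co))
})

test_that("severity factors are positive, right-skewed, mean 1", {
  s <- severityProfile(1000, seed = 4L)
  expect_true(all(s > 0))
  # gamma(2, 0.5): SE of the mean at n=1000 is 0.0224; 0.05 ~ 2.2 SE
  expect_lt(abs(mean(s) - 1), 0.05)
  expect_gt(mean((s - mean(s))^3), 0) # right skew
  expect_length(severityProfile(1, seed = 1L), 1L)
  expect_identical(severityProfile(50, seed = 9L),
                   severityProfile(50, seed = 9L))
})

test_that("a null cohort shows no systematic group difference", {
  # atrophy_effect_sd = 0: groups exchangeable; region-wise Wilcoxon on raw
  # morphometry rejects at about the nominal rate
  pvals <- unlist(lapply(1:25, function(i) {
    co <- simulateCohort(tinyConfig(seed = 100L + i, atrophy_effect_sd = 0))
    g <- groupLabels(co)
    m <- morphometry(co)
    apply(m, 1, function(v)
      wilcox.test(v[g == "control"], v[g == "case"])$p.value)
  }))
  rate <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("with zero noise and no covariate effects the outcome is an exact
           affine function of its single driver region", {
  cfg <- simulationConfig(n_control = 15L, n_case = 30L, n_regions = 12L,
                          atrophy_region_indices = 1:4,
                          outcome_region_indices = 2L, noise_sd = 0,
                          outcome_model = "linear",
                          outcome_covariate_scale = 0, seed = 3L)
  co <- simulateCohort(cfg)
  y <- SummarizedExperiment::colData(co)$timing_precision # unrounded scale
  x <- morphometry(co)[2, ]
  fit <- lm(y ~ x)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("atrophy lowers case morphometry in the configured regions only", {
  co <- simulateCohort(tinyConfig(seed = 11L, atrophy_effect_sd = 1.5))
  g <- groupLabels(co)
  m <- morphometry(co)
  gt <- S4Vectors::metadata(co)$ground_truth
  dif <- rowMeans(m[, g == "control"]) - rowMeans(m[, g == "case"])
  inA <- rownames(co) %in% gt$atrophy_regions
  # thickness scale: every atrophied region should sit above the spared ones
  expect_gt(min(dif[inA & regionKind(co) == "thickness"]),
            max(dif[!inA]))
})

test_that("config invariants are enforced", {
  expect_error(simulationConfig(n_control = 5), ">= 10")
  expect_error(simulationConfig(atrophy_region_indices = integer(0),
                                outcome_region_indices = 3L),
               "nonempty atrophy set")
  expect_error(simulationConfig(n_regions = 10,
                                atrophy_region_indices = 1:12),
               "out of range")
  expect_error(
    simulationConfig(atrophy_region_indices = 1:5,
                     outcome_region_indices = 7L), "subset")
})
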