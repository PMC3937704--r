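test_that("one-sided rank-sum p-values equal exhaustive enumeration", {
  # tie-free small samples: exact path must agree with brute-force
  # enumeration of all rank assignments, p = P(W >= w_obs)
  set.seed(51)
  for (i in 1:20) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    a <- round(rnorm(na), 3)
    b <- round(rnorm(nb, mean = 0.5), 3)
    if (any(duplicated(c(a, b)))) next
    for (side in c("greater", "less", "two.sided")) {
      got <- wilcoxonRankSum(a, b, side = side)$p_value
      expect_equal(got, enumWilcoxP(a, b, side), tolerance = 1e-12,
                   info = paste(side, i))
    }
  }
  # fully separated samples: the most extreme of the C(6,3)=20 splits
  expect_equal(wilcoxonRankSum(c(10, 11, 12), c(1, 2, 3),
                               side = "greater")$p_value, 1 / 20)
  expect_equal(enumWilcoxP(c(10, 11, 12), c(1, 2, 3)), 1 / 20)
})

test_that("identical samples give p >= 0.5 and degenerate data warn", {
  expect_gte(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3),
                             side = "greater")$p_value, 0.5)
  expect_warning(r <- wilcoxonRankSum(rep(1, 4), rep(1, 5)), "degenerate")
  expect_equal(r$p_value, 1)
  expect_error(wilcoxonRankSum(1, c(1, 2)), "at least 2")
})

test_that("ties fall back to the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 5)
  b <- c(2, 3, 3, 4, 6, 7)
  got <- wilcoxonRankSum(a, b, side = "greater")
  ref <- suppressWarnings(wilcox.test(a, b, alternative = "greater",
                                      exact = FALSE, correct = TRUE))
  expect_equal(got$p_value, ref$p.value)
})

test_that("BH matches a hand-executed step-up procedure", {
  bh <- benjaminiHochberg(c(0.01, 0.02, 0.20), alpha = 0.05)
  # step-up: 0.20 > 3/3*0.05; 0.02 <= 2/3*0.05; reject first two
  expect_identical(bh$reject, c(TRUE, TRUE, FALSE))
  expect_equal(bh$q_values, c(0.03, 0.03, 0.20))

  expect_identical(benjaminiHochberg(rep(0, 4))$reject, rep(TRUE, 4))
  expect_equal(benjaminiHochberg(0.04, 0.05)$q_values, 0.04)
  expect_true(benjaminiHochberg(0.04, 0.05)$reject)
  expect_length(benjaminiHochberg(numeric(0))$q_values, 0)

  set.seed(52)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    ours <- benjaminiHochberg(p, 0.05)
    manual <- bhManual(p, 0.05)
    expect_equal(ours$q_values, manual$q, tolerance = 1e-12)
    expect_identical(ours$reject, manual$reject)
    # BH rejections always contain the Bonferroni rejections
    expect_true(all(ours$reject[p <= 0.05 / length(p)]))
  }
})

test_that("screening flags atrophied regions, one-sided, FDR-ordered", {
  co <- simulateCohort(tinyConfig(seed = 61L, atrophy_effect_sd = 1.2))
  mod <- fitNormative(co, nTrees = 100, seed = 5)
  res <- residualizeCohort(mod, co)
  sc <- screenRegions(res, alpha = 0.05)
  gt <- S4Vectors::metadata(co)$ground_truth
  sel <- S4Vectors::metadata(sc)$predictor_set
  expect_true(all(gt$atrophy_regions %in% sel))
  expect_true(all(sc$q_value[sc$significant] <= 0.05))
  expect_identical(sel, sc$region[sc$significant]) # original region order
})

test_that("a shift in the wrong direction is never selected", {
  set.seed(62)
  n1 <- 40; n2 <- 60
  res <- matrix(rnorm(5 * (n1 + n2), sd = 0.1), 5,
                dimnames = list(paste0("r", 1:5),
                                sprintf("s%03d", 1:(n1 + n2))))
  res[3, (n1 + 1):(n1 + n2)] <- res[3, (n1 + 1):(n1 + n2)] + 0.1 # thicker!
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(residuals = res),
    colData = S4Vectors::DataFrame(
      group = factor(rep(c("control", "case"), c(n1, n2)),
                     levels = c("control", "case"))))
  rs <- methods::as(se, "ResidualSet")
  sc <- suppressWarnings(screenRegions(rs))
  expect_false("r3" %in% S4Vectors::metadata(sc)$predictor_set)
})

test_that("selection is invariant to a monotone transform of one region", {
  co <- simulateCohort(tinyConfig(seed = 63L, atrophy_effect_sd = 0.6))
  mod <- fitNormative(co, nTrees = 80, seed = 6)
  res <- residualizeCohort(mod, co)
  sc1 <- suppressWarnings(screenRegions(res))
  r <- SummarizedExperiment::assay(res, "residuals")
  r["region_002", ] <- exp(r["region_002", ]) # strictly increasing
  res2 <- methods::as(SummarizedExperiment::SummarizedExperiment(
    assays = list(residuals = r),
    colData = SummarizedExperiment::colData(res)), "ResidualSet")
  sc2 <- suppressWarnings(screenRegions(res2))
  expect_identical(sc1$significant, sc2$significant)
  expect_equal(sc1$p_value, sc2$p_value)
})
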