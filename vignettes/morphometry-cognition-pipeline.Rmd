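---
title: "Mapping regional brain morphometry to cognition with random forests"
author: "MorphoCog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping regional brain morphometry to cognition with random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MorphoCog)
```

## The problem

In prodromal Huntington disease (prHD), gene-expansion carriers show
measurable striatal atrophy and cortical thinning years before motor
diagnosis, and perform worse across several cognitive domains. Which
regional pattern of morphometry goes with which cognitive domain is the
scientific question this package addresses. The statistical obstacles are
well known: dozens of regional measures, most of them strongly correlated;
likely interactions among regions; and no reason to assume linearity.
Random-forest regression handles all three, which is why the pipeline is
built around it rather than around multiple regression.

MorphoCog implements that analysis as a reusable, testable pipeline over
tabular inputs: per-subject demographics, regional cortical thickness (mm)
and basal-ganglia volumes expressed as volume/ICV ratios, and five
continuous cognitive scores. Image processing (segmentation, surface
reconstruction, parcellation) is out of scope; the pipeline starts from
already-extracted regional measures.

## The two-stage model

**Stage 1 — normative adjustment and screening.** Age and sex affect
morphometry in nonlinear, possibly interacting ways. For each region a
random-forest regressor is trained on the *control group only* with
predictors age and sex; trees absorb the nonlinearity and the age-by-sex
interaction without explicit terms. Residuals are then formed for both
groups against this normative model: "residual 1" for controls, "residual
2" for cases. Atrophy in cases makes residual 1 stochastically larger than
residual 2, so each region is tested with a one-sided two-sample Wilcoxon
rank-sum test (control residuals greater), and the Benjamini–Hochberg
step-up procedure at FDR 0.05 — one family covering cortical and striatal
regions together — selects the significant regions as the sMRI predictor
set.

Two details deserve justification:

* *Out-of-bag control predictions.* In-sample forest predictions hug the
  training data, which would shrink control residuals toward zero and
  exaggerate the control-case residual gap. Control predictions therefore
  default to out-of-bag aggregation (`mode = "oob"`); cases, being out of
  the training set, always use the full forest. `in_sample` remains
  available for comparison, and the shrinkage is assertable (and asserted
  in the tests).
* *mtry in the normative stage.* The usual regression rule
  `mtry = max(1, floor(p/3))` degenerates at p = 2: nodes that draw only
  the binary sex variable as candidate, and are already sex-pure, stall
  and truncate the tree. The normative forests therefore use both
  predictors as split candidates (bagged CART), which restores accuracy on
  smooth noiseless responses from around R² 0.85 to R² > 0.99.

**Stage 2 — importance ranking and parsimonious selection.** Within the
case group only, each cognitive outcome is modelled by a random forest on
the screened regions plus four covariates (age, sex, education, visit
count). The covariates take part in every fit — and count toward p in the
`mtry = max(1, floor(p/3))` rule — but never appear in the ranking.
Importance of a region is the raw permutation importance: the mean over
trees of the increase in out-of-bag MSE when that region's values are
permuted within the tree's OOB set, one fresh permutation per tree and per
variable. Because single-forest rankings are noisy in correlated data, the
whole fit is repeated (default 1000 times at 5000 trees per forest) and
the per-repetition ranks (midranks for ties, so each repetition's ranks
sum to m(m+1)/2) are averaged.

Model size is then chosen on the nested top-k curve: for each k, repeated
forests (default 200 runs) on the k best-ranked regions plus covariates,
recording mean OOB MSE and its standard error. `strict_min` takes the
argmin; the default `one_se` rule formalizes the "technically lowest but
very close — prefer the smaller model" judgement as the smallest k within
one standard error of the minimum, so it can never select a larger model
than the argmin. The reported top-k table includes a direction check: the
Spearman correlation between each selected region's morphometry and the
outcome in cases, flagged `consistent` when thinner/smaller accompanies
worse performance, `indeterminate` below a configurable |rho| threshold
(default 0.1; raise it at small n where the null sampling SD of rho
approaches the threshold).

## The synthetic cohort: what it emulates, what it does not

The study data behind this design are not publicly deposited, so every
inferential claim in the test suite is made against simulated cohorts with
known ground truth, generated by `simulateCohort()`:

* **Cohort structure.** 119 controls and 325 cases by default; ages from a
  truncated normal (mean 41, SD 10.8) on 18–75; 65% female; education
  around 14.5 ± 2.7 years; visit count 1 or 3; CAG lengths around 20 in
  controls and 42 in carriers. These follow the demographic table of the
  cohort the pipeline is designed for.
* **Regions.** 34 Desikan–Killiany cortical parcels per hemisphere
  (thickness, mm) plus bilateral caudate and putamen, generated as mm³
  volumes divided by a simulated intracranial volume (males ~8% larger,
  ICV noise SD 1e5 mm³) — so striatal predictors carry realistic
  ratio-measurement noise that cortical ones do not.
* **Covariate effects.** On a latent residual-SD scale, age acts as a
  monotone decreasing mild quadratic, sex adds a small offset, and a small
  age-by-sex interaction is present — exactly the effects the normative
  forest is supposed to absorb.
* **Correlation.** Regional noise has a within-lobe block correlation
  (default rho 0.4), emulating the high inter-regional correlation that
  motivates the forest approach; a diagonal option (`block_rho = 0`)
  exists for oracle tests.
* **Atrophy.** Cases in a configured region set lose
  `atrophy_effect_sd` x residual-SD x severity, where severity is a
  per-case gamma(2, 0.5) factor (mean 1, right-skewed) emulating
  heterogeneous proximity to onset. The default atrophy set has 40 regions
  (both striatal pairs plus 36 cortical parcels), mirroring the screened
  set size the design anticipates.
* **Outcomes.** Five scores (SDMT, letter-number sequencing, HVLT-R
  immediate recall, negative-emotion recognition, timing precision) are
  linear (optionally nonlinear or interacting) functions of the *measured*
  values of the outcome regions — standardized across the cohort, so
  striatal drivers act through their ICV ratios — plus small covariate
  effects and Gaussian noise. Counts are rounded and floored at zero;
  timing precision is floored at a small positive value. Outcome regions
  must be a subset of the atrophy set, since signal that cannot survive
  screening is undiscoverable by a two-stage design.

What the generator does **not** emulate: scanner/site effects, the
CAG-age product structure of real progression scores, longitudinal
dependence, realistic per-region effect-size maps, or missing-data
patterns. A green recovery test therefore establishes that the pipeline's
machinery identifies planted structure under plausible noise — not that
the original study's regional findings would replicate.

## Numerical choices

* **Forest engine.** No random-forest package is available in the target
  environment, and per-tree OOB bookkeeping is the heart of the method, so
  the package ships its own regression CART engine (Rcpp): bootstrap of n
  with replacement per tree, variance-reduction splits at midpoints, leaf
  threshold `nodeSize = 5` (the regression convention), presorted index
  arrays with stable partitioning so no sorting happens inside nodes. The
  engine's permutation importance is verified in the tests against a
  brute-force R reimplementation that re-predicts every OOB case with the
  recorded permutation sequences.
* **Reproducibility.** All engine randomness flows from an explicit seed
  through an internal xorshift64* generator, so fits are bit-reproducible
  and independent of (and invisible to) R's global RNG. Repetition r of a
  repeated analysis uses a seed derived deterministically from the master
  seed and r (kept below 2^31), so results do not depend on execution
  order or worker count. Predictors are canonicalized (name-sorted) before
  fitting, making rankings invariant to the order predictor columns are
  supplied.
* **Wilcoxon conventions.** Exact enumeration (p = P(W >= w_obs)) when
  both samples have at most 10 observations and the pooled data are
  tie-free; otherwise the normal approximation with continuity and midrank
  tie corrections. Degenerate all-identical input returns p = 1 with a
  warning.
* **Ties in rankings** within a repetition get midranks (conserving the
  rank sum); ties in the aggregated mean rank are broken by higher mean
  importance, then variable name, so output order is deterministic.
* **Missingness.** The container tolerates missing covariates or
  outcomes; each analysis stage excludes incomplete subjects for its own
  variables and reports the count. Controls used for normative fitting
  must have age and sex.
* **Extrapolation guard.** Residualizing subjects whose age lies more than
  10 years (configurable) outside the normative training range warns but
  proceeds — a deliberate warning-not-error, since case cohorts routinely
  extend slightly beyond control age ranges.
* **Curve comparability.** The top-k MSE curve applies the protocol mtry
  rule by default. At very small p the rule itself changes per-split
  capacity as k grows (floor(p/3) jumps), which can dominate the curve;
  `buildCurve(mtry = )` pins the candidate count for such diagnostic uses.

## Scale, defaults, and deviations

Protocol-scale settings — 5000 trees per forest, 1000 ranking repetitions,
200 selection runs — are the package defaults (`forestConfig()`,
`buildCurve()`), and `runConfig(scale = "full")` runs them. The test suite
and the smoke pipeline use reduced configurations (hundreds of trees, tens
of repetitions); every reduced run records the deviation in its metadata.
Monte-Carlo acceptance checks in the tests use the stated designs: null
false-discovery control over 200 simulated cohorts, screening sensitivity
at a 0.5 SD mean shift over 50 cohorts, and recovery of 5 planted outcome
regions (within the top 10 of ~40 ranked) over 20 cohorts at 500 trees and
50 repetitions. For the recovery and curve worlds the atrophy effect is
set to 0.8 SD so that the planted drivers reliably survive screening —
those checks exercise the ranking and selection stages conditional on a
screened predictor set of the intended size; screening power itself is
measured separately at 0.5 SD.

## Known limitations

* Only forests are offered for normative adjustment (no spline/polynomial
  alternative), matching the design being implemented.
* No conditional or partial importance variants; correlated predictors
  share importance stochastically, which the duplicate-predictor test
  documents rather than corrects.
* The selection stage implements only the nested top-k minimum-OOB-MSE
  procedure, not the full interpretation/prediction distinction of
  VSURF-style selection.
* ANCOVA group comparisons use OLS with sex as a binary indicator; with a
  single two-level factor and continuous covariates the group test is
  insensitive to sums-of-squares conventions, so none are exposed.

## A worked example

```{r example, eval = FALSE}
library(MorphoCog)

co <- simulateCohort(simulationConfig(seed = 1))
co

mod <- fitNormative(co, nTrees = 200, seed = 2)
res <- residualizeCohort(mod, co)
sc <- screenRegions(res, alpha = 0.05)
preds <- S4Vectors::metadata(sc)$predictor_set
length(preds)

rk <- rankVariables(co, "sdmt", preds,
                    config = forestConfig(nTrees = 500, nRepetitions = 50,
                                          seed = 3))
cur <- buildCurve(co, rk, nRuns = 50, nTrees = 500, seed = 4)
plotSelectionCurve(cur)
reportSelected(co, rk, chosenK(cur))
```

The same sequence, with per-stage CSV/JSON outputs and run metadata, is
available as `runPipeline(runConfig(...))` or from the shell via
`inst/scripts/morphocog-pipeline.R`.
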