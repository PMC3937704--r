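# Synthetic two-group cohorts with known ground truth: a case-control
# morphometry study (by default 119 controls / 325 cases, 34 cortical
# regions per hemisphere plus bilateral caudate and putamen) in which a
# known subset of regions atrophies in cases and a known subset of those
# drives each cognitive outcome.

.dkNames <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal",
  "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
  "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
  "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
  "transversetemporal")

.dkLobe <- c(
  bankssts = "temporal", caudalanteriorcingulate = "cingulate",
  caudalmiddlefrontal = "frontal", cuneus = "occipital",
  entorhinal = "temporal", frontalpole = "frontal", fusiform = "temporal",
  inferiorparietal = "parietal", inferiortemporal = "temporal",
  insula = "cingulate", isthmuscingulate = "cingulate",
  lateraloccipital = "occipital", lateralorbitofrontal = "frontal",
  lingual = "occipital", medialorbitofrontal = "frontal",
  middletemporal = "temporal", paracentral = "frontal",
  parahippocampal = "temporal", parsopercularis = "frontal",
  parsorbitalis = "frontal", parstriangularis = "frontal",
  pericalcarine = "occipital", postcentral = "parietal",
  posteriorcingulate = "cingulate", precentral = "frontal",
  precuneus = "parietal", rostralanteriorcingulate = "cingulate",
  rostralmiddlefrontal = "frontal", superiorfrontal = "frontal",
  superiorparietal = "parietal", superiortemporal = "temporal",
  supramarginal = "parietal", temporalpole = "temporal",
  transversetemporal = "temporal")

# run expr under a fixed seed, restoring the caller's RNG state afterwards
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the cohort structure the pipeline is designed for:
#' 119 controls and 325 cases, 72 regions (34 Desikan-Killiany cortical
#' parcels per hemisphere, then bilateral caudate and putamen as
#' volume-ratio regions), a 40-region atrophy set (both striatal pairs plus
#' 36 cortical parcels) with a mean case shift of 0.5 residual SD scaled by
#' a right-skewed per-case severity factor, and five cognitive outcomes
#' driven by 5 of the atrophied regions plus small covariate effects.
#'
#' @param n_control,n_case group sizes (each >= 10).
#' @param n_regions number of regions; when 72 the Desikan-Killiany naming
#'   and lobe-block correlation structure is used, otherwise generic names
#'   in blocks of 6 (the last 4 regions are striatal whenever
#'   `n_regions >= 8`).
#' @param atrophy_region_indices indices (1-based) of regions atrophied in
#'   cases.
#' @param atrophy_effect_sd mean case-group shift in units of the residual
#'   SD (i.e. of `noise_sd` on the latent scale); per-case shift is this
#'   value times the subject's severity factor.
#' @param outcome_region_indices indices of regions driving the outcomes
#'   (must be a subset of the atrophy set so that the signal can survive
#'   screening); either one vector used for all five outcomes or a named
#'   list per outcome.
#' @param outcome_model functional form linking outcome regions to scores:
#'   `"linear"`, `"nonlinear"` (adds a centered quadratic in the regional
#'   signal) or `"interaction"` (adds a product of the first two outcome
#'   regions).
#' @param noise_sd SD of the region-level residual noise on the latent
#'   scale; also the SD of the outcome noise. 0 gives noiseless morphometry
#'   and outcomes.
#' @param age_range min/max age in years (ages drawn from a truncated
#'   normal, mean 41, SD 10.8).
#' @param seed integer master seed (mandatory for reproducibility).
#' @param block_rho within-block (lobe) correlation of regional noise.
#' @param severity_shape,severity_scale gamma parameters of the per-case
#'   severity factor (defaults shape 2, scale 0.5: mean 1, right-skewed).
#' @param outcome_signal scale of the regional signal in the outcomes.
#' @param outcome_covariate_scale scale of the covariate effects on the
#'   outcomes (0 removes them; used by degenerate-noise oracles).
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_control = 119L, n_case = 325L,
                             n_regions = 72L,
                             atrophy_region_indices = NULL,
                             atrophy_effect_sd = 0.5,
                             outcome_region_indices = NULL,
                             outcome_model = c("linear", "nonlinear",
                                               "interaction"),
                             noise_sd = 1, age_range = c(18, 75), seed = 1L,
                             block_rho = 0.4, severity_shape = 2,
                             severity_scale = 0.5, outcome_signal = 1,
                             outcome_covariate_scale = 1) {
  outcome_model <- match.arg(outcome_model)
  if (n_control < 10 || n_case < 10)
    stop("n_control and n_case must both be >= 10")
  if (is.null(atrophy_region_indices)) {
    atrophy_region_indices <-
      if (n_regions == 72L) c(1:18, 35:52, 69:72) else
        seq_len(min(n_regions, max(1L, round(n_regions * 0.55))))
  }
  if (is.null(outcome_region_indices)) {
    pick <- if (n_regions == 72L) c(69L, 71L, 2L, 36L, 8L) else
      utils::head(atrophy_region_indices, 5L)
    outcome_region_indices <- pick
  }
  outList <- if (is.list(outcome_region_indices)) outcome_region_indices
             else stats::setNames(rep(list(outcome_region_indices),
                                      length(.cognitionCols)),
                                  .cognitionCols)
  if (!setequal(names(outList), .cognitionCols))
    names(outList) <- .cognitionCols
  allOut <- unique(unlist(outList))
  if (!all(atrophy_region_indices %in% seq_len(n_regions)))
    stop("atrophy_region_indices out of range")
  if (length(allOut) && !length(atrophy_region_indices))
    stop("outcome regions require a nonempty atrophy set")
  if (!all(allOut %in% atrophy_region_indices))
    stop("outcome_region_indices must be a subset of atrophy_region_indices")
  structure(list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    n_regions = as.integer(n_regions),
    atrophy_region_indices = sort(unique(as.integer(atrophy_region_indices))),
    atrophy_effect_sd = atrophy_effect_sd,
    outcome_region_indices = lapply(outList, as.integer),
    outcome_model = outcome_model, noise_sd = noise_sd,
    age_range = as.numeric(age_range), seed = as.integer(seed),
    block_rho = block_rho, severity_shape = severity_shape,
    severity_scale = severity_scale, outcome_signal = outcome_signal,
    outcome_covariate_scale = outcome_covariate_scale),
    class = "SimulationConfig")
}

#' Per-case disease-severity factors
#'
#' Right-skewed positive multipliers with mean 1 (gamma, default shape 2 and
#' scale 0.5) emulating the wide variation in baseline progression across
#' prodromal cases, so that `atrophy_effect_sd` is the *mean* group shift.
#'
#' @param nCase number of cases.
#' @param seed integer seed.
#' @param shape,scale gamma parameters; `shape * scale` should be 1.
#' @return vector of `nCase` positive reals.
#' @export
severityProfile <- function(nCase, seed, shape = 2, scale = 0.5) {
  stopifnot(nCase >= 1)
  withSeed(seed, stats::rgamma(nCase, shape = shape, scale = scale))
}

.regionLayout <- function(nRegions) {
  if (nRegions == 72L) {
    names <- c(paste0("lh_", .dkNames), paste0("rh_", .dkNames),
               "lh_caudate", "rh_caudate", "lh_putamen", "rh_putamen")
    kind <- c(rep("thickness", 68), rep("volume_ratio", 4))
    block <- c(paste0("lh_", .dkLobe[.dkNames]),
               paste0("rh_", .dkLobe[.dkNames]), rep("striatum", 4))
  } else {
    names <- sprintf("region_%03d", seq_len(nRegions))
    nStri <- if (nRegions >= 8) 4L else 0L
    kind <- c(rep("thickness", nRegions - nStri),
              rep("volume_ratio", nStri))
    if (nStri) names[(nRegions - 3):nRegions] <-
        c("lh_caudate", "rh_caudate", "lh_putamen", "rh_putamen")
    block <- paste0("b", ceiling(seq_len(nRegions) / 6))
    if (nStri) block[(nRegions - 3):nRegions] <- "striatum"
  }
  list(names = names, kind = kind, block = block)
}

# monotone-decreasing, mildly nonlinear normative age effect (latent SD
# units); s is age centered at 45 and scaled by 15
.fAge <- function(age) {
  s <- (age - 45) / 15
  -0.4 * s - 0.1 * s^2
}

#' Simulate a two-group morphometry + cognition cohort
#'
#' Generates per-subject demographics, regional morphometry and five
#' cognitive scores under a known generative model. On a latent (residual
#' SD) scale each region is `f(age) + g(sex) + h(age, sex) - atrophy +
#' correlated noise`, where `f` is monotone decreasing and mildly quadratic,
#' `g` a small sex offset, `h` a small age-by-sex interaction, and the
#' atrophy term applies only to cases in the configured atrophy set, scaled
#' by a right-skewed per-case severity factor ([severityProfile()]).
#' Cortical latents map to thickness in mm (floored at 0.5 mm, floor events
#' counted in the ground truth); striatal latents map to mm^3 volumes that
#' are divided by a simulated intracranial volume. Outcomes are a
#' linear/nonlinear/interacting function of the outcome regions as
#' measured (standardized across the cohort, so striatal drivers act
#' through their ICV-normalized ratios), plus small covariate effects and
#' Gaussian noise, mapped to each test's scale (counts rounded and clipped
#' at 0).
#'
#' @param config a [simulationConfig()].
#' @return an [HDCohort-class] with `metadata()$ground_truth` recording the
#'   atrophy set, per-outcome driver regions, generative coefficients and
#'   the floored-value count.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(cfg) {
  n <- cfg$n_control + cfg$n_case
  R <- cfg$n_regions
  ids <- sprintf("S%04d", seq_len(n))
  group <- factor(rep(c("control", "case"), c(cfg$n_control, cfg$n_case)),
                  levels = c("control", "case"))
  isCase <- group == "case"

  # demographics: balanced across groups by construction
  age <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      a <- stats::rnorm(1, 41, 10.8)
      if (a >= cfg$age_range[1] && a <= cfg$age_range[2]) break
    }
    age[i] <- a
  }
  sex <- factor(ifelse(stats::runif(n) < 0.65, "female", "male"),
                levels = c("female", "male"))
  male <- as.numeric(sex == "male")
  edu <- pmax(0, stats::rnorm(n, 14.5, 2.7))
  visits <- sample(c(1L, 3L), n, replace = TRUE)
  cag <- integer(n)
  cag[!isCase] <- pmin(35L, pmax(15L, round(stats::rnorm(sum(!isCase),
                                                         20.2, 3.3))))
  cag[isCase] <- pmin(50L, pmax(38L, round(stats::rnorm(sum(isCase),
                                                        42.3, 2.3))))
  motor <- pmax(0, stats::rnorm(n, ifelse(isCase, 5.2, 2.7),
                                ifelse(isCase, 5.5, 3.4)))

  layout <- .regionLayout(R)
  blocks <- factor(layout$block)
  nb <- nlevels(blocks)

  severity <- severityProfile(cfg$n_case, seed = deriveSeed(cfg$seed, 1L),
                              shape = cfg$severity_shape,
                              scale = cfg$severity_scale)
  shift <- numeric(n)
  shift[isCase] <- cfg$atrophy_effect_sd * cfg$noise_sd * severity

  s <- (age - 45) / 15
  fixed <- .fAge(age) + 0.25 * male + 0.1 * male * s  # n-vector

  uBlock <- matrix(stats::rnorm(n * nb), n, nb)
  eps <- matrix(stats::rnorm(n * R), n, R)
  noise <- cfg$noise_sd * (sqrt(cfg$block_rho) *
                             uBlock[, as.integer(blocks), drop = FALSE] +
                             sqrt(1 - cfg$block_rho) * eps)
  z <- matrix(fixed, n, R) + noise
  inAtrophy <- seq_len(R) %in% cfg$atrophy_region_indices
  z[, inAtrophy] <- z[, inAtrophy] - shift  # shift only nonzero for cases

  # map latents to measurement units
  isThick <- layout$kind == "thickness"
  baseThick <- 2.2 + 0.8 * ((which(isThick) - 1) %% 9) / 8
  m <- matrix(0, n, R, dimnames = list(ids, layout$names))
  nFloored <- 0L
  if (any(isThick)) {
    th <- sweep(z[, isThick, drop = FALSE] * 0.15, 2, baseThick, "+")
    nFloored <- sum(th < 0.5)
    th[th < 0.5] <- 0.5
    m[, isThick] <- th
  }
  icv <- 1.45e6 * (1 + 0.08 * male) + stats::rnorm(n, 0, 1e5)
  icv <- pmax(icv, 1e6)
  rawVolumes <- NULL
  if (any(!isThick)) {
    striNames <- layout$names[!isThick]
    baseVol <- ifelse(grepl("caudate", striNames), 3800, 4700)
    vol <- sweep(1 + 0.07 * z[, !isThick, drop = FALSE], 2, baseVol, "*")
    vol <- pmax(vol, 1)
    m[, !isThick] <- vol / icv
    rawVolumes <- vol
    dimnames(rawVolumes) <- list(ids, paste0(striNames, "_vol_mm3"))
  }

  # cognitive outcomes driven by the outcome regions as *measured* (the
  # same scale the pipeline analyzes, including the ICV-ratio measurement
  # noise of striatal regions), standardized across the cohort
  zMeas <- m
  for (r in seq_len(R)) {
    sdr <- stats::sd(m[, r])
    zMeas[, r] <- if (sdr > 0) (m[, r] - mean(m[, r])) / sdr else 0
  }
  outMeans <- c(sdmt = 50, letter_number = 11, hvlt_immediate = 25,
                negative_emotions = 18, timing_precision = 0.035)
  outSds <- c(sdmt = 10, letter_number = 3, hvlt_immediate = 5,
              negative_emotions = 4, timing_precision = 0.012)
  covEff <- cfg$outcome_covariate_scale *
    (-0.2 * s + 0.1 * (edu - 14) / 3 + 0.05 * (visits - 2))
  cog <- data.frame(row.names = ids)
  coefLog <- list()
  for (o in .cognitionCols) {
    idx <- cfg$outcome_region_indices[[o]]
    if (length(idx)) {
      zo <- zMeas[, idx, drop = FALSE]
      sig <- rowSums(zo) / sqrt(length(idx))
      u <- switch(cfg$outcome_model,
        linear = sig,
        nonlinear = sig + 0.4 * (sig^2 - mean(sig^2)),
        interaction = if (length(idx) >= 2)
          sig + 0.5 * zo[, 1] * zo[, 2] else sig)
    } else u <- 0
    lat <- cfg$outcome_signal * u + covEff +
      cfg$noise_sd * stats::rnorm(n)
    raw <- outMeans[[o]] + outSds[[o]] * lat / 2
    if (o == "timing_precision") {
      cog[[o]] <- pmax(raw, 0.002)
    } else {
      cog[[o]] <- pmax(0, round(raw))
    }
    coefLog[[o]] <- list(regions = layout$names[idx],
                         weight = cfg$outcome_signal / sqrt(max(1,
                                                        length(idx))),
                         scale = outSds[[o]] / 2)
  }

  subjects <- data.frame(
    subject_id = ids, group = group, age = age, sex = sex,
    education_years = edu, visit_count = visits, cag_repeats = cag,
    motor_score = motor, icv_mm3 = icv, row.names = ids)

  gt <- list(
    atrophy_region_indices = cfg$atrophy_region_indices,
    atrophy_regions = layout$names[cfg$atrophy_region_indices],
    outcome_regions = lapply(cfg$outcome_region_indices,
                             function(i) layout$names[i]),
    coefficients = coefLog,
    severity = severity,
    config = unclass(cfg),
    n_floored = nFloored)

  HDCohort(m, subjects, kind = layout$kind, cognition = cog,
           metadata = list(ground_truth = gt, raw_volumes = rawVolumes))
}
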