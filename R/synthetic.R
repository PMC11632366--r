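## Synthetic longitudinal cohort generator with known ground truth: the
## stand-in for real amyloid-positive tau PET cohorts.

.defaultSyntheticRegions <- function(tiny = FALSE) {
  if (tiny) {
    ## six midline units for brute-force oracle tests; sig1 carries an
    ## early Braak stage so the denominator prior binds, ref1 is a
    ## reference candidate so the numerator prior binds
    df <- data.frame(
      region_id = c("sig1", "sig2", "stab1", "stab2", "ref1", "ref2"),
      hemisphere = "midline", bilateral_pair_id = NA_character_,
      braak_stage = c(3L, NA, NA, NA, NA, NA),
      reference_candidate = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
      composites = c("meta_temporal", "meta_temporal", "rest", "rest",
                     "whole_cerebellum", "brainstem"),
      role = c("signal", "signal", "stable", "stable", "reference",
               "reference"),
      slope_CU = c(0.02, 0.02, 0, 0, 0, 0),
      slope_CI = c(0.05, 0.05, 0, 0, 0, 0),
      base_log = c(0.25, 0.25, 0.10, 0.10, 0, 0),
      volume = c(2000, 2500, 8000, 9000, 120000, 30000),
      stringsAsFactors = FALSE)
    return(df)
  }
  pair <- function(id, braak, refc, comp, role, sCU, sCI, base, vol) {
    data.frame(
      region_id = paste0(id, c("_L", "_R")),
      hemisphere = c("left", "right"), bilateral_pair_id = id,
      braak_stage = braak, reference_candidate = refc, composites = comp,
      role = role, slope_CU = sCU, slope_CI = sCI, base_log = base,
      volume = vol * c(1, 1.04), stringsAsFactors = FALSE)
  }
  mid <- function(id, refc, comp, base, vol) {
    data.frame(region_id = id, hemisphere = "midline",
               bilateral_pair_id = NA_character_,
               braak_stage = NA_integer_, reference_candidate = refc,
               composites = comp, role = "reference", slope_CU = 0,
               slope_CI = 0, base_log = base, volume = vol,
               stringsAsFactors = FALSE)
  }
  rbind(
    pair("entorhinal", 1L, FALSE, "meta_temporal;mesial_temporal",
         "signal", 0.02, 0.05, 0.30, 1800),
    pair("amygdala", 3L, FALSE, "meta_temporal;mesial_temporal",
         "signal", 0.02, 0.05, 0.28, 1600),
    pair("fusiform", 3L, FALSE, "meta_temporal;temporoparietal",
         "signal", 0.015, 0.05, 0.25, 9000),
    pair("inferior_temporal", 4L, FALSE, "meta_temporal;temporoparietal",
         "signal", 0.015, 0.055, 0.25, 11000),
    pair("middle_temporal", 4L, FALSE, "meta_temporal;temporoparietal",
         "signal", 0.01, 0.05, 0.22, 12000),
    pair("precentral", 6L, FALSE, "rest", "stable", 0, 0, 0.10, 13000),
    pair("postcentral", 6L, FALSE, "rest", "stable", 0, 0, 0.10, 10000),
    mid("whole_cerebellum", TRUE, "whole_cerebellum", 0.00, 120000),
    mid("inferior_cerebellum_gm", TRUE, "inferior_cerebellum_gm", 0.00,
        30000),
    mid("cerebellum_cortex", TRUE, "cerebellum_cortex", 0.00, 100000),
    mid("brainstem", TRUE, "brainstem;composite_reference", 0.05, 28000),
    mid("eroded_subcortical_wm", TRUE,
        "eroded_subcortical_wm;composite_reference", 0.15, 50000))
}

## add composite_reference membership for whole cerebellum in the non-tiny
## default (paper-style composite reference = ewm + whole cerebellum +
## brainstem)
.finishRegions <- function(df) {
  i <- df$region_id == "whole_cerebellum"
  if (any(i))
    df$composites[i] <- "whole_cerebellum;composite_reference"
  df
}

#' Construct a SyntheticConfig
#'
#' Defaults emulate an amyloid-positive longitudinal tau PET cohort:
#' subjects with 2--4 visits, inter-visit intervals mostly 0.7--1.5 years,
#' group-dependent accumulation slopes on the signal regions (log
#' scale/year), correlated subject-level random intercepts and slopes, a
#' per-scan global multiplicative scale factor shared by all regions
#' (SD 0.05) and independent regional noise.
#'
#' @param nCU,nCI subject counts.
#' @param visitProbs probabilities of 2, 3, 4 visits per subject.
#' @param intervalMix probabilities of interval bins <=1.5, 1.5--2.5,
#'   2.5--3.5, >3.5 years.
#' @param regions region-role table; see [SyntheticConfig-class].
#' @param sigmaB0,sigmaB1,rho,sigmaNoise,sigmaScale,volumeJitter variance
#'   components.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nCU = 76L, nCI = 122L,
                            visitProbs = c(0.5, 0.3, 0.2),
                            intervalMix = c(0.61, 0.22, 0.06, 0.11),
                            regions = .finishRegions(
                              .defaultSyntheticRegions()),
                            sigmaB0 = 0.10, sigmaB1 = 0.02, rho = 0.5,
                            sigmaNoise = 0.02, sigmaScale = 0.05,
                            volumeJitter = 0.05) {
  new("SyntheticConfig", nCU = as.integer(nCU), nCI = as.integer(nCI),
      visitProbs = visitProbs, intervalMix = intervalMix,
      regions = regions, sigmaB0 = sigmaB0, sigmaB1 = sigmaB1, rho = rho,
      sigmaNoise = sigmaNoise, sigmaScale = sigmaScale,
      volumeJitter = volumeJitter)
}

#' Cohort presets
#'
#' \code{experiment1_like}: 76 CU + 122 CI subjects, CU-style inter-visit
#' interval mix (0.61/0.22/0.06/0.11), for the 54-month preclinical
#' design. \code{experiment2_like}: the same cohort sizes with the
#' CI-style interval mix (0.72/0.17/0.06/0.05), for the 18-month clinical
#' design. \code{tiny_oracle}: a 6-region midline-only cohort small enough
#' for brute-force search. Presets are pure: no random numbers are drawn
#' until [generateCohort()].
#'
#' @param name preset name.
#' @return A [SyntheticConfig-class].
#' @export
cohortPreset <- function(name = c("experiment1_like", "experiment2_like",
                                  "tiny_oracle")) {
  name <- match.arg(name)
  switch(name,
         experiment1_like = syntheticConfig(),
         experiment2_like = syntheticConfig(
           intervalMix = c(0.72, 0.17, 0.06, 0.05)),
         tiny_oracle = syntheticConfig(
           nCU = 14L, nCI = 22L,
           regions = .defaultSyntheticRegions(tiny = TRUE)))
}

#' Region metadata implied by a synthetic configuration
#'
#' @param config a [SyntheticConfig-class].
#' @return A [RegionMetadata-class] matching the generated datasets.
#' @export
syntheticMetadata <- function(config) {
  RegionMetadata(config@regions[c("region_id", "hemisphere",
                                  "bilateral_pair_id", "braak_stage",
                                  "reference_candidate", "composites")])
}

#' Generate a synthetic longitudinal cohort
#'
#' For subject j of group g observed at time t (first visit at 0,
#' subsequent visits at cumulative sampled intervals), region r:
#' \deqn{\log suv = m_r + a_j + (s_{r,g} + c_j) t + \log g_j(t) + e_{jrt}}
#' with \code{(a_j, c_j)} bivariate normal, the global scan factor
#' \code{g_j(t)} lognormal and shared by all regions of the scan, and
#' independent N(0, sigmaNoise^2) regional noise. Stable and reference
#' regions have zero slope. Volumes are region constants with lognormal
#' per-subject jitter, held fixed across a subject's visits.
#'
#' @param config a [SyntheticConfig-class].
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return list: \code{dataset} (a [RegionalDataset-class]), \code{truth}
#'   (a [SyntheticTruth-class]), \code{metadata} (a
#'   [RegionMetadata-class]).
#' @export
generateCohort <- function(config, seed = 1L) {
  validObject(config)
  set.seed(seed)
  rg <- config@regions
  R <- nrow(rg)
  n <- config@nCU + config@nCI
  groups <- c(rep("CU", config@nCU), rep("CI", config@nCI))
  ids <- sprintf("sub%03d", seq_len(n))

  bins <- rbind(c(0.7, 1.5), c(1.5, 2.5), c(2.5, 3.5), c(3.5, 5.0))
  b <- MASS::mvrnorm(n, c(0, 0), matrix(c(
    config@sigmaB0^2, rep(config@rho * config@sigmaB0 * config@sigmaB1, 2),
    config@sigmaB1^2), 2, 2))
  if (config@sigmaB0 == 0 && config@sigmaB1 == 0) b <- matrix(0, n, 2)

  suv_cols <- list(); vol_cols <- list()
  subj_col <- character(); grp_col <- character(); time_col <- numeric()
  scale_log <- list()
  for (jj in seq_len(n)) {
    nvis <- sample(2:4, 1, prob = config@visitProbs)
    gap_bin <- sample(1:4, nvis - 1, replace = TRUE,
                      prob = config@intervalMix)
    gaps <- runif(nvis - 1, bins[gap_bin, 1], bins[gap_bin, 2])
    times <- c(0, cumsum(gaps))
    vols <- rg$volume * exp(rnorm(R, 0, config@volumeJitter))
    slope <- if (groups[jj] == "CI") rg$slope_CI else rg$slope_CU
    for (t in times) {
      lg <- rnorm(1, 0, config@sigmaScale)
      e <- rnorm(R, 0, config@sigmaNoise)
      lsuv <- rg$base_log + b[jj, 1] + (slope + b[jj, 2]) * t + lg + e
      suv_cols[[length(suv_cols) + 1L]] <- exp(lsuv)
      vol_cols[[length(vol_cols) + 1L]] <- vols
      subj_col <- c(subj_col, ids[jj])
      grp_col <- c(grp_col, groups[jj])
      time_col <- c(time_col, t)
      scale_log[[length(scale_log) + 1L]] <-
        data.frame(subject_id = ids[jj], scan_time = t, log_g = lg,
                   stringsAsFactors = FALSE)
    }
  }
  suv <- do.call(cbind, suv_cols)
  vol <- do.call(cbind, vol_cols)
  rownames(suv) <- rownames(vol) <- rg$region_id
  dataset <- RegionalDataset(suv = suv, volume = vol, subjectId = subj_col,
                             group = grp_col, scanTime = time_col)
  truth <- new("SyntheticTruth",
               randomEffects = data.frame(subject_id = ids, group = groups,
                                          b0 = b[, 1], b1 = b[, 2],
                                          stringsAsFactors = FALSE),
               scanScale = do.call(rbind, scale_log),
               regionRoles = rg[c("region_id", "role", "slope_CU",
                                  "slope_CI")])
  list(dataset = dataset, truth = truth,
       metadata = syntheticMetadata(config))
}

#' Simulate directly from the longitudinal model
#'
#' Generates a centred modelling frame straight from the
#' random-intercept/slope model (bypassing regions and ratios): used for
#' parameter-recovery, power and bootstrap-coverage studies where the
#' generating model must be exactly the fitted one.
#'
#' @param beta numeric(4): intercept, time slope, dx offset, time-dx
#'   interaction.
#' @param sigmaB0,sigmaB1,rho,sigmaEps variance components.
#' @param nPerGroup subjects per diagnostic group (CU, CI).
#' @param visitTimes visit schedule (years) given to every subject before
#'   within-subject centring.
#' @return data.frame frame as from [centerTime()], with attribute
#'   \code{truth} carrying the generating parameters.
#' @export
simulateLongitudinal <- function(beta = c(0.3, 0.02, 0.01, 0.03),
                                 sigmaB0 = 0.1, sigmaB1 = 0.02, rho = 0.5,
                                 sigmaEps = 0.02, nPerGroup = c(50, 50),
                                 visitTimes = c(0, 1.5, 3)) {
  n <- sum(nPerGroup)
  dx <- rep(c(0L, 1L), nPerGroup)
  Sigma <- matrix(c(sigmaB0^2, rep(rho * sigmaB0 * sigmaB1, 2),
                    sigmaB1^2), 2, 2)
  b <- if (sigmaB0 == 0 && sigmaB1 == 0) matrix(0, n, 2) else
    MASS::mvrnorm(n, c(0, 0), Sigma)
  tc <- visitTimes - mean(visitTimes)
  k <- length(tc)
  subject <- rep(sprintf("s%04d", seq_len(n)), each = k)
  time <- rep(tc, n)
  DX <- rep(dx, each = k)
  y <- beta[1] + beta[2] * time + beta[3] * DX + beta[4] * time * DX +
    rep(b[, 1], each = k) + rep(b[, 2], each = k) * time +
    rnorm(n * k, 0, sigmaEps)
  out <- data.frame(subject = subject, time = time, dx = DX, y = y,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(beta = beta, sigmaB0 = sigmaB0,
                             sigmaB1 = sigmaB1, rho = rho,
                             sigmaEps = sigmaEps)
  out
}
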