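#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats qnorm qchisq pchisq rnorm runif sd var logLik anova
#'   coef dnorm optimize uniroot complete.cases setNames predict quantile
#'   resid qt pt
#' @importFrom utils read.csv write.csv head
NULL

## ---------------------------------------------------------------------------
## RegionalDataset: region x scan SUV and volume matrices
## ---------------------------------------------------------------------------

#' RegionalDataset: longitudinal regional PET observations
#'
#' A \linkS4class{SummarizedExperiment} holding one row per region and one
#' column per scan (a subject/visit pair). Two assays are required, both
#' strictly positive: \code{"suv"} (regional standardized uptake values,
#' unitless) and \code{"volume"} (regional volumes, mm^3). Column metadata
#' carries \code{subject_id}, \code{group} (factor with levels \code{CU},
#' \code{CI}) and \code{scan_time} (years; either age or time from first
#' scan -- all modelling centres time within subject, so the origin is
#' irrelevant).
#'
#' Validity enforces the modelling contracts: every scan carries the full
#' region set (guaranteed by the matrix layout), each subject has at least
#' two distinct scan times, the group label is constant within subject, and
#' both assays are finite and positive.
#'
#' @seealso [loadRegionalTable()], [makeBilateral()], [computeCVR()]
#' @export
setClass("RegionalDataset", contains = "SummarizedExperiment")

setValidity("RegionalDataset", function(object) {
  msg <- character()
  if (!all(c("suv", "volume") %in% SummarizedExperiment::assayNames(object)))
    return("assays 'suv' and 'volume' are required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "group", "scan_time")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  if (!all(levels(factor(cd$group)) %in% c("CU", "CI")))
    msg <- c(msg, "group must only take values 'CU' and 'CI'")
  s <- SummarizedExperiment::assay(object, "suv")
  v <- SummarizedExperiment::assay(object, "volume")
  if (anyNA(s) || anyNA(v) || any(!is.finite(s)) || any(!is.finite(v)))
    msg <- c(msg, "suv and volume must be finite and non-missing")
  else if (any(s <= 0) || any(v <= 0))
    msg <- c(msg, "suv and volume must be strictly positive")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "region ids (rownames) must be present and unique")
  if (ncol(object) > 0) {
    key <- paste(cd$subject_id, cd$scan_time)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (subject_id, scan_time) scans")
    nvis <- vapply(split(cd$scan_time, cd$subject_id),
                   function(t) length(unique(t)), integer(1))
    if (any(nvis < 2))
      msg <- c(msg, paste("subjects with fewer than 2 distinct scan times:",
                          paste(names(nvis)[nvis < 2], collapse = ", ")))
    ngrp <- vapply(split(as.character(cd$group), cd$subject_id),
                   function(g) length(unique(g)), integer(1))
    if (any(ngrp > 1))
      msg <- c(msg, paste("group label not constant within subject:",
                          paste(names(ngrp)[ngrp > 1], collapse = ", ")))
  } else msg <- c(msg, "dataset has no scans")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionalDataset
#'
#' @param suv,volume numeric matrices, regions in rows, scans in columns,
#'   identical dimnames.
#' @param subjectId character vector, one entry per scan column.
#' @param group character/factor vector of \code{"CU"}/\code{"CI"} labels.
#' @param scanTime numeric vector of scan times in years.
#' @return A validated [RegionalDataset-class] object.
#' @export
RegionalDataset <- function(suv, volume, subjectId, group, scanTime) {
  stopifnot(is.matrix(suv), is.matrix(volume),
            identical(dim(suv), dim(volume)))
  group <- factor(as.character(group), levels = c("CU", "CI"))
  cd <- S4Vectors::DataFrame(subject_id = as.character(subjectId),
                             group = group,
                             scan_time = as.numeric(scanTime))
  colnames(suv) <- colnames(volume) <-
    paste(cd$subject_id, format(cd$scan_time, trim = TRUE), sep = "@")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(suv = suv, volume = volume), colData = cd)
  new("RegionalDataset", se)
}

## ---------------------------------------------------------------------------
## RegionMetadata
## ---------------------------------------------------------------------------

#' RegionMetadata: atlas-level region annotation
#'
#' One row per region: hemisphere (\code{left}/\code{right}/\code{midline}),
#' an optional bilateral pair label shared by exactly one left and one right
#' region, the Braak stage at which tau pathology reaches the region (1--6
#' or \code{NA}), a flag marking conventional SUVR reference regions
#' (excluded from discovered numerators), and the named-composite labels the
#' region belongs to. Region ids are case-sensitive and never parsed;
#' hemisphere information comes only from this table.
#'
#' @slot table a \code{data.frame} with columns \code{region_id},
#'   \code{hemisphere}, \code{bilateral_pair_id}, \code{braak_stage},
#'   \code{reference_candidate} and \code{composites} (a list column of
#'   character vectors).
#' @seealso [loadRegionMetadata()], [compositeMembers()], [searchUnits()]
#' @export
setClass("RegionMetadata", representation(table = "data.frame"))

setValidity("RegionMetadata", function(object) {
  tb <- object@table
  need <- c("region_id", "hemisphere", "bilateral_pair_id", "braak_stage",
            "reference_candidate", "composites")
  if (!all(need %in% colnames(tb)))
    return(paste("metadata table must contain:", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(tb$region_id))
    msg <- c(msg, paste("duplicate region_id:",
                        paste(unique(tb$region_id[duplicated(tb$region_id)]),
                              collapse = ", ")))
  if (!all(tb$hemisphere %in% c("left", "right", "midline")))
    msg <- c(msg, "hemisphere must be left/right/midline")
  if (!all(is.na(tb$braak_stage) | tb$braak_stage %in% 1:6))
    msg <- c(msg, "braak_stage must be 1..6 or NA")
  if (any(tb$hemisphere == "midline" & !is.na(tb$bilateral_pair_id)))
    msg <- c(msg, "midline regions must have no bilateral pair")
  pid <- tb$bilateral_pair_id[!is.na(tb$bilateral_pair_id)]
  for (p in unique(pid)) {
    rows <- tb[!is.na(tb$bilateral_pair_id) & tb$bilateral_pair_id == p, ]
    if (nrow(rows) != 2 || !setequal(rows$hemisphere, c("left", "right")))
      msg <- c(msg, paste0("asymmetric bilateral pair '", p, "' (regions: ",
                           paste(rows$region_id, collapse = ", "), ")"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct RegionMetadata from a data.frame
#'
#' @param table data.frame with columns \code{region_id}, \code{hemisphere},
#'   \code{bilateral_pair_id}, \code{braak_stage}, \code{reference_candidate},
#'   \code{composites}. \code{composites} may be a \code{";"}-separated
#'   character column or a list of character vectors; \code{"none"}, \code{""}
#'   and \code{NA} mean no membership. \code{bilateral_pair_id} and
#'   \code{braak_stage} accept \code{"none"} for absent.
#' @return A validated [RegionMetadata-class] object.
#' @export
RegionMetadata <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  none2na <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "none", "NA")] <- NA_character_
    x
  }
  table$region_id <- as.character(table$region_id)
  table$hemisphere <- as.character(table$hemisphere)
  table$bilateral_pair_id <- none2na(table$bilateral_pair_id)
  table$braak_stage <- suppressWarnings(as.integer(none2na(table$braak_stage)))
  table$reference_candidate <- as.logical(table$reference_candidate)
  if (!is.list(table$composites))
    table$composites <- lapply(strsplit(none2na(table$composites), ";"),
                               function(x) x[!is.na(x) & nzchar(x)])
  if (anyDuplicated(table$region_id))
    stop("duplicate region_id: ",
         paste(unique(table$region_id[duplicated(table$region_id)]),
               collapse = ", "))
  rownames(table) <- table$region_id
  new("RegionMetadata", table = table)
}

## ---------------------------------------------------------------------------
## Search encoding and ratio specification
## ---------------------------------------------------------------------------

#' Genome: the 0/1/2 search encoding
#'
#' An integer assignment over searchable units (regions in lateral mode;
#' bilateral pair labels plus midline regions in bilateral mode): 0 places a
#' unit in the numerator, 2 in the denominator, 1 excludes it. Units listed
#' in \code{frozen} are pinned to a value (restricted-search mode) and are
#' never altered by the variation operators or by [repairGenome()].
#'
#' Structural validity (values in \{0,1,2\}, frozen consistency) is checked
#' here; the search constraints (non-empty sides, no Braak 1--3 unit in the
#' denominator, no reference-candidate unit in the numerator) depend on
#' metadata and are checked by [validGenome()] / enforced by [repairGenome()].
#'
#' @slot assignment named integer vector over units, values in \{0,1,2\}.
#' @slot frozen named integer vector (possibly empty) of pinned values.
#' @export
setClass("Genome",
         representation(assignment = "integer", frozen = "integer"))

setValidity("Genome", function(object) {
  a <- object@assignment
  msg <- character()
  if (is.null(names(a)) || anyDuplicated(names(a)))
    msg <- c(msg, "assignment must be named by unique unit ids")
  if (!all(a %in% 0:2)) msg <- c(msg, "assignment values must be in {0,1,2}")
  f <- object@frozen
  if (length(f)) {
    if (is.null(names(f)) || !all(names(f) %in% names(a)))
      msg <- c(msg, "frozen units must name assignment units")
    if (!all(f %in% 0:2)) msg <- c(msg, "frozen values must be in {0,1,2}")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Genome-class
#' @param assignment named integer (or numeric) vector over units.
#' @param frozen named integer vector of pinned unit values.
#' @return A [Genome-class] object.
#' @export
Genome <- function(assignment, frozen = integer(0)) {
  a <- as.integer(assignment)
  names(a) <- names(assignment)
  f <- as.integer(frozen)
  names(f) <- names(frozen)
  new("Genome", assignment = a, frozen = f)
}

#' RatioSpec: a decoded numerator/denominator region-set pair
#'
#' @slot numerator,denominator character vectors of region ids; non-empty
#'   and disjoint.
#' @export
setClass("RatioSpec",
         representation(numerator = "character", denominator = "character"))

setValidity("RatioSpec", function(object) {
  msg <- character()
  if (!length(object@numerator)) msg <- c(msg, "empty numerator")
  if (!length(object@denominator)) msg <- c(msg, "empty denominator")
  if (length(intersect(object@numerator, object@denominator)))
    msg <- c(msg, "numerator and denominator must be disjoint")
  if (anyDuplicated(object@numerator) || anyDuplicated(object@denominator))
    msg <- c(msg, "duplicated region ids within a side")
  if (length(msg)) msg else TRUE
})

#' @rdname RatioSpec-class
#' @param numerator,denominator character vectors of region ids.
#' @return A [RatioSpec-class] object.
#' @export
RatioSpec <- function(numerator, denominator)
  new("RatioSpec", numerator = as.character(numerator),
      denominator = as.character(denominator))

#' CompositeConfig: how composite signals are formed
#'
#' @slot method \code{"mean_suv"} (unweighted mean over units) or
#'   \code{"volume_weighted"} (volume-weighted mean).
#' @slot laterality \code{"bilateral"} (left/right pairs collapse to one
#'   volume-weighted unit) or \code{"lateral"} (hemispheres independent).
#' @export
setClass("CompositeConfig",
         representation(method = "character", laterality = "character"))

setValidity("CompositeConfig", function(object) {
  msg <- character()
  if (!object@method %in% c("mean_suv", "volume_weighted"))
    msg <- c(msg, "method must be 'mean_suv' or 'volume_weighted'")
  if (!object@laterality %in% c("bilateral", "lateral"))
    msg <- c(msg, "laterality must be 'bilateral' or 'lateral'")
  if (length(msg)) msg else TRUE
})

#' @rdname CompositeConfig-class
#' @param method composition method.
#' @param laterality hemisphere handling.
#' @return A [CompositeConfig-class] object.
#' @export
CompositeConfig <- function(method = c("mean_suv", "volume_weighted"),
                            laterality = c("bilateral", "lateral")) {
  new("CompositeConfig", method = match.arg(method),
      laterality = match.arg(laterality))
}

## ---------------------------------------------------------------------------
## Model fit and trial evaluation containers
## ---------------------------------------------------------------------------

#' LMMFit: fitted random-intercept/slope model on the log biomarker
#'
#' Captures the ingredients of the three trial metrics: fixed effects
#' (intercept, time slope, diagnosis offset, time-by-diagnosis interaction)
#' with standard errors; the unstructured random-effect covariance
#' (intercept SD, slope SD, correlation); the residual SD on the log scale;
#' conditional residuals; and the (restricted) log-likelihood.
#'
#' @slot beta,se named numeric(4): \code{intercept}, \code{time}, \code{dx},
#'   \code{time_dx}.
#' @slot sigmaB0,sigmaB1 random intercept / slope SDs (log scale, per year
#'   for the slope).
#' @slot rho random intercept-slope correlation.
#' @slot sigmaEps residual SD (log scale).
#' @slot residuals conditional residuals, one per observation.
#' @slot logLik maximised (restricted) log-likelihood.
#' @slot REML logical; criterion used.
#' @slot converged,singular fit-status flags (a singular fit, slope variance
#'   on the zero boundary, is valid-with-warning).
#' @slot nObs,nSubjects sizes.
#' @slot model the underlying \code{lme4} fit (or \code{NULL}); kept for
#'   fast bootstrap refits.
#' @export
setClass("LMMFit", representation(
  beta = "numeric", se = "numeric", sigmaB0 = "numeric", sigmaB1 = "numeric",
  rho = "numeric", sigmaEps = "numeric", residuals = "numeric",
  logLik = "numeric", REML = "logical", converged = "logical",
  singular = "logical", nObs = "integer", nSubjects = "integer",
  model = "ANY"))

#' TrialDesign: parameters of the hypothetical slope-reduction trial
#'
#' @slot group trial population, \code{"CU"} or \code{"CI"}.
#' @slot visitTimes trial visit schedule in years (default two visits,
#'   baseline and end of follow-up).
#' @slot power target power (default 0.80).
#' @slot alpha two-sided type-I error (default 0.05).
#' @slot pctChange detectable effect as a fraction of the group mean slope
#'   (default 0.20).
#' @export
setClass("TrialDesign", representation(
  group = "character", visitTimes = "numeric", power = "numeric",
  alpha = "numeric", pctChange = "numeric"))

setValidity("TrialDesign", function(object) {
  msg <- character()
  if (!object@group %in% c("CU", "CI")) msg <- c(msg, "group must be CU or CI")
  if (length(unique(object@visitTimes)) < 2)
    msg <- c(msg, "at least two distinct visit times required")
  if (!(object@power > 0 && object@power < 1))
    msg <- c(msg, "power must be in (0,1)")
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be in (0,1)")
  if (!(object@pctChange > 0 && object@pctChange <= 1))
    msg <- c(msg, "pctChange must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' @rdname TrialDesign-class
#' @param group trial population.
#' @param visitTimes visit schedule (years).
#' @param power,alpha,pctChange design parameters.
#' @return A [TrialDesign-class] object.
#' @export
TrialDesign <- function(group = c("CI", "CU"), visitTimes = c(0, 1.5),
                        power = 0.80, alpha = 0.05, pctChange = 0.20) {
  new("TrialDesign", group = match.arg(group),
      visitTimes = as.numeric(visitTimes), power = power, alpha = alpha,
      pctChange = pctChange)
}

#' EvaluationResult: the metric bundle for one candidate biomarker
#'
#' @slot spec the evaluated [RatioSpec-class] (or \code{NULL}).
#' @slot sse per-arm sample-size estimate after ceiling (\code{Inf} for a
#'   zero-slope candidate).
#' @slot rawSse pre-ceiling sample size, used for fitness and tie-breaks.
#' @slot separation Wald t-statistic of the time-by-diagnosis interaction;
#'   positive when the impaired group accumulates faster.
#' @slot repeatability percent error: 100 x SD of conditional residuals.
#' @slot fitness separation / rawSse^sseExponent; \code{-Inf} for invalid
#'   candidates.
#' @slot valid logical; \code{FALSE} when the model fit failed.
#' @slot fit the underlying [LMMFit-class] (or \code{NULL}).
#' @slot message why an invalid candidate failed.
#' @export
setClass("EvaluationResult", representation(
  spec = "ANY", sse = "numeric", rawSse = "numeric", separation = "numeric",
  repeatability = "numeric", fitness = "numeric", valid = "logical",
  fit = "ANY", message = "character"))

## ---------------------------------------------------------------------------
## GA configuration and results
## ---------------------------------------------------------------------------

#' GAConfig: genetic-algorithm settings
#'
#' Defaults follow the search recipe: tournament selection with 3 random
#' picks, blend crossover, random adaptive mutation, population 32, 300
#' generations, with one elite copied each generation.
#'
#' @slot populationSize,generations,tournamentSize integers.
#' @slot blendAlpha blend-crossover expansion factor.
#' @slot mutationRate base per-gene mutation probability; \code{NA} means
#'   \code{1/L} for genome length \code{L}.
#' @slot stagnationWindow,mutationBoost,mutationCap adaptive-mutation
#'   controller: after \code{stagnationWindow} generations without
#'   improvement the rate is multiplied by \code{mutationBoost} (capped);
#'   any improvement resets it to base.
#' @slot elitismCount elite copies per generation.
#' @slot crossover \code{"blend"} or \code{"uniform"}.
#' @slot sseExponent exponent on the sample size in the fitness (default 2).
#' @slot frozen named integer vector of pinned unit values.
#' @slot seed RNG seed for the whole run.
#' @export
setClass("GAConfig", representation(
  populationSize = "integer", generations = "integer",
  tournamentSize = "integer", blendAlpha = "numeric",
  mutationRate = "numeric", stagnationWindow = "integer",
  mutationBoost = "numeric", mutationCap = "numeric",
  elitismCount = "integer", crossover = "character",
  sseExponent = "numeric", frozen = "integer", seed = "integer"))

setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@populationSize < 2) msg <- c(msg, "populationSize must be >= 2")
  if (object@tournamentSize > object@populationSize)
    msg <- c(msg, "tournamentSize must be <= populationSize")
  if (!is.na(object@mutationRate) &&
      (object@mutationRate < 0 || object@mutationRate > 1))
    msg <- c(msg, "mutationRate must be in [0,1]")
  if (!object@crossover %in% c("blend", "uniform"))
    msg <- c(msg, "crossover must be 'blend' or 'uniform'")
  if (object@elitismCount < 0 || object@elitismCount >= object@populationSize)
    msg <- c(msg, "elitismCount must be in [0, populationSize)")
  if (length(msg)) msg else TRUE
})

#' @rdname GAConfig-class
#' @param populationSize,generations,tournamentSize,blendAlpha,mutationRate,
#'   stagnationWindow,mutationBoost,mutationCap,elitismCount,crossover,
#'   sseExponent,frozen,seed see slot documentation.
#' @return A [GAConfig-class] object.
#' @export
GAConfig <- function(populationSize = 32L, generations = 300L,
                     tournamentSize = 3L, blendAlpha = 0.5,
                     mutationRate = NA_real_, stagnationWindow = 10L,
                     mutationBoost = 2, mutationCap = 0.5,
                     elitismCount = 1L, crossover = c("blend", "uniform"),
                     sseExponent = 2, frozen = integer(0), seed = 1L) {
  f <- as.integer(frozen); names(f) <- names(frozen)
  new("GAConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      tournamentSize = as.integer(tournamentSize), blendAlpha = blendAlpha,
      mutationRate = mutationRate,
      stagnationWindow = as.integer(stagnationWindow),
      mutationBoost = mutationBoost, mutationCap = mutationCap,
      elitismCount = as.integer(elitismCount),
      crossover = match.arg(crossover), sseExponent = sseExponent,
      frozen = f, seed = as.integer(seed))
}

#' SearchResult: the outcome of a genetic-algorithm run
#'
#' @slot bestGenome best [Genome-class] found.
#' @slot bestSpec its decoded [RatioSpec-class].
#' @slot bestResult its [EvaluationResult-class].
#' @slot trace per-generation data.frame: \code{generation},
#'   \code{best_fitness} (best-so-far; non-decreasing under elitism),
#'   \code{mean_fitness} (finite members of the current population) and
#'   \code{mutation_rate}.
#' @slot topN list of the top-ranked distinct candidates, each a list with
#'   \code{genome} and \code{result}.
#' @slot cacheStats named numeric: \code{evaluations} (distinct genomes
#'   fitted) and \code{hits} (memoized lookups).
#' @slot gaConfig,design,compositeConfig the run configuration.
#' @export
setClass("SearchResult", representation(
  bestGenome = "Genome", bestSpec = "RatioSpec", bestResult = "EvaluationResult",
  trace = "data.frame", topN = "list", cacheStats = "numeric",
  gaConfig = "GAConfig", design = "TrialDesign",
  compositeConfig = "CompositeConfig"))

## ---------------------------------------------------------------------------
## Screening
## ---------------------------------------------------------------------------

#' GMMFit: two-component Gaussian mixture for positivity screening
#'
#' @slot weights,means,sds numeric(2), components sorted by mean.
#' @slot cutoff the derived positivity cutoff.
#' @slot cutoffRule rule used (\code{"equal_posterior"} default).
#' @slot cutoffFallback TRUE when the rule had no root between the means and
#'   the density-valley fallback was used.
#' @slot converged logical.
#' @slot logLik maximised log-likelihood.
#' @export
setClass("GMMFit", representation(
  weights = "numeric", means = "numeric", sds = "numeric", cutoff = "numeric",
  cutoffRule = "character", cutoffFallback = "logical", converged = "logical",
  logLik = "numeric"))

## ---------------------------------------------------------------------------
## Synthetic cohorts
## ---------------------------------------------------------------------------

#' SyntheticConfig: generative settings for a synthetic longitudinal cohort
#'
#' The generator mirrors the fitted model on the log scale: per subject j,
#' region r, time t,
#' \deqn{\log suv = m_r + a_j + (s_{r,g} + c_j) t + \log g_j(t) + e_{jrt}}
#' with (a_j, c_j) bivariate normal (sigmaB0, sigmaB1, rho), a per-scan
#' global lognormal scale factor g shared by all regions of the scan
#' (instrumentation-type confound that ratios cancel) and independent
#' regional noise e. Stable and reference regions have zero slope.
#'
#' @slot nCU,nCI subject counts.
#' @slot visitProbs probabilities of 2, 3 and 4 visits per subject.
#' @slot intervalMix probabilities of the four inter-visit interval bins
#'   (<=1.5, 1.5--2.5, 2.5--3.5, >3.5 years).
#' @slot regions data.frame: \code{region_id}, \code{hemisphere},
#'   \code{bilateral_pair_id}, \code{braak_stage}, \code{reference_candidate},
#'   \code{composites}, \code{role} (signal/stable/reference),
#'   \code{slope_CU}, \code{slope_CI} (log-scale/year), \code{base_log}
#'   (baseline log SUV), \code{volume} (mm^3).
#' @slot sigmaB0,sigmaB1,rho subject random-effect components.
#' @slot sigmaNoise regional measurement noise SD (log scale).
#' @slot sigmaScale SD of the log global per-scan scale factor.
#' @slot volumeJitter relative SD of per-subject volume deviation.
#' @export
setClass("SyntheticConfig", representation(
  nCU = "integer", nCI = "integer", visitProbs = "numeric",
  intervalMix = "numeric", regions = "data.frame", sigmaB0 = "numeric",
  sigmaB1 = "numeric", rho = "numeric", sigmaNoise = "numeric",
  sigmaScale = "numeric", volumeJitter = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (abs(sum(object@intervalMix) - 1) > 1e-8)
    msg <- c(msg, "intervalMix must sum to 1")
  if (abs(sum(object@visitProbs) - 1) > 1e-8)
    msg <- c(msg, "visitProbs must sum to 1")
  if (any(c(object@sigmaB0, object@sigmaB1, object@sigmaNoise,
            object@sigmaScale) < 0))
    msg <- c(msg, "all SDs must be >= 0")
  if (abs(object@rho) > 1) msg <- c(msg, "|rho| must be <= 1")
  rg <- object@regions
  sig <- rg$role == "signal"
  if (any(sig) && any(rg$slope_CI[sig] < rg$slope_CU[sig]))
    msg <- c(msg, "signal regions must have slope_CI >= slope_CU")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: the realized ground truth of a generated cohort
#'
#' @slot randomEffects data.frame: subject_id, group, b0, b1.
#' @slot scanScale data.frame: subject_id, scan_time, log_g.
#' @slot regionRoles data.frame: region_id, role, slope_CU, slope_CI.
#' @export
setClass("SyntheticTruth", representation(
  randomEffects = "data.frame", scanScale = "data.frame",
  regionRoles = "data.frame"))

#' BaselineCatalog: the literature-inspired SUVR baseline grid
#'
#' @slot table data.frame: \code{name}, \code{target}, \code{reference},
#'   \code{method}, \code{usable}, \code{reason}.
#' @slot specs named list of [RatioSpec-class] (NULL for unusable rows).
#' @export
setClass("BaselineCatalog",
         representation(table = "data.frame", specs = "list"))
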