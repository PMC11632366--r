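## Sample-size estimation for a slope-reduction trial, fitness, and the
## full candidate-evaluation pipeline.

#' Shipped trial-design presets
#'
#' \code{experiment1}: preclinical trial in cognitively unimpaired (CU)
#' participants, two visits 54 months apart. \code{experiment2}: clinical
#' trial in cognitively impaired (CI) participants, two visits 18 months
#' apart. Both: 80\% power, two-sided alpha 0.05, detectable effect 20\% of
#' the group mean slope.
#'
#' @param name \code{"experiment1"} or \code{"experiment2"}.
#' @return A [TrialDesign-class].
#' @export
trialPreset <- function(name = c("experiment1", "experiment2")) {
  name <- match.arg(name)
  if (name == "experiment1") TrialDesign("CU", c(0, 4.5))
  else TrialDesign("CI", c(0, 1.5))
}

#' Read a trial design from a YAML config
#'
#' Fields: \code{group}, \code{visit_times}, \code{power}, \code{alpha},
#' \code{pct_change}. Missing fields take the defaults of [TrialDesign()].
#'
#' @param path YAML file.
#' @return A [TrialDesign-class].
#' @export
readTrialDesign <- function(path) {
  x <- yaml::read_yaml(path)
  TrialDesign(group = x$group %||% "CI",
              visitTimes = x$visit_times %||% c(0, 1.5),
              power = x$power %||% 0.80, alpha = x$alpha %||% 0.05,
              pctChange = x$pct_change %||% 0.20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-arm sample-size estimate for a slope-reduction trial
#'
#' The random-slope (Edland-type) formula. With group mean slope
#' \eqn{\gamma} (\code{time} for CU, \code{time + time_dx} for CI),
#' detectable effect \eqn{\Delta = pctChange \cdot |\gamma|}, design visit
#' times \eqn{t_k} and fitted variance components:
#' \deqn{n = 2 (z_{1-\alpha/2} + z_{power})^2
#'   \left(\sigma_{b1}^2 + \sigma_\epsilon^2 / \sum_k (t_k - \bar t)^2\right)
#'   / \Delta^2}
#' The returned \code{sse} is the ceiling of \code{raw}; fitness and
#' tie-breaking use the raw value to avoid integer plateaus. Before the
#' ceiling, the estimate scales exactly as \code{pctChange^-2}.
#'
#' @param fit an [LMMFit-class] from the joint two-group model; variance
#'   components are pooled, the slope is group-specific.
#' @param design a [TrialDesign-class].
#' @return list: \code{sse} (integer-valued, \code{Inf} when the group
#'   slope is zero), \code{raw}, \code{slope}, \code{delta}.
#' @examples
#' \dontrun{sampleSizeEstimate(fit, trialPreset("experiment2"))}
#' @export
sampleSizeEstimate <- function(fit, design) {
  if (!fit@converged) stop("fit did not converge")
  if (is.na(fit@sigmaB1) || is.na(fit@sigmaEps))
    stop("variance components unavailable")
  slope <- unname(if (design@group == "CU") fit@beta["time"]
                  else fit@beta["time"] + fit@beta["time_dx"])
  delta <- design@pctChange * abs(slope)
  if (delta == 0)
    return(list(sse = Inf, raw = Inf, slope = slope, delta = 0))
  tk <- design@visitTimes
  ssq <- sum((tk - mean(tk))^2)
  z <- qnorm(1 - design@alpha / 2) + qnorm(design@power)
  raw <- 2 * z^2 * (fit@sigmaB1^2 + fit@sigmaEps^2 / ssq) / delta^2
  list(sse = ceiling(raw), raw = raw, slope = slope, delta = delta)
}

#' Search fitness of a candidate biomarker
#'
#' \code{separation / sse^exponent}, with the sample size entering squared
#' by default so that trial size is prioritised slightly over group
#' separation. A negative separation (signal decreasing in the impaired
#' group) yields negative fitness and is disfavoured; invalid candidates
#' map to \code{-Inf} and rank below every valid one.
#'
#' @param separation signed t-statistic.
#' @param sse per-arm sample size (raw, pre-ceiling, preferred).
#' @param sseExponent exponent on the sample size (default 2).
#' @return scalar fitness; \code{-Inf} for non-finite inputs.
#' @export
cvrFitness <- function(separation, sse, sseExponent = 2) {
  if (!is.finite(separation) || !is.finite(sse) || sse <= 0) return(-Inf)
  separation / sse^sseExponent
}

.invalidResult <- function(spec, message) {
  new("EvaluationResult", spec = spec, sse = Inf, rawSse = Inf,
      separation = NA_real_, repeatability = NA_real_, fitness = -Inf,
      valid = FALSE, fit = NULL, message = message)
}

#' Evaluate a candidate biomarker against a trial design
#'
#' Composes the full pipeline: [computeCVR()] -> [centerTime()] ->
#' [fitLMM()] -> ([groupSeparation()], [repeatabilityPercent()],
#' [sampleSizeEstimate()], [cvrFitness()]). One joint model is fitted on
#' all subjects of both groups; the sample size uses the design group's
#' slope with the pooled variance components. All candidate-level failures
#' are absorbed into an invalid result (fitness \code{-Inf}); nothing is
#' raised inside a search loop. Evaluation is deterministic given the data.
#'
#' @param dataset a [RegionalDataset-class].
#' @param spec a [RatioSpec-class].
#' @param config a [CompositeConfig-class].
#' @param design a [TrialDesign-class].
#' @param meta region metadata (required for bilateral laterality).
#' @param sseExponent fitness exponent (default 2).
#' @return An [EvaluationResult-class].
#' @export
evaluateCandidate <- function(dataset, spec, config, design, meta = NULL,
                              sseExponent = 2) {
  tryCatch({
    series <- computeCVR(dataset, spec, config, meta)
    frame <- centerTime(series)
    evaluateFrame(frame, design, sseExponent = sseExponent, spec = spec)
  }, error = function(e) .invalidResult(spec, conditionMessage(e)))
}

#' Evaluate an already-centred modelling frame
#'
#' The model-and-metrics tail of [evaluateCandidate()], exposed for
#' workflows that start from a modelling frame (for example simulation
#' studies built on [simulateLongitudinal()]).
#'
#' @param frame output of [centerTime()].
#' @param design a [TrialDesign-class].
#' @param sseExponent fitness exponent.
#' @param spec optional [RatioSpec-class] recorded in the result.
#' @return An [EvaluationResult-class].
#' @export
evaluateFrame <- function(frame, design, sseExponent = 2, spec = NULL) {
  fit <- fitLMM(frame)
  if (!fit@converged) return(.invalidResult(spec, "model did not converge"))
  sep <- groupSeparation(fit)
  rep_ <- repeatabilityPercent(fit)
  sse <- sampleSizeEstimate(fit, design)
  new("EvaluationResult", spec = spec, sse = sse$sse, rawSse = sse$raw,
      separation = sep, repeatability = rep_,
      fitness = cvrFitness(sep, sse$raw, sseExponent), valid = TRUE,
      fit = fit, message = "")
}

#' Monte-Carlo empirical power of a two-arm slope trial
#'
#' Independent validation of [sampleSizeEstimate()]: simulates per-subject
#' slope estimates for placebo and treated arms and applies a two-sample
#' pooled t-test on the slopes. Under the model, the OLS slope of a subject
#' observed at the design visit times has variance
#' \eqn{\sigma_{b1}^2 + \sigma_\epsilon^2 / \sum_k (t_k - \bar t)^2}.
#'
#' @param n per-arm sample size.
#' @param slope placebo-arm mean slope (log scale / year).
#' @param delta absolute slope reduction in the treated arm.
#' @param sigmaB1,sigmaEps variance components.
#' @param visitTimes trial visit schedule.
#' @param nsim number of simulated trials.
#' @param alpha two-sided significance level.
#' @return empirical power (fraction of trials rejecting).
#' @export
mcTrialPower <- function(n, slope, delta, sigmaB1, sigmaEps,
                         visitTimes = c(0, 1.5), nsim = 2000,
                         alpha = 0.05) {
  ssq <- sum((visitTimes - mean(visitTimes))^2)
  sd_slope <- sqrt(sigmaB1^2 + sigmaEps^2 / ssq)
  placebo <- matrix(rnorm(n * nsim, slope, sd_slope), n, nsim)
  treated <- matrix(rnorm(n * nsim, slope - delta, sd_slope), n, nsim)
  m1 <- colMeans(placebo); m2 <- colMeans(treated)
  v1 <- apply(placebo, 2, var); v2 <- apply(treated, 2, var)
  pooled <- sqrt(((n - 1) * v1 + (n - 1) * v2) / (2 * n - 2))
  tstat <- (m1 - m2) / (pooled * sqrt(2 / n))
  mean(abs(tstat) > qt(1 - alpha / 2, df = 2 * n - 2))
}
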