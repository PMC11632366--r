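## The random-intercept/slope model on the log biomarker and the three
## metric ingredients: group separation, repeatability, variance components.

#' Build the centred longitudinal modelling frame
#'
#' Time is centred at each subject's mean scan time, which (together with
#' the correlated random intercepts and slopes) makes every downstream
#' metric invariant to shifting any subject's visit times by a constant.
#' The response is the natural log of the biomarker value.
#'
#' @param series biomarker series as returned by [computeCVR()]: a
#'   data.frame with \code{subject_id}, \code{scan_time} and either
#'   \code{log_value} or \code{value}, and optionally \code{group}.
#' @param groups optional named vector mapping subject ids to
#'   \code{"CU"}/\code{"CI"}; defaults to the series' \code{group} column.
#' @return data.frame with \code{subject}, \code{time} (centred years),
#'   \code{dx} (0 = CU, 1 = CI) and \code{y} (log value).
#' @export
centerTime <- function(series, groups = NULL) {
  if (is.null(groups)) {
    if (is.null(series$group)) stop("no group labels supplied")
    groups <- tapply(as.character(series$group), series$subject_id,
                     function(g) g[1])
  }
  subj <- as.character(series$subject_id)
  unlabelled <- setdiff(unique(subj), names(groups))
  if (length(unlabelled))
    stop("subject(s) without group label: ",
         paste(unlabelled, collapse = ", "))
  nvis <- tapply(series$scan_time, subj, function(t) length(unique(t)))
  if (any(nvis < 2))
    stop("subject(s) with fewer than 2 observations: ",
         paste(names(nvis)[nvis < 2], collapse = ", "))
  y <- if (!is.null(series$log_value)) series$log_value else
    log(series$value)
  tbar <- tapply(series$scan_time, subj, mean)
  g <- as.character(groups[subj])
  if (!all(g %in% c("CU", "CI"))) stop("groups must be 'CU' or 'CI'")
  data.frame(subject = subj, time = series$scan_time - tbar[subj],
             dx = as.integer(g == "CI"), y = y,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the correlated random-intercept/slope model
#'
#' Fits \code{y ~ time * dx + (time | subject)} by REML (default): fixed
#' intercept, common time slope, diagnosis offset and time-by-diagnosis
#' interaction, with an unstructured 2x2 random-effect covariance and
#' residual error. Non-convergence is flagged, not raised (the search loop
#' treats flagged fits as invalid candidates); a boundary fit with the
#' slope variance at zero is valid with \code{singular = TRUE}.
#'
#' @param frame output of [centerTime()].
#' @param REML use restricted maximum likelihood (set \code{FALSE} for
#'   nested likelihood-ratio comparisons).
#' @param correlated keep the intercept-slope correlation (\code{FALSE}
#'   fits independent random effects, used by [lrtRandomCorrelation()]).
#' @return An [LMMFit-class].
#' @export
fitLMM <- function(frame, REML = TRUE, correlated = TRUE) {
  stopifnot(all(c("subject", "time", "dx", "y") %in% colnames(frame)))
  two_group <- length(unique(frame$dx)) > 1
  form <- if (two_group) {
    if (correlated) y ~ time * dx + (time | subject)
    else y ~ time * dx + (time || subject)
  } else {
    if (correlated) y ~ time + (time | subject)
    else y ~ time + (time || subject)
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.nobs.vs.nlev = "ignore")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = frame, REML = REML, control = ctrl))),
    error = function(e) e)
  nobs <- nrow(frame)
  nsub <- length(unique(frame$subject))
  if (inherits(fit, "error"))
    return(new("LMMFit", beta = setNames(rep(NA_real_, 4), .betaNames()),
               se = setNames(rep(NA_real_, 4), .betaNames()),
               sigmaB0 = NA_real_, sigmaB1 = NA_real_, rho = NA_real_,
               sigmaEps = NA_real_, residuals = numeric(0),
               logLik = NA_real_, REML = REML, converged = FALSE,
               singular = FALSE, nObs = as.integer(nobs),
               nSubjects = as.integer(nsub), model = NULL))
  .lmmFromMer(fit, REML = REML, correlated = correlated, nObs = nobs,
              nSubjects = nsub)
}

## Extract the LMMFit summary from a fitted merMod (also used for fast
## bootstrap refits).
.lmmFromMer <- function(fit, REML, correlated = TRUE, nObs = NULL,
                        nSubjects = NULL) {
  if (is.null(nObs)) nObs <- stats::nobs(fit)
  if (is.null(nSubjects)) nSubjects <- unname(lme4::ngrps(fit)[1])
  converged <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0L
  singular <- lme4::isSingular(fit, tol = 1e-5)
  vcl <- lme4::VarCorr(fit)
  if (correlated) {
    vc <- vcl$subject
    sds <- attr(vc, "stddev")
    corr <- attr(vc, "correlation")
    rho <- if (!is.null(corr) && nrow(corr) == 2) corr[1, 2] else 0
  } else {
    # double-bar formula: two independent variance terms for one group
    sds <- vapply(vcl, function(v) attr(v, "stddev")[1], numeric(1))
    rho <- 0
  }
  fe <- lme4::fixef(fit)
  ses <- suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit)))))
  beta <- setNames(rep(0, 4), .betaNames())
  se <- setNames(rep(NA_real_, 4), .betaNames())
  key <- c("(Intercept)" = "intercept", "time" = "time", "dx" = "dx",
           "time:dx" = "time_dx")
  beta[key[names(fe)]] <- fe
  se[key[names(fe)]] <- ses
  new("LMMFit", beta = beta, se = se,
      sigmaB0 = unname(sds[1]),
      sigmaB1 = if (length(sds) > 1) unname(sds[2]) else 0,
      rho = unname(rho), sigmaEps = stats::sigma(fit),
      residuals = unname(stats::resid(fit)),
      logLik = as.numeric(stats::logLik(fit)), REML = REML,
      converged = converged, singular = singular,
      nObs = as.integer(nObs), nSubjects = as.integer(nSubjects),
      model = fit)
}

.betaNames <- function() c("intercept", "time", "dx", "time_dx")

#' Cognitive-group trajectory separation
#'
#' The Wald t-statistic of the time-by-diagnosis interaction:
#' \code{beta_time_dx / SE}. Positive when the impaired group accumulates
#' faster. No finite-sample df correction is applied; only the relative
#' magnitude feeds the search fitness.
#'
#' @param fit an [LMMFit-class].
#' @return signed scalar.
#' @export
groupSeparation <- function(fit) {
  if (!fit@converged) stop("fit did not converge")
  se <- fit@se["time_dx"]
  if (is.na(se)) stop("fit has no diagnosis term")
  if (se == 0) stop("degenerate fit: zero standard error")
  unname(fit@beta["time_dx"] / se)
}

#' Longitudinal repeatability (percent error)
#'
#' 100 times the standard deviation of the conditional residuals on the
#' log scale, which approximates relative error in percent. The model's
#' residual-SD parameter is available as \code{fit@sigmaEps} for
#' comparison; the empirical residual SD is the default metric.
#'
#' @param fit an [LMMFit-class].
#' @return percent error (scalar >= 0).
#' @export
repeatabilityPercent <- function(fit) {
  if (!fit@converged) stop("fit did not converge")
  100 * sd(fit@residuals)
}

#' Likelihood-ratio test of the random intercept-slope correlation
#'
#' Fits the correlated and uncorrelated random-effects models by maximum
#' likelihood (not REML, for comparability) and returns the chi-squared
#' statistic \code{2 (LL_corr - LL_uncorr)} on 1 df with its upper-tail
#' p-value. The test is conservative near the boundary.
#'
#' @param frame output of [centerTime()].
#' @return list: \code{chisq}, \code{df}, \code{p},
#'   \code{logLik_correlated}, \code{logLik_uncorrelated}.
#' @export
lrtRandomCorrelation <- function(frame) {
  f1 <- fitLMM(frame, REML = FALSE, correlated = TRUE)
  f0 <- fitLMM(frame, REML = FALSE, correlated = FALSE)
  if (!f1@converged || !f0@converged)
    stop("one of the nested fits did not converge")
  chisq <- max(0, 2 * (f1@logLik - f0@logLik))
  list(chisq = chisq, df = 1L, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       logLik_correlated = f1@logLik, logLik_uncorrelated = f0@logLik)
}

#' Serialize an LMMFit summary to JSON
#'
#' @param fit an [LMMFit-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLMMFit <- function(fit, path) {
  jsonlite::write_json(list(
    beta = as.list(fit@beta), se = as.list(fit@se),
    sigma_b0 = fit@sigmaB0, sigma_b1 = fit@sigmaB1, rho = fit@rho,
    sigma_eps = fit@sigmaEps, logLik = fit@logLik, REML = fit@REML,
    converged = fit@converged, singular = fit@singular,
    n_obs = fit@nObs, n_subjects = fit@nSubjects),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
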