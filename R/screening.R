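## Cohort-inclusion utilities: fixed-threshold amyloid positivity and the
## data-driven two-component Gaussian-mixture cutoff.

#' Fixed-threshold amyloid positivity
#'
#' Boundary inclusive: positive iff \code{value >= cutoff}. Published
#' composite-SUVR cutoffs for common tracers are 0.78 (Florbetapir F18)
#' and 0.74 (Florbetaben F18).
#'
#' @param value numeric vector of composite amyloid measures.
#' @param cutoff scalar threshold.
#' @return logical vector.
#' @examples
#' thresholdPositivity(c(0.779, 0.78), 0.78)  # FALSE TRUE
#' @export
thresholdPositivity <- function(value, cutoff) {
  stopifnot(is.finite(cutoff), all(is.finite(value)))
  value >= cutoff
}

#' Fit a two-component univariate Gaussian mixture
#'
#' EM fit (via \pkg{mclust}, unequal variances) with components sorted so
#' that \code{means[1] < means[2]}. Degenerate inputs (for example all
#' values identical) yield a non-converged fit rather than an error. The
#' equal-posterior positivity cutoff is attached (see
#' [positivityCutoff()]).
#'
#' @param values numeric vector (>= 10 finite values).
#' @param seed RNG seed (the EM initialisation is deterministic; the seed
#'   is set for reproducibility of any downstream stochastic use).
#' @return A [GMMFit-class].
#' @export
fitGMM2 <- function(values, seed = 1L) {
  stopifnot(length(values) >= 10, all(is.finite(values)))
  set.seed(seed)
  nonconv <- new("GMMFit", weights = c(NA_real_, NA_real_),
                 means = c(NA_real_, NA_real_), sds = c(NA_real_, NA_real_),
                 cutoff = NA_real_, cutoffRule = "equal_posterior",
                 cutoffFallback = FALSE, converged = FALSE,
                 logLik = NA_real_)
  # degenerate spread: no two-component structure to fit
  if (length(unique(values)) < 3 ||
      sd(values) < 1e-10 * max(1, abs(mean(values))))
    return(nonconv)
  m <- tryCatch(
    suppressWarnings(mclust::Mclust(values, G = 2, modelNames = c("V", "E"),
                                    verbose = FALSE)),
    error = function(e) NULL)
  bad <- is.null(m) || is.null(m$parameters) || anyNA(m$parameters$mean) ||
    any(!is.finite(sqrt(m$parameters$variance$sigmasq)))
  if (!bad) {
    sds <- sqrt(m$parameters$variance$sigmasq)
    if (length(sds) == 1) sds <- rep(sds, 2)
    bad <- any(sds <= 0) ||
      abs(diff(m$parameters$mean)) < .Machine$double.eps
  }
  if (bad) return(nonconv)
  ord <- order(m$parameters$mean)
  fit <- new("GMMFit", weights = m$parameters$pro[ord],
             means = unname(m$parameters$mean[ord]), sds = sds[ord],
             cutoff = NA_real_, cutoffRule = "equal_posterior",
             cutoffFallback = FALSE, converged = TRUE,
             logLik = as.numeric(m$loglik))
  cut <- positivityCutoff(fit)
  fit@cutoff <- cut
  fit@cutoffFallback <- isTRUE(attr(cut, "fallback"))
  fit
}

#' Derive a positivity cutoff from a two-component mixture
#'
#' The default rule is the equal-posterior point: the location between the
#' component means where the weighted component densities are equal (the
#' Bayes decision boundary), solved in closed form from the quadratic in x
#' of \code{log(w1 phi1(x)) = log(w2 phi2(x))}. For equal weights and SDs
#' this is exactly the midpoint of the means. If no such root lies between
#' the means (extreme weight imbalance), the rule falls back to the
#' density-valley minimum and flags it. Alternative rules:
#' \code{"valley"} (mixture-density minimum between the means) and
#' \code{"mu1_2sd"} (mean of the lower component plus two of its SDs).
#'
#' @param fit a converged [GMMFit-class].
#' @param rule cutoff rule.
#' @return scalar cutoff, with attribute \code{fallback} when the
#'   equal-posterior rule had to fall back.
#' @export
positivityCutoff <- function(fit, rule = c("equal_posterior", "valley",
                                           "mu1_2sd")) {
  rule <- match.arg(rule)
  if (!fit@converged) stop("mixture fit did not converge")
  mu <- fit@means; s <- fit@sds; w <- fit@weights
  stopifnot(mu[1] < mu[2])
  if (rule == "mu1_2sd") return(mu[1] + 2 * s[1])
  valley <- function() {
    optimize(function(x) w[1] * dnorm(x, mu[1], s[1]) +
               w[2] * dnorm(x, mu[2], s[2]),
             interval = mu, maximum = FALSE)$minimum
  }
  if (rule == "valley") return(valley())
  # equal posterior: quadratic a x^2 + b x + c = 0
  a <- 1 / (2 * s[1]^2) - 1 / (2 * s[2]^2)
  b <- mu[2] / s[2]^2 - mu[1] / s[1]^2
  cc <- mu[1]^2 / (2 * s[1]^2) - mu[2]^2 / (2 * s[2]^2) -
    log((w[1] * s[2]) / (w[2] * s[1]))
  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside)) return(inside[1])
  out <- valley()
  attr(out, "fallback") <- TRUE
  out
}

#' Write a screening result as JSON
#'
#' @param fit a [GMMFit-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGMMFit <- function(fit, path) {
  jsonlite::write_json(list(
    converged = fit@converged, weights = fit@weights, means = fit@means,
    sds = fit@sds, cutoff = fit@cutoff, cutoff_rule = fit@cutoffRule,
    cutoff_fallback = fit@cutoffFallback, logLik = fit@logLik),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
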