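## Literature-inspired SUVR baseline grid, regional ablation, and
## parametric-bootstrap confidence intervals.

.baselineTargets <- function() c(paste0("braak", 1:6), "meta_temporal",
                                 "mesial_temporal", "temporoparietal",
                                 "rest")

## The eleven reference regions: six single composites and five of their
## unions, as used across the SUVR literature.
.baselineReferences <- function() list(
  whole_cerebellum = "whole_cerebellum",
  inferior_cerebellum_gm = "inferior_cerebellum_gm",
  composite_reference = "composite_reference",
  eroded_subcortical_wm = "eroded_subcortical_wm",
  cerebellum_cortex = "cerebellum_cortex",
  brainstem = "brainstem",
  ewm_inferior_cerebellum_gm = c("eroded_subcortical_wm",
                                 "inferior_cerebellum_gm"),
  ewm_whole_cerebellum = c("eroded_subcortical_wm", "whole_cerebellum"),
  whole_cerebellum_brainstem = c("whole_cerebellum", "brainstem"),
  inferior_cerebellum_gm_brainstem = c("inferior_cerebellum_gm",
                                       "brainstem"),
  ewm_inferior_cerebellum_gm_brainstem = c("eroded_subcortical_wm",
                                           "inferior_cerebellum_gm",
                                           "brainstem"))

#' Enumerate the literature-inspired SUVR baseline grid
#'
#' Every combination of composite target (the six Braak-stage region sets,
#' meta-temporal, mesial-temporal, temporoparietal, 'rest'), reference
#' region (six single references and five of their unions) and composition
#' method (mean SUV, volume-weighted SUV): 10 x 11 x 2 = 220 baselines for
#' the default metadata. A target or reference whose member set is empty,
#' or that overlaps its counterpart, marks the baseline unusable with a
#' reason rather than dropping it silently.
#'
#' @param meta a [RegionMetadata-class].
#' @return A [BaselineCatalog-class].
#' @export
enumerateBaselines <- function(meta) {
  targets <- .baselineTargets()
  refs <- .baselineReferences()
  methods <- c("mean_suv", "volume_weighted")
  rows <- list(); specs <- list()
  for (tg in targets) {
    tg_members <- compositeMembers(meta, tg)
    for (rf in names(refs)) {
      rf_members <- unique(unlist(lapply(refs[[rf]], compositeMembers,
                                         meta = meta)))
      for (m in methods) {
        name <- paste0(if (m == "mean_suv") "mSUV" else "SUV", "_",
                       tg, "/", rf)
        usable <- TRUE; reason <- ""
        if (!length(tg_members)) {
          usable <- FALSE; reason <- "target composite has no members"
        } else if (!length(rf_members)) {
          usable <- FALSE; reason <- "reference composite has no members"
        } else if (length(intersect(tg_members, rf_members))) {
          usable <- FALSE; reason <- "target and reference overlap"
        }
        rows[[name]] <- data.frame(name = name, target = tg,
                                   reference = rf, method = m,
                                   usable = usable, reason = reason,
                                   stringsAsFactors = FALSE)
        specs[[name]] <- if (usable) RatioSpec(tg_members, rf_members)
        else NULL
      }
    }
  }
  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  new("BaselineCatalog", table = tb, specs = specs)
}

#' Number of baselines in a catalog
#'
#' @param catalog a [BaselineCatalog-class].
#' @param usableOnly count only usable entries.
#' @return integer.
#' @export
catalogSize <- function(catalog, usableOnly = FALSE) {
  if (usableOnly) sum(catalog@table$usable) else nrow(catalog@table)
}

#' Evaluate every baseline of a catalog
#'
#' One row per baseline per design; candidate-level failures and unusable
#' baselines are recorded as sentinel rows (infinite sample size, \code{-Inf}
#' fitness), never raised. Row order follows the catalog.
#'
#' @param dataset a [RegionalDataset-class].
#' @param catalog a [BaselineCatalog-class].
#' @param meta a [RegionMetadata-class].
#' @param designs a named list of [TrialDesign-class] (or a single design).
#' @param laterality hemisphere handling for all baselines.
#' @param sseExponent fitness exponent.
#' @return data.frame: \code{name}, \code{design}, \code{method},
#'   \code{sse}, \code{raw_sse}, \code{separation}, \code{repeatability},
#'   \code{fitness}, \code{valid}, \code{message}.
#' @export
evaluateCatalog <- function(dataset, catalog, meta, designs,
                            laterality = "bilateral", sseExponent = 2) {
  if (is(designs, "TrialDesign")) designs <- list(design = designs)
  tb <- catalog@table
  out <- list()
  for (d in names(designs)) {
    for (i in seq_len(nrow(tb))) {
      nm <- tb$name[i]
      res <- if (!tb$usable[i]) .invalidResult(NULL, tb$reason[i]) else
        evaluateCandidate(dataset, catalog@specs[[nm]],
                          CompositeConfig(tb$method[i], laterality),
                          designs[[d]], meta = meta,
                          sseExponent = sseExponent)
      out[[length(out) + 1L]] <- data.frame(
        name = nm, design = d, method = tb$method[i], sse = res@sse,
        raw_sse = res@rawSse, separation = res@separation,
        repeatability = res@repeatability, fitness = res@fitness,
        valid = res@valid, message = res@message, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Single-region ablation of a biomarker
#'
#' Re-evaluates the biomarker once per region removal, for every region
#' whose removal keeps both sides non-empty; impossible removals are
#' listed as skipped with a reason.
#'
#' @param dataset a [RegionalDataset-class].
#' @param spec a [RatioSpec-class] to ablate.
#' @param config a [CompositeConfig-class].
#' @param design a [TrialDesign-class].
#' @param meta region metadata.
#' @param sseExponent fitness exponent.
#' @return data.frame: \code{region}, \code{side}, \code{skipped},
#'   \code{reason}, and the metric columns of [evaluateCatalog()].
#' @export
ablate <- function(dataset, spec, config, design, meta = NULL,
                   sseExponent = 2) {
  rows <- list()
  for (side in c("numerator", "denominator")) {
    members <- slot(spec, side)
    for (r in members) {
      if (length(members) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, side = side, skipped = TRUE,
          reason = paste("removal would empty the", side),
          sse = NA_real_, raw_sse = NA_real_, separation = NA_real_,
          repeatability = NA_real_, fitness = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      s2 <- if (side == "numerator")
        RatioSpec(setdiff(members, r), spec@denominator)
      else RatioSpec(spec@numerator, setdiff(members, r))
      res <- evaluateCandidate(dataset, s2, config, design, meta = meta,
                               sseExponent = sseExponent)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, side = side, skipped = FALSE, reason = "",
        sse = res@sse, raw_sse = res@rawSse, separation = res@separation,
        repeatability = res@repeatability, fitness = res@fitness,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Parametric-bootstrap confidence intervals for biomarker metrics
#'
#' Model-based parametric bootstrap: holding the design matrix fixed, new
#' responses are built from the fitted fixed effects plus random effects
#' drawn from the estimated bivariate normal and residuals from
#' N(0, sigma_eps^2); the model is refitted and the metrics recomputed.
#' Percentile 2.5/97.5 intervals over \code{B} replicates. Non-convergent
#' replicates are dropped and counted; more than 20\% failures flags the
#' interval unreliable. Percentile crossing from skew is flagged, not
#' failed. Deterministic given \code{seed}.
#'
#' @param dataset a [RegionalDataset-class].
#' @param spec a [RatioSpec-class].
#' @param config a [CompositeConfig-class].
#' @param design a [TrialDesign-class].
#' @param meta region metadata.
#' @param metrics which metrics to summarise (subset of \code{"sse"},
#'   \code{"separation"}, \code{"repeatability"}, \code{"fitness"},
#'   \code{"beta3"}).
#' @param B replicate count (default 500).
#' @param seed RNG seed.
#' @param sseExponent fitness exponent.
#' @return data.frame: \code{metric}, \code{point}, \code{lower},
#'   \code{upper}, \code{B}, \code{B_used}, \code{unreliable},
#'   \code{crossed}; replicate draws attached as
#'   \code{attr(, "replicates")}.
#' @export
bootstrapCI <- function(dataset, spec, config, design, meta = NULL,
                        metrics = c("sse", "separation", "repeatability",
                                    "fitness"),
                        B = 500L, seed = 1L, sseExponent = 2) {
  metrics <- match.arg(metrics, c("sse", "separation", "repeatability",
                                  "fitness", "beta3"), several.ok = TRUE)
  base <- evaluateCandidate(dataset, spec, config, design, meta = meta,
                            sseExponent = sseExponent)
  if (!base@valid) stop("baseline fit failed: ", base@message)
  bootstrapCIFromFit(base, design, metrics = metrics, B = B, seed = seed,
                     sseExponent = sseExponent)
}

## Fast REML re-optimizer for bootstrap replicates: reuses the fitted
## model's lme4 deviance function, swapping in the replicate response and
## re-optimizing the 2x2 covariance parameters with nlminb. Agrees with
## lme4::refit() to optimizer tolerance at a fraction of the overhead.
.fastLmmEngine <- function(model) {
  devfun <- suppressMessages(suppressWarnings(
    stats::update(model, devFunOnly = TRUE)))
  rho <- environment(devfun)
  th0 <- lme4::getME(model, "theta")
  n <- stats::nobs(model)
  fenames <- names(lme4::fixef(model))
  p <- length(fenames)
  REML <- lme4::isREML(model)
  denom <- if (REML) n - p else n
  key <- c("(Intercept)" = "intercept", "time" = "time", "dx" = "dx",
           "time:dx" = "time_dx")
  nsub <- unname(lme4::ngrps(model)[1])
  function(ystar) {
    rho$resp$setResp(ystar)
    opt <- nlminb(th0, devfun, lower = rho$lower)
    devfun(opt$par)  # leave the environment at the optimum
    fe <- rho$pp$beta(1)
    names(fe) <- fenames
    sig <- sqrt((rho$resp$wrss() + rho$pp$sqrL(1)) / denom)
    ses <- sig * sqrt(diag(as.matrix(rho$pp$unsc())))
    names(ses) <- fenames
    th <- opt$par
    beta <- setNames(rep(0, 4), .betaNames())
    se <- setNames(rep(NA_real_, 4), .betaNames())
    beta[key[fenames]] <- fe
    se[key[fenames]] <- ses
    sb1 <- if (length(th) >= 3) sig * sqrt(th[2]^2 + th[3]^2) else 0
    new("LMMFit", beta = beta, se = se, sigmaB0 = sig * th[1],
        sigmaB1 = sb1,
        rho = if (sb1 > 0) sig * th[2] / sb1 else 0, sigmaEps = sig,
        residuals = as.vector(ystar - rho$resp$mu),
        logLik = -opt$objective / 2, REML = REML,
        converged = opt$convergence == 0, singular = any(th[c(1, 3)] < 1e-5),
        nObs = as.integer(n), nSubjects = as.integer(nsub), model = NULL)
  }
}

#' @rdname bootstrapCI
#' @param result an already-computed valid [EvaluationResult-class] (with
#'   its model retained), for callers that have one.
#' @export
bootstrapCIFromFit <- function(result, design,
                               metrics = c("sse", "separation",
                                           "repeatability", "fitness"),
                               B = 500L, seed = 1L, sseExponent = 2) {
  fit <- result@fit
  model <- fit@model
  if (is.null(model)) stop("fit does not retain its model")
  set.seed(seed)
  fr <- model@frame
  subj <- as.character(fr$subject)
  usub <- unique(subj)
  j <- match(subj, usub)
  mu <- as.vector(predict(model, re.form = NA))
  Sigma <- matrix(c(fit@sigmaB0^2,
                    rep(fit@rho * fit@sigmaB0 * fit@sigmaB1, 2),
                    fit@sigmaB1^2), 2, 2)
  point <- c(sse = result@sse, separation = result@separation,
             repeatability = result@repeatability,
             fitness = result@fitness,
             beta3 = unname(fit@beta["time_dx"]))
  engine <- tryCatch(.fastLmmEngine(model), error = function(e) NULL)
  refit_fit <- function(ystar) {
    m2 <- tryCatch(
      suppressMessages(suppressWarnings(lme4::refit(model, ystar))),
      error = function(e) NULL)
    if (is.null(m2)) NULL else .lmmFromMer(m2, REML = fit@REML)
  }
  draw_one <- function() {
    b <- MASS::mvrnorm(length(usub), c(0, 0), Sigma)
    ystar <- mu + b[j, 1] + b[j, 2] * fr$time +
      rnorm(nrow(fr), 0, fit@sigmaEps)
    f2 <- if (!is.null(engine))
      tryCatch(engine(ystar), error = function(e) NULL)
    else refit_fit(ystar)
    if (is.null(f2) || !f2@converged) return(NULL)
    sep <- tryCatch(groupSeparation(f2), error = function(e) NA_real_)
    ss <- sampleSizeEstimate(f2, design)
    c(sse = ss$sse, separation = sep,
      repeatability = repeatabilityPercent(f2),
      fitness = cvrFitness(sep, ss$raw, sseExponent),
      beta3 = unname(f2@beta["time_dx"]))
  }
  reps <- vapply(seq_len(B), function(i) {
    r <- draw_one()
    if (is.null(r)) rep(NA_real_, 5) else r
  }, numeric(5))
  rownames(reps) <- c("sse", "separation", "repeatability", "fitness",
                      "beta3")
  used <- colSums(is.na(reps)) == 0
  unreliable <- mean(!used) > 0.20
  out <- do.call(rbind, lapply(metrics, function(m) {
    q <- quantile(reps[m, used], c(0.025, 0.975), na.rm = TRUE,
                  names = FALSE)
    data.frame(metric = m, point = unname(point[m]), lower = q[1],
               upper = q[2], B = B, B_used = sum(used),
               unreliable = unreliable,
               crossed = !(q[1] <= point[m] && point[m] <= q[2]),
               stringsAsFactors = FALSE)
  }))
  attr(out, "replicates") <- reps[metrics, used, drop = FALSE]
  out
}
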