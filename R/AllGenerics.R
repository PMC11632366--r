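#' @rdname RegionalDataset-class
#' @param object,x a package object.
#' @param ... passed on.
#' @export
setGeneric("suv", function(x) standardGeneric("suv"))

#' @rdname RegionalDataset-class
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname RegionalDataset-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname RegionalDataset-class
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname RegionalDataset-class
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))

#' @rdname RegionalDataset-class
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @export
#' @rdname RegionalDataset-class
setMethod("suv", "RegionalDataset",
          function(x) SummarizedExperiment::assay(x, "suv"))

#' @export
#' @rdname RegionalDataset-class
setMethod("volumes", "RegionalDataset",
          function(x) SummarizedExperiment::assay(x, "volume"))

#' @export
#' @rdname RegionalDataset-class
setMethod("subjectIds", "RegionalDataset",
          function(x) SummarizedExperiment::colData(x)$subject_id)

#' @export
#' @rdname RegionalDataset-class
setMethod("groups", "RegionalDataset",
          function(x) SummarizedExperiment::colData(x)$group)

#' @export
#' @rdname RegionalDataset-class
setMethod("scanTimes", "RegionalDataset",
          function(x) SummarizedExperiment::colData(x)$scan_time)

#' @export
#' @rdname RegionalDataset-class
setMethod("regionIds", "RegionalDataset", function(x) rownames(x))

#' @export
#' @rdname RegionMetadata-class
setMethod("regionIds", "RegionMetadata", function(x) x@table$region_id)

#' @rdname RegionMetadata-class
#' @param x a [RegionMetadata-class] object.
#' @export
setGeneric("metadataTable", function(x) standardGeneric("metadataTable"))

#' @export
#' @rdname RegionMetadata-class
setMethod("metadataTable", "RegionMetadata", function(x) x@table)

setMethod("show", "RegionalDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("RegionalDataset:", nrow(object), "regions x", ncol(object), "scans\n")
  cat("  subjects:", length(unique(cd$subject_id)),
      sprintf("(CU %d, CI %d)",
              length(unique(cd$subject_id[cd$group == "CU"])),
              length(unique(cd$subject_id[cd$group == "CI"]))), "\n")
  cat("  scan_time range:", paste(signif(range(cd$scan_time), 4),
                                  collapse = " .. "), "years\n")
})

setMethod("show", "RegionMetadata", function(object) {
  tb <- object@table
  cat("RegionMetadata:", nrow(tb), "regions;",
      sum(!is.na(tb$bilateral_pair_id)) / 2, "bilateral pairs;",
      sum(tb$reference_candidate), "reference candidates\n")
  labs <- compositeLabels(object)
  if (length(labs))
    cat("  composites:", paste(head(labs, 8), collapse = ", "),
        if (length(labs) > 8) "...", "\n")
})

setMethod("show", "Genome", function(object) {
  a <- object@assignment
  cat("Genome over", length(a), "units:",
      sum(a == 0), "numerator /", sum(a == 2), "denominator /",
      sum(a == 1), "excluded")
  if (length(object@frozen)) cat(";", length(object@frozen), "frozen")
  cat("\n")
})

setMethod("show", "RatioSpec", function(object) {
  cat("RatioSpec\n  numerator  (", length(object@numerator), "): ",
      paste(object@numerator, collapse = ", "), "\n  denominator(",
      length(object@denominator), "): ",
      paste(object@denominator, collapse = ", "), "\n", sep = "")
})

setMethod("show", "LMMFit", function(object) {
  cat("LMMFit (", if (object@REML) "REML" else "ML", "), ",
      object@nObs, " obs / ", object@nSubjects, " subjects; converged: ",
      object@converged, if (object@singular) " (singular)", "\n", sep = "")
  print(signif(rbind(beta = object@beta, se = object@se), 4))
  cat("  sigma_b0 =", signif(object@sigmaB0, 4),
      " sigma_b1 =", signif(object@sigmaB1, 4),
      " rho =", signif(object@rho, 3),
      " sigma_eps =", signif(object@sigmaEps, 4), "\n")
})

setMethod("show", "EvaluationResult", function(object) {
  if (!object@valid) {
    cat("EvaluationResult: INVALID (", object@message, ")\n", sep = "")
  } else {
    cat("EvaluationResult: SSE =", object@sse,
        " separation =", signif(object@separation, 3),
        " repeatability =", signif(object@repeatability, 3), "%",
        " fitness =", signif(object@fitness, 4), "\n")
  }
})

setMethod("show", "SearchResult", function(object) {
  cat("SearchResult after", max(object@trace$generation), "generations\n")
  show(object@bestResult)
  show(object@bestSpec)
  cat("  evaluations:", object@cacheStats["evaluations"],
      " cache hits:", object@cacheStats["hits"], "\n")
})

setMethod("show", "GMMFit", function(object) {
  cat("GMMFit: converged =", object@converged, "\n")
  if (object@converged) {
    cat("  means =", paste(signif(object@means, 4), collapse = ", "),
        " sds =", paste(signif(object@sds, 4), collapse = ", "),
        " weights =", paste(signif(object@weights, 3), collapse = ", "), "\n")
    cat("  cutoff =", signif(object@cutoff, 5), "(", object@cutoffRule,
        if (object@cutoffFallback) ", fallback", ")\n")
  }
})

setMethod("show", "TrialDesign", function(object) {
  cat("TrialDesign:", object@group, "group, visits at {",
      paste(object@visitTimes, collapse = ", "), "} years, power",
      object@power, ", alpha", object@alpha, ", effect",
      object@pctChange * 100, "% of slope\n")
})
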