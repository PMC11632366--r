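## Fixtures built in code: small metadata tables and datasets used across
## the suite.

## Four midline regions: a/b are plausible targets, c carries an early
## Braak stage, d is a conventional reference region.
tinyMeta <- function() {
  RegionMetadata(data.frame(
    region_id = c("a", "b", "c", "d"),
    hemisphere = "midline", bilateral_pair_id = "none",
    braak_stage = c("none", "none", "2", "none"),
    reference_candidate = c(FALSE, FALSE, FALSE, TRUE),
    composites = c("meta_temporal", "meta_temporal", "none",
                   "whole_cerebellum"),
    stringsAsFactors = FALSE))
}

## One bilateral pair plus a midline reference.
pairMeta <- function() {
  RegionMetadata(data.frame(
    region_id = c("amygdala_L", "amygdala_R", "whole_cerebellum"),
    hemisphere = c("left", "right", "midline"),
    bilateral_pair_id = c("amygdala", "amygdala", "none"),
    braak_stage = "none",
    reference_candidate = c(FALSE, FALSE, TRUE),
    composites = c("meta_temporal", "meta_temporal", "whole_cerebellum"),
    stringsAsFactors = FALSE))
}

## Deterministic little long table: nsub subjects x nvis visits x regions.
longTable <- function(nsub = 2, nvis = 3, regions = c("a", "b", "c", "d"),
                      groups = NULL) {
  if (is.null(groups))
    groups <- rep(c("CU", "CI"), length.out = nsub)
  rows <- expand.grid(subject_id = sprintf("s%02d", seq_len(nsub)),
                      scan_time = seq(0, by = 1.2, length.out = nvis),
                      region_id = regions, stringsAsFactors = FALSE)
  rows$group <- groups[as.integer(sub("s", "", rows$subject_id))]
  rows$suv <- 1 + 0.1 * as.integer(factor(rows$region_id)) +
    0.01 * rows$scan_time
  rows$volume <- 1000 + 100 * as.integer(factor(rows$region_id))
  rows
}

tinyDataset <- function(...) regionalDatasetFromLong(longTable(...),
                                                     quiet = TRUE)

## Build a RegionalDataset directly from matrices (regions x scans).
matrixDataset <- function(suv, volume = NULL, subjectId, group, scanTime) {
  if (is.null(volume))
    volume <- matrix(1000, nrow(suv), ncol(suv),
                     dimnames = dimnames(suv))
  RegionalDataset(suv = suv, volume = volume, subjectId = subjectId,
                  group = group, scanTime = scanTime)
}

## EvaluationResult-style fitness comparison tolerance for the fast
## evaluator vs the reference path.
FAST_EVAL_TOL <- 1e-4
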