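## Composite signals, the composite-value ratio (CVR), the 0/1/2 genome and
## its constraint handling.

#' Searchable units implied by metadata and laterality
#'
#' In lateral mode every region is its own unit. In bilateral mode each
#' left/right pair collapses to one unit named by its pair label, and
#' midline regions remain units of their own. A unit is numerator-eligible
#' unless any of its regions is a reference candidate, and
#' denominator-eligible unless any of its regions lies in Braak stages 1--3
#' (the two biological search priors).
#'
#' @param meta a [RegionMetadata-class].
#' @param laterality \code{"bilateral"} or \code{"lateral"}.
#' @return data.frame with columns \code{unit}, \code{regions} (list),
#'   \code{numerator_ok}, \code{denominator_ok}.
#' @export
searchUnits <- function(meta, laterality = c("bilateral", "lateral")) {
  laterality <- match.arg(laterality)
  tb <- metadataTable(meta)
  if (laterality == "lateral") {
    units <- tb$region_id
    regions <- as.list(tb$region_id)
  } else {
    paired <- !is.na(tb$bilateral_pair_id)
    units <- c(unique(tb$bilateral_pair_id[paired]), tb$region_id[!paired])
    regions <- lapply(units, function(u) {
      hit <- tb$region_id[paired & tb$bilateral_pair_id == u]
      if (length(hit)) hit else u
    })
  }
  braak13 <- function(rs) any(tb[rs, "braak_stage"] %in% 1:3)
  refc <- function(rs) any(tb[rs, "reference_candidate"])
  out <- data.frame(unit = units, stringsAsFactors = FALSE)
  out$regions <- regions
  out$numerator_ok <- !vapply(regions, refc, logical(1))
  out$denominator_ok <- !vapply(regions, braak13, logical(1))
  rownames(out) <- out$unit
  out
}

#' Collapse left/right pairs to bilateral units
#'
#' Each pair becomes one unit with \code{volume = vol_L + vol_R} and
#' \code{suv = (suv_L * vol_L + suv_R * vol_R) / (vol_L + vol_R)} -- the
#' volume-weighted hemispheric average, which preserves the identity with
#' whole-structure uptake. Midline regions pass through unchanged.
#'
#' @param dataset a [RegionalDataset-class].
#' @param meta a [RegionMetadata-class] supplying pair labels.
#' @return A [RegionalDataset-class] whose rows are bilateral units plus
#'   midline regions.
#' @export
makeBilateral <- function(dataset, meta) {
  tb <- metadataTable(meta)
  s <- suv(dataset); v <- volumes(dataset)
  present <- rownames(s)
  tb <- tb[tb$region_id %in% present, , drop = FALSE]
  paired <- !is.na(tb$bilateral_pair_id)
  pairs <- unique(tb$bilateral_pair_id[paired])
  for (p in pairs) {
    members <- tb$region_id[paired & tb$bilateral_pair_id == p]
    if (length(members) != 2)
      stop("pair '", p, "': hemisphere missing from dataset (have: ",
           paste(members, collapse = ", "), ")")
  }
  midline <- tb$region_id[!paired]
  units <- c(pairs, midline)
  ns <- matrix(NA_real_, length(units), ncol(s),
               dimnames = list(units, colnames(s)))
  nv <- ns
  for (p in pairs) {
    members <- tb$region_id[paired & tb$bilateral_pair_id == p]
    vv <- v[members[1], ] + v[members[2], ]
    ns[p, ] <- (s[members[1], ] * v[members[1], ] +
                  s[members[2], ] * v[members[2], ]) / vv
    nv[p, ] <- vv
  }
  if (length(midline)) {
    ns[midline, ] <- s[midline, , drop = FALSE]
    nv[midline, ] <- v[midline, , drop = FALSE]
  }
  cd <- SummarizedExperiment::colData(dataset)
  RegionalDataset(suv = ns, volume = nv, subjectId = cd$subject_id,
                  group = cd$group, scanTime = cd$scan_time)
}

#' Composite signal of a region set at one scan
#'
#' \code{mean_suv}: unweighted mean of the units' SUVs.
#' \code{volume_weighted}: sum(suv * vol) / sum(vol).
#'
#' @param suv numeric vector of unit SUVs.
#' @param volume numeric vector of unit volumes (ignored for
#'   \code{mean_suv}).
#' @param method composition method.
#' @return positive scalar.
#' @examples
#' compositeValue(c(1.5, 2.5), method = "mean_suv")        # 2
#' compositeValue(c(1.2, 1.8), c(100, 300), "volume_weighted")  # 1.65
#' @export
compositeValue <- function(suv, volume = NULL,
                           method = c("mean_suv", "volume_weighted")) {
  method <- match.arg(method)
  if (!length(suv)) stop("empty region set")
  if (anyNA(suv)) stop("missing region value")
  if (method == "mean_suv") return(mean(suv))
  if (is.null(volume) || length(volume) != length(suv))
    stop("volume_weighted composition requires matching volumes")
  sum(suv * volume) / sum(volume)
}

.compositeMatrixValue <- function(s, v, rows, method) {
  ss <- s[rows, , drop = FALSE]
  if (method == "mean_suv") return(colMeans(ss))
  vv <- v[rows, , drop = FALSE]
  colSums(ss * vv) / colSums(vv)
}

#' Map region ids to search units
#'
#' @param regions character vector of region ids.
#' @param meta a [RegionMetadata-class].
#' @return character vector of unit ids (pair labels for paired regions),
#'   deduplicated.
#' @export
regionsToUnits <- function(regions, meta) {
  tb <- metadataTable(meta)
  unknown <- setdiff(regions, tb$region_id)
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  u <- ifelse(is.na(tb[regions, "bilateral_pair_id"]), regions,
              tb[regions, "bilateral_pair_id"])
  unique(u)
}

#' Compute the composite-value-ratio biomarker series
#'
#' Per scan, \code{value = composite(numerator) / composite(denominator)}
#' and \code{log_value = log(value)}. With bilateral laterality the dataset
#' is first collapsed with [makeBilateral()] and the spec's region ids are
#' mapped to their bilateral units, so that each unit contributes one term
#' to a \code{mean_suv} composite (one unit, one vote). Any per-scan
#' multiplicative rescaling of the SUVs cancels exactly in the ratio.
#'
#' @param dataset a [RegionalDataset-class].
#' @param spec a [RatioSpec-class].
#' @param config a [CompositeConfig-class].
#' @param meta a [RegionMetadata-class]; required when
#'   \code{laterality == "bilateral"}.
#' @return data.frame: \code{subject_id}, \code{group}, \code{scan_time},
#'   \code{value}, \code{log_value}, one row per scan.
#' @export
computeCVR <- function(dataset, spec, config = CompositeConfig(),
                       meta = NULL) {
  validObject(spec)
  num <- spec@numerator; den <- spec@denominator
  if (config@laterality == "bilateral") {
    if (is.null(meta))
      stop("bilateral CVR computation requires region metadata")
    dataset <- makeBilateral(dataset, meta)
    num <- regionsToUnits(num, meta)
    den <- regionsToUnits(den, meta)
    if (length(intersect(num, den)))
      stop("numerator and denominator share a bilateral unit: ",
           paste(intersect(num, den), collapse = ", "))
  }
  s <- suv(dataset); v <- volumes(dataset)
  missing <- setdiff(c(num, den), rownames(s))
  if (length(missing))
    stop("region(s) absent from dataset: ", paste(missing, collapse = ", "))
  numerator <- .compositeMatrixValue(s, v, num, config@method)
  denominator <- .compositeMatrixValue(s, v, den, config@method)
  if (any(denominator <= 0))
    stop("non-positive denominator composite (corrupt input?)")
  cd <- SummarizedExperiment::colData(dataset)
  data.frame(subject_id = cd$subject_id, group = as.character(cd$group),
             scan_time = cd$scan_time, value = numerator / denominator,
             log_value = log(numerator) - log(denominator),
             stringsAsFactors = FALSE, row.names = NULL)
}

.genomeUnits <- function(genome, units) {
  missing <- setdiff(names(genome@assignment), units$unit)
  if (length(missing))
    stop("genome unit(s) unknown to metadata: ",
         paste(missing, collapse = ", "))
  units[names(genome@assignment), , drop = FALSE]
}

#' Check a genome against the search constraints
#'
#' @param genome a [Genome-class].
#' @param meta a [RegionMetadata-class].
#' @param laterality unit mode, as in [searchUnits()].
#' @param units precomputed [searchUnits()] table (performance hook for
#'   search loops).
#' @return \code{TRUE}, or a character vector of violation messages.
#' @export
validGenome <- function(genome, meta, laterality = "bilateral",
                        units = searchUnits(meta, laterality)) {
  ui <- .genomeUnits(genome, units)
  a <- genome@assignment
  msg <- character()
  if (!any(a == 0)) msg <- c(msg, "empty numerator")
  if (!any(a == 2)) msg <- c(msg, "empty denominator")
  bad_den <- names(a)[a == 2 & !ui$denominator_ok]
  if (length(bad_den))
    msg <- c(msg, paste("Braak 1-3 unit(s) in denominator:",
                        paste(bad_den, collapse = ", ")))
  bad_num <- names(a)[a == 0 & !ui$numerator_ok]
  if (length(bad_num))
    msg <- c(msg, paste("reference-candidate unit(s) in numerator:",
                        paste(bad_num, collapse = ", ")))
  f <- genome@frozen
  if (length(f)) {
    if (any(a[names(f)] != f))
      msg <- c(msg, "frozen unit(s) not at pinned value")
    # a pinned side is fixed exactly: no unfrozen unit may join it
    for (side in c(0L, 2L)) {
      if (any(f == side)) {
        extra <- setdiff(names(a)[a == side], names(f))
        if (length(extra))
          msg <- c(msg, paste0("side ", side, " is pinned; unfrozen ",
                               "unit(s) assigned to it: ",
                               paste(extra, collapse = ", ")))
      }
    }
  }
  if (length(msg)) msg else TRUE
}

#' Decode a genome into a ratio specification
#'
#' Units valued 0 contribute their regions to the numerator, units valued 2
#' to the denominator; bilateral units expand to both hemispheres. Invalid
#' genomes raise an error (repair is the caller's job).
#'
#' @inheritParams validGenome
#' @return A [RatioSpec-class].
#' @export
decodeGenome <- function(genome, meta, laterality = "bilateral",
                         units = searchUnits(meta, laterality)) {
  ok <- validGenome(genome, meta, laterality, units)
  if (!isTRUE(ok)) stop("invalid genome: ", paste(ok, collapse = "; "))
  ui <- .genomeUnits(genome, units)
  a <- genome@assignment
  RatioSpec(numerator = unlist(ui$regions[a == 0], use.names = FALSE),
            denominator = unlist(ui$regions[a == 2], use.names = FALSE))
}

#' Repair a genome to satisfy all search constraints
#'
#' Braak 1--3 units valued 2 are reset to 1; reference-candidate units
#' valued 0 are reset to 1; frozen units are restored to their pinned
#' values (and a side containing a pinned unit is fixed exactly: unfrozen
#' units are evicted from it); if either side is then empty, one uniformly
#' chosen eligible (unfrozen) unit is assigned to it. Uses R's global RNG
#' stream.
#'
#' @inheritParams validGenome
#' @return A valid [Genome-class].
#' @export
repairGenome <- function(genome, meta, laterality = "bilateral",
                         units = searchUnits(meta, laterality)) {
  ui <- .genomeUnits(genome, units)
  a <- genome@assignment
  f <- genome@frozen
  a[a == 2 & !ui$denominator_ok] <- 1L
  a[a == 0 & !ui$numerator_ok] <- 1L
  if (length(f)) {
    a[names(f)] <- f
    for (side in c(0L, 2L))
      if (any(f == side))
        a[setdiff(names(a)[a == side], names(f))] <- 1L
  }
  free <- setdiff(names(a), names(f))
  for (side in c(0L, 2L)) {
    if (any(a == side)) next
    ok <- if (side == 0L) ui$numerator_ok else ui$denominator_ok
    eligible <- intersect(names(a)[ok], free)
    # prefer units not already committed to the other side
    other <- if (side == 0L) 2L else 0L
    pool <- eligible[a[eligible] != other]
    if (!length(pool)) pool <- eligible
    if (!length(pool))
      stop("no eligible unit available for ",
           if (side == 0L) "numerator" else "denominator",
           "; infeasible configuration")
    pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
    a[pick] <- side
  }
  out <- Genome(a, frozen = f)
  ok <- validGenome(out, meta, laterality, units)
  if (!isTRUE(ok))
    stop("repair failed: ", paste(ok, collapse = "; "))
  out
}

#' Serialize a discovered biomarker to JSON
#'
#' The exchange format carries the region sets and the composition settings:
#' \code{\{numerator:[...], denominator:[...], method, laterality\}}.
#'
#' @param spec a [RatioSpec-class].
#' @param config a [CompositeConfig-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBiomarker <- function(spec, config, path) {
  jsonlite::write_json(
    list(numerator = spec@numerator, denominator = spec@denominator,
         method = jsonlite::unbox(config@method),
         laterality = jsonlite::unbox(config@laterality)),
    path, pretty = TRUE)
  invisible(path)
}

#' Read a biomarker JSON written by [writeBiomarker()]
#'
#' @param path JSON path.
#' @return list with elements \code{spec} ([RatioSpec-class]) and
#'   \code{config} ([CompositeConfig-class]).
#' @export
readBiomarker <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(spec = RatioSpec(x$numerator, x$denominator),
       config = CompositeConfig(x$method, x$laterality))
}
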