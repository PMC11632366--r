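## Reading, validation and reshaping of longitudinal regional tables.
## No science here, only contracts.

#' Build a RegionalDataset from a long data.frame
#'
#' Applies the loading contract shared by the CSV readers: rows with missing
#' or non-positive suv/volume are dropped (logged), scans not carrying the
#' full region set (the union over all rows) are dropped (logged), and
#' subjects left with fewer than two distinct scan times, or with an
#' inconsistent group label, are dropped (logged).
#'
#' @param df data.frame with columns \code{subject_id}, \code{group},
#'   \code{scan_time}, \code{region_id}, \code{suv}, \code{volume}.
#' @param quiet suppress the exclusion log messages.
#' @return A [RegionalDataset-class].
#' @export
regionalDatasetFromLong <- function(df, quiet = FALSE) {
  need <- c("subject_id", "group", "scan_time", "region_id", "suv", "volume")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$subject_id <- as.character(df$subject_id)
  df$region_id <- as.character(df$region_id)
  df$scan_time <- as.numeric(df$scan_time)
  df$suv <- as.numeric(df$suv)
  df$volume <- as.numeric(df$volume)
  note <- function(...) if (!quiet) message("regionalDataset: ", ...)

  bad <- !(is.finite(df$suv) & is.finite(df$volume) &
             df$suv > 0 & df$volume > 0) | is.na(df$scan_time)
  if (any(bad)) {
    note(sum(bad), " row(s) dropped (missing or non-positive suv/volume)")
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("empty dataset after filtering")
  if (!all(df$group %in% c("CU", "CI")))
    stop("group must be 'CU' or 'CI'; found: ",
         paste(setdiff(unique(df$group), c("CU", "CI")), collapse = ", "))

  regions <- sort(unique(df$region_id))
  key <- paste(df$subject_id, df$scan_time, sep = "@")
  if (anyDuplicated(paste(key, df$region_id)))
    stop("duplicated (subject, scan_time, region) rows")
  per_scan <- table(key)
  incomplete <- names(per_scan)[per_scan < length(regions)]
  if (length(incomplete)) {
    note(length(incomplete),
         " scan(s) dropped (incomplete region coverage): ",
         paste(head(incomplete, 5), collapse = ", "),
         if (length(incomplete) > 5) " ...")
    df <- df[!key %in% incomplete, , drop = FALSE]
    key <- paste(df$subject_id, df$scan_time, sep = "@")
  }
  if (!nrow(df)) stop("empty dataset after filtering")

  scans <- unique(df[c("subject_id", "group", "scan_time")])
  nvis <- tapply(scans$scan_time, scans$subject_id,
                 function(t) length(unique(t)))
  ngrp <- tapply(scans$group, scans$subject_id,
                 function(g) length(unique(g)))
  drop_subj <- union(names(nvis)[nvis < 2], names(ngrp)[ngrp > 1])
  if (length(drop_subj)) {
    for (s in drop_subj)
      note("subject '", s, "' dropped (",
           if (s %in% names(ngrp)[ngrp > 1]) "inconsistent group label"
           else "fewer than 2 distinct scan times", ")")
    df <- df[!df$subject_id %in% drop_subj, , drop = FALSE]
  }
  if (!nrow(df)) stop("empty dataset after filtering")

  scans <- unique(df[c("subject_id", "group", "scan_time")])
  scans <- scans[order(scans$subject_id, scans$scan_time), ]
  skey <- paste(scans$subject_id, scans$scan_time, sep = "@")
  mk <- function(col) {
    m <- matrix(NA_real_, length(regions), nrow(scans),
                dimnames = list(regions, skey))
    m[cbind(match(df$region_id, regions),
            match(paste(df$subject_id, df$scan_time, sep = "@"), skey))] <-
      df[[col]]
    m
  }
  RegionalDataset(suv = mk("suv"), volume = mk("volume"),
                  subjectId = scans$subject_id, group = scans$group,
                  scanTime = scans$scan_time)
}

#' Load a longitudinal regional feature table
#'
#' Long format expects columns \code{subject_id, group, scan_time,
#' region_id, suv, volume}. Wide format expects \code{subject_id, group,
#' scan_time} plus a \code{suv_<region>} / \code{vol_<region>} column pair
#' per region, and is melted to long before applying the same contract.
#'
#' @param path CSV file (UTF-8, header row).
#' @param format \code{"long"} or \code{"wide"}.
#' @param quiet suppress exclusion log messages.
#' @return A [RegionalDataset-class].
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' df <- expand.grid(subject_id = c("s1", "s2"), scan_time = c(0, 1, 2),
#'                   region_id = c("a", "b", "c", "d"))
#' df$group <- "CU"; df$suv <- 1.2; df$volume <- 1000
#' write.csv(df, tmp, row.names = FALSE)
#' d <- loadRegionalTable(tmp)
#' @export
loadRegionalTable <- function(path, format = c("long", "wide"),
                              quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "wide") df <- .wideToLong(df)
  regionalDatasetFromLong(df, quiet = quiet)
}

.wideToLong <- function(df) {
  idcols <- c("subject_id", "group", "scan_time")
  miss <- setdiff(idcols, colnames(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  suv_cols <- grep("^suv_", colnames(df), value = TRUE)
  vol_cols <- grep("^vol_", colnames(df), value = TRUE)
  regions <- intersect(sub("^suv_", "", suv_cols), sub("^vol_", "", vol_cols))
  if (!length(regions))
    stop("missing required column(s): no suv_<region>/vol_<region> pairs")
  long <- do.call(rbind, lapply(regions, function(r) {
    data.frame(df[idcols], region_id = r, suv = df[[paste0("suv_", r)]],
               volume = df[[paste0("vol_", r)]], stringsAsFactors = FALSE)
  }))
  long
}

#' Convert a RegionalDataset to a canonical long data.frame
#'
#' Rows sorted by subject, scan time and region id, so matched content
#' yields byte-identical record sets regardless of input format.
#'
#' @param dataset a [RegionalDataset-class].
#' @return data.frame with the long-schema columns.
#' @export
asLongDataFrame <- function(dataset) {
  s <- suv(dataset); v <- volumes(dataset)
  cd <- SummarizedExperiment::colData(dataset)
  df <- data.frame(
    subject_id = rep(cd$subject_id, each = nrow(s)),
    group = rep(as.character(cd$group), each = nrow(s)),
    scan_time = rep(cd$scan_time, each = nrow(s)),
    region_id = rep(rownames(s), ncol(s)),
    suv = as.vector(s), volume = as.vector(v),
    stringsAsFactors = FALSE)
  df <- df[order(df$subject_id, df$scan_time, df$region_id), ]
  rownames(df) <- NULL
  df
}

#' Write a RegionalDataset as canonical long CSV
#'
#' @param dataset a [RegionalDataset-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRegionalTable <- function(dataset, path) {
  write.csv(asLongDataFrame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a region-metadata table
#'
#' CSV with one row per region and columns \code{region_id, hemisphere,
#' bilateral_pair_id, braak_stage, reference_candidate, composites}
#' (\code{";"}-separated composite labels; \code{none} for empty fields).
#' Unknown composite labels are retained: the composite registry is
#' user-extensible. Asymmetric bilateral pairing or duplicate region ids are
#' fatal.
#'
#' @param path CSV file.
#' @return A [RegionMetadata-class].
#' @export
loadRegionMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region_id", "hemisphere", "bilateral_pair_id", "braak_stage",
            "reference_candidate", "composites")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  RegionMetadata(df)
}

#' Default Desikan-Killiany-style region metadata
#'
#' The packaged atlas-level metadata: 36 bilateral cortical/limbic region
#' pairs annotated with Braak-stage membership and named-composite labels,
#' plus five midline aggregate reference structures (whole cerebellum,
#' cerebellum cortex, inferior cerebellar grey matter, brainstem, eroded
#' subcortical white matter). Exact parity with any specific cohort export
#' is not claimed; the table is editable and user-extensible.
#'
#' @return A [RegionMetadata-class].
#' @export
defaultRegionMetadata <- function() {
  loadRegionMetadata(system.file("extdata", "dk_regions.csv",
                                 package = "CVRseek", mustWork = TRUE))
}

#' Write region metadata as CSV
#'
#' Inverse of [loadRegionMetadata()]: composites are joined with
#' \code{";"}, absent fields written as \code{"none"}.
#'
#' @param meta a [RegionMetadata-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRegionMetadata <- function(meta, path) {
  tb <- metadataTable(meta)
  tb$composites <- vapply(tb$composites, function(x)
    if (length(x)) paste(x, collapse = ";") else "none", "")
  tb$bilateral_pair_id[is.na(tb$bilateral_pair_id)] <- "none"
  tb$braak_stage <- ifelse(is.na(tb$braak_stage), "none",
                           as.character(tb$braak_stage))
  tb$reference_candidate <- ifelse(tb$reference_candidate, "true", "false")
  write.csv(tb, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Composite labels defined by a metadata table
#'
#' Union of the labels in the \code{composites} column and the implicit
#' \code{braak1..braak6} labels derived from \code{braak_stage}.
#'
#' @param meta a [RegionMetadata-class].
#' @return character vector of labels.
#' @export
compositeLabels <- function(meta) {
  tb <- metadataTable(meta)
  labs <- unique(unlist(tb$composites))
  braak <- paste0("braak", sort(unique(tb$braak_stage[!is.na(tb$braak_stage)])))
  sort(unique(c(labs, braak)))
}

#' Resolve the member regions of a named composite
#'
#' \code{braak1..braak6} resolve through the \code{braak_stage} column; all
#' other labels through \code{composites} membership.
#'
#' @param meta a [RegionMetadata-class].
#' @param label composite label.
#' @return character vector of region ids (possibly empty).
#' @export
compositeMembers <- function(meta, label) {
  tb <- metadataTable(meta)
  if (grepl("^braak[1-6]$", label)) {
    stage <- as.integer(sub("braak", "", label))
    return(tb$region_id[!is.na(tb$braak_stage) & tb$braak_stage == stage])
  }
  tb$region_id[vapply(tb$composites, function(x) label %in% x, logical(1))]
}

#' Cross-validate a dataset against region metadata
#'
#' Produces a validation report: dataset regions absent from the metadata
#' are fatal (constraints cannot be applied); metadata regions absent from
#' the dataset are warnings; named composites with incomplete dataset
#' coverage are warnings (those composites are unusable as baselines).
#'
#' @param dataset a [RegionalDataset-class].
#' @param meta a [RegionMetadata-class].
#' @return A data.frame of class \code{cvr_validation} with columns
#'   \code{level} (\code{fatal}/\code{warning}), \code{type}, \code{item},
#'   \code{detail}. Zero rows means a clean report.
#' @export
crossValidate <- function(dataset, meta) {
  dreg <- regionIds(dataset)
  mreg <- regionIds(meta)
  rep_ <- list()
  add <- function(level, type, item, detail)
    rep_[[length(rep_) + 1]] <<- data.frame(
      level = level, type = type, item = item, detail = detail,
      stringsAsFactors = FALSE)
  for (r in setdiff(dreg, mreg))
    add("fatal", "dataset_region_missing_from_metadata", r,
        "no metadata row; constraints cannot be applied")
  for (r in setdiff(mreg, dreg))
    add("warning", "metadata_region_missing_from_dataset", r,
        "region annotated but not observed")
  for (lab in compositeLabels(meta)) {
    members <- compositeMembers(meta, lab)
    missing <- setdiff(members, dreg)
    if (length(members) && length(missing))
      add("warning", "composite_incomplete", lab,
          paste0("missing members: ", paste(missing, collapse = ", "),
                 "; composite unusable"))
  }
  out <- if (length(rep_)) do.call(rbind, rep_) else
    data.frame(level = character(), type = character(), item = character(),
               detail = character(), stringsAsFactors = FALSE)
  class(out) <- c("cvr_validation", class(out))
  out
}

#' Abort if a validation report carries fatal entries
#'
#' @param report output of [crossValidate()].
#' @return the report, invisibly, when clean of fatal entries.
#' @export
stopOnFatal <- function(report) {
  fatal <- report[report$level == "fatal", , drop = FALSE]
  if (nrow(fatal))
    stop("fatal validation entries: ",
         paste(unique(fatal$item), collapse = ", "))
  invisible(report)
}

#' Write a validation report as JSON
#'
#' @param report output of [crossValidate()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  jsonlite::write_json(as.data.frame(unclass(report)), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
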