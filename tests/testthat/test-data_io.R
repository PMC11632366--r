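test_that("long reader builds the expected record set and validates it", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(longTable(nsub = 2, nvis = 3), tmp, row.names = FALSE)
  d <- loadRegionalTable(tmp, quiet = TRUE)
  expect_s4_class(d, "RegionalDataset")
  expect_equal(nrow(asLongDataFrame(d)), 2 * 3 * 4)
  expect_equal(sort(regionIds(d)), c("a", "b", "c", "d"))
  expect_equal(length(unique(subjectIds(d))), 2)
  expect_true(all(suv(d) > 0), all(volumes(d) > 0))
})

test_that("subjects violating the visit and group invariants are dropped with a log", {
  df <- longTable(nsub = 3, nvis = 3)
  df <- df[!(df$subject_id == "s03" & df$scan_time > 0), ]  # 1 visit left
  expect_message(d <- regionalDatasetFromLong(df), "s03")
  expect_false("s03" %in% subjectIds(d))

  df2 <- longTable(nsub = 2, nvis = 2)
  df2$group[df2$subject_id == "s02" & df2$scan_time == 0] <- "CU"
  expect_message(d2 <- regionalDatasetFromLong(df2), "inconsistent group")
  expect_false("s02" %in% subjectIds(d2))
})

test_that("rows with missing or non-positive measurements are dropped, and emptiness is fatal", {
  df <- longTable(nsub = 3, nvis = 2)
  df$suv[df$subject_id == "s01" & df$scan_time == 0 &
           df$region_id == "a"] <- NA
  expect_message(d <- regionalDatasetFromLong(df), "dropped")
  # that scan lost a region, so the whole scan goes; s01 keeps 1 visit
  expect_false("s01" %in% subjectIds(d))
  df$suv <- NA
  expect_error(regionalDatasetFromLong(df, quiet = TRUE), "empty dataset")
  expect_error(regionalDatasetFromLong(longTable()[0, ], quiet = TRUE),
               "empty|missing")
})

test_that("missing required columns are named in the error", {
  df <- longTable()
  df$volume <- NULL
  expect_error(regionalDatasetFromLong(df), "volume")
})

test_that("wide and long readers are equivalent on matched content", {
  long <- longTable(nsub = 2, nvis = 2, regions = c("hippocampus_L",
                                                    "hippocampus_R"))
  wide <- reshape(long, direction = "wide",
                  idvar = c("subject_id", "group", "scan_time"),
                  timevar = "region_id")
  colnames(wide) <- sub("^suv\\.", "suv_", colnames(wide))
  colnames(wide) <- sub("^volume\\.", "vol_", colnames(wide))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(long, f1, row.names = FALSE)
  write.csv(wide, f2, row.names = FALSE)
  d1 <- loadRegionalTable(f1, "long", quiet = TRUE)
  d2 <- loadRegionalTable(f2, "wide", quiet = TRUE)
  expect_equal(asLongDataFrame(d1), asLongDataFrame(d2))
})

test_that("loading is idempotent through the canonical writer", {
  d <- tinyDataset(nsub = 3, nvis = 3)
  tmp <- tempfile(fileext = ".csv")
  writeRegionalTable(d, tmp)
  d2 <- loadRegionalTable(tmp, quiet = TRUE)
  expect_equal(asLongDataFrame(d), asLongDataFrame(d2))
})

test_that("metadata loads composites and rejects structural errors", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c(
    "region_id,hemisphere,bilateral_pair_id,braak_stage,reference_candidate,composites",
    "amygdala_L,left,amygdala,none,false,meta_temporal",
    "amygdala_R,right,amygdala,none,false,meta_temporal;custom_label",
    "brainstem,midline,none,none,true,brainstem"), tmp)
  m <- loadRegionMetadata(tmp)
  expect_true("amygdala_L" %in% compositeMembers(m, "meta_temporal"))
  # unknown labels are retained (user-extensible registry)
  expect_true("custom_label" %in% compositeLabels(m))

  bad <- metadataTable(m)
  bad$composites <- vapply(bad$composites, paste, "", collapse = ";")
  bad$bilateral_pair_id[2] <- "elsewhere"
  expect_error(RegionMetadata(bad), "amygdala")
  dup <- metadataTable(m)
  dup$composites <- vapply(dup$composites, paste, "", collapse = ";")
  dup <- rbind(dup, dup[1, ])
  expect_error(RegionMetadata(dup), "duplicate")
})

test_that("cross-validation reports fatal and warning entries by contract", {
  d <- tinyDataset()
  m <- tinyMeta()
  rep0 <- crossValidate(d, m)
  expect_equal(nrow(rep0), 0)
  expect_silent(stopOnFatal(rep0))

  # dataset region unknown to metadata -> fatal
  tb <- metadataTable(m)
  tb$composites <- vapply(tb$composites, paste, "", collapse = ";")
  m2 <- RegionMetadata(tb[tb$region_id != "a", ])
  rep1 <- crossValidate(d, m2)
  expect_true(any(rep1$level == "fatal" & rep1$item == "a"))
  expect_error(stopOnFatal(rep1), "a")

  # metadata region/composite member missing from dataset -> warnings
  d2 <- tinyDataset(regions = c("b", "c", "d"))
  rep2 <- crossValidate(d2, m)
  expect_true(any(rep2$level == "warning" &
                    rep2$type == "metadata_region_missing_from_dataset"))
  expect_true(any(rep2$level == "warning" &
                    rep2$type == "composite_incomplete" &
                    rep2$item == "meta_temporal"))
  expect_false(any(rep2$level == "fatal"))

  tmp <- tempfile(fileext = ".json")
  writeValidationReport(rep2, tmp)
  expect_true(file.exists(tmp))
})

test_that("shipped default metadata is valid and complete for the baseline grid", {
  m <- defaultRegionMetadata()
  expect_s4_class(m, "RegionMetadata")
  labs <- compositeLabels(m)
  expect_true(all(c(paste0("braak", 1:6), "meta_temporal",
                    "mesial_temporal", "temporoparietal", "rest",
                    "composite_reference") %in% labs))
  # the published meta-temporal membership, both hemispheres
  mt <- compositeMembers(m, "meta_temporal")
  expect_setequal(mt, paste0(rep(c("entorhinal", "parahippocampal",
                                   "amygdala", "inferior_temporal",
                                   "fusiform", "middle_temporal"),
                                 each = 2), c("_L", "_R")))
  # the published composite reference constituents
  expect_setequal(compositeMembers(m, "composite_reference"),
                  c("eroded_subcortical_wm", "whole_cerebellum",
                    "brainstem"))
})
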