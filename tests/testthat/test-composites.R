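test_that("bilateral collapse is the volume-weighted hemispheric average", {
  m <- pairMeta()
  suv <- matrix(c(1.0, 2.0, 1.1,
                  1.2, 1.2, 1.1,
                  1.0, 3.0, 1.1), nrow = 3,
                dimnames = list(c("amygdala_L", "amygdala_R",
                                  "whole_cerebellum"), NULL))
  vol <- matrix(c(100, 100, 500,
                  70, 90, 500,
                  100, 300, 500), nrow = 3,
                dimnames = dimnames(suv))
  d <- matrixDataset(suv, vol, subjectId = c("s1", "s1", "s1"),
                     group = "CU", scanTime = c(0, 1, 2))
  b <- makeBilateral(d, m)
  expect_equal(unname(suv(b)["amygdala", ]), c(1.5, 1.2, 2.5))
  expect_equal(unname(volumes(b)["amygdala", ]), c(200, 160, 400))
  # midline passthrough
  expect_equal(unname(suv(b)["whole_cerebellum", ]), rep(1.1, 3))

  # one hemisphere missing -> error naming the pair
  expect_error(makeBilateral(d[c("amygdala_L", "whole_cerebellum"), ], m),
               "amygdala")
})

test_that("composite values follow the two composition rules", {
  expect_equal(compositeValue(c(1.5, 2.5), method = "mean_suv"), 2.0)
  expect_equal(compositeValue(c(1.2, 1.8), c(100, 300), "volume_weighted"),
               1.65)
  # single region: both methods return the region's value
  expect_equal(compositeValue(3.3, 999, "mean_suv"), 3.3)
  expect_equal(compositeValue(3.3, 999, "volume_weighted"), 3.3)
  expect_error(compositeValue(numeric(0)), "empty")
  expect_error(compositeValue(c(1, NA)), "missing")
})

test_that("CVR is the composite ratio and cancels per-scan rescaling", {
  suv <- matrix(c(2.0, 2.0, 1.0,
                  3.0, 1.0, 2.0), nrow = 3,
                dimnames = list(c("a", "b", "d"), NULL))
  d <- matrixDataset(suv, subjectId = c("s1", "s1"), group = "CI",
                     scanTime = c(0, 1))
  spec <- RatioSpec(c("a", "b"), "d")
  s <- computeCVR(d, spec, CompositeConfig("mean_suv", "lateral"))
  expect_equal(s$value, c(mean(c(2, 2)) / 1, mean(c(3, 1)) / 2))
  expect_equal(s$log_value, log(s$value))

  # per-scan multiplicative rescaling (e.g. scanner/dose factor) cancels
  set.seed(1)
  d2 <- tinyDataset(nsub = 4, nvis = 3)
  fac <- runif(ncol(d2), 0.3, 3.7)
  suv2 <- suv(d2) * rep(fac, each = nrow(d2))
  d3 <- matrixDataset(suv2, volumes(d2), subjectIds(d2),
                      groups(d2), scanTimes(d2))
  for (method in c("mean_suv", "volume_weighted")) {
    cfg <- CompositeConfig(method, "lateral")
    s1 <- computeCVR(d2, RatioSpec(c("a", "b"), c("c", "d")), cfg)
    s2 <- computeCVR(d3, RatioSpec(c("a", "b"), c("c", "d")), cfg)
    expect_equal(s1$value, s2$value, tolerance = 1e-12)
  }

  # SUV inputs and SUVR inputs (all regions divided by a per-scan
  # reference) give identical series
  ref <- suv(d2)["d", ]
  suvr <- suv(d2) / rep(ref, each = nrow(d2))
  d4 <- matrixDataset(suvr, volumes(d2), subjectIds(d2), groups(d2),
                      scanTimes(d2))
  s5 <- computeCVR(d4, RatioSpec(c("a", "b"), "c"),
                   CompositeConfig("mean_suv", "lateral"))
  s6 <- computeCVR(d2, RatioSpec(c("a", "b"), "c"),
                   CompositeConfig("mean_suv", "lateral"))
  expect_equal(s5$value, s6$value, tolerance = 1e-12)
})

test_that("bilateral-then-composite equals the volume-weighted union composite", {
  m <- pairMeta()
  set.seed(2)
  suv <- matrix(runif(6, 1, 3), nrow = 3,
                dimnames = list(c("amygdala_L", "amygdala_R",
                                  "whole_cerebellum"), NULL))
  vol <- matrix(runif(6, 500, 2000), nrow = 3, dimnames = dimnames(suv))
  d <- matrixDataset(suv, vol, subjectId = c("s1", "s1"), group = "CU",
                     scanTime = c(0, 1.3))
  spec <- RatioSpec(c("amygdala_L", "amygdala_R"), "whole_cerebellum")
  bilat <- computeCVR(d, spec, CompositeConfig("volume_weighted",
                                               "bilateral"), m)
  lat <- computeCVR(d, spec, CompositeConfig("volume_weighted", "lateral"))
  expect_equal(bilat$value, lat$value, tolerance = 1e-12)
})

test_that("genomes decode by the 0/1/2 convention with bilateral expansion", {
  m <- tinyMeta()
  g <- Genome(c(a = 0, b = 1, c = 1, d = 2))
  spec <- decodeGenome(g, m, "lateral")
  expect_equal(spec@numerator, "a")
  expect_equal(spec@denominator, "d")

  mp <- pairMeta()
  g2 <- Genome(c(amygdala = 0, whole_cerebellum = 2))
  spec2 <- decodeGenome(g2, mp, "bilateral")
  expect_setequal(spec2@numerator, c("amygdala_L", "amygdala_R"))

  expect_error(decodeGenome(Genome(c(a = 1, b = 1, c = 1, d = 1)), m,
                            "lateral"), "empty")
  # constraint violations are errors at decode (repair is the caller's job)
  expect_error(decodeGenome(Genome(c(a = 0, b = 1, c = 2, d = 2)), m,
                            "lateral"), "Braak")
  expect_error(decodeGenome(Genome(c(a = 1, b = 2, c = 1, d = 0)), m,
                            "lateral"), "reference")
})

test_that("repair enforces the priors and never leaves a side empty", {
  m <- tinyMeta()
  # Braak unit in the denominator is evicted
  g <- repairGenome(Genome(c(a = 0, b = 1, c = 2, d = 2)), m, "lateral")
  expect_equal(unname(g@assignment["c"]), 1L)
  # an already-valid genome is returned unchanged
  v <- Genome(c(a = 0, b = 2, c = 1, d = 2))
  expect_identical(repairGenome(v, m, "lateral")@assignment, v@assignment)
  # all-excluded genome gets exactly one unit per side
  set.seed(4)
  r <- repairGenome(Genome(c(a = 1, b = 1, c = 1, d = 1)), m, "lateral")
  expect_equal(sum(r@assignment == 0), 1)
  expect_equal(sum(r@assignment == 2), 1)
  expect_true(isTRUE(validGenome(r, m, "lateral")))

  # property: decode(repair(g)) never raises over random vectors
  set.seed(5)
  for (i in 1:200) {
    raw <- Genome(setNames(sample(0:2, 4, replace = TRUE),
                           c("a", "b", "c", "d")))
    expect_s4_class(decodeGenome(repairGenome(raw, m, "lateral"), m,
                                 "lateral"), "RatioSpec")
  }
})

test_that("pinned units fix their side exactly in restricted-search mode", {
  m <- tinyMeta()
  frozen <- c(a = 0L)
  set.seed(6)
  for (i in 1:50) {
    raw <- Genome(setNames(sample(0:2, 4, replace = TRUE),
                           c("a", "b", "c", "d")), frozen = frozen)
    rep_ <- repairGenome(raw, m, "lateral")
    expect_equal(names(rep_@assignment)[rep_@assignment == 0], "a")
  }
})

test_that("biomarker JSON serialization round-trips", {
  spec <- RatioSpec(c("a", "b"), "d")
  cfg <- CompositeConfig("mean_suv", "lateral")
  tmp <- tempfile(fileext = ".json")
  writeBiomarker(spec, cfg, tmp)
  back <- readBiomarker(tmp)
  expect_equal(back$spec@numerator, spec@numerator)
  expect_equal(back$spec@denominator, spec@denominator)
  expect_equal(back$config@method, "mean_suv")
})
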