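test_that("time centring is per subject and shift invariant", {
  series <- data.frame(subject_id = rep(c("s1", "s2"), each = 2),
                       group = rep(c("CU", "CI"), each = 2),
                       scan_time = c(70.0, 71.5, 0.0, 2.0),
                       value = c(1.1, 1.2, 1.3, 1.4))
  fr <- centerTime(series)
  expect_equal(fr$time[fr$subject == "s1"], c(-0.75, 0.75))
  expect_equal(as.vector(tapply(fr$time, fr$subject, mean)), c(0, 0),
               tolerance = 1e-12)
  expect_equal(fr$y, log(series$value))
  expect_equal(fr$dx, c(0L, 0L, 1L, 1L))

  shifted <- series
  shifted$scan_time[shifted$subject_id == "s2"] <-
    shifted$scan_time[shifted$subject_id == "s2"] + 10
  expect_equal(centerTime(shifted), fr)

  expect_error(centerTime(series[, -2]), "group")
  series$group <- NULL
  expect_error(centerTime(series,
                          groups = c(s1 = "CU")), "s2")
})

test_that("noise-free data are interpolated exactly", {
  fr <- do.call(rbind, lapply(1:12, function(j) {
    dx <- as.integer(j > 6)
    data.frame(subject = paste0("s", j), time = c(-1, 0, 1), dx = dx,
               y = 1 + 0.05 * c(-1, 0, 1) + 0.02 * dx * c(-1, 0, 1))
  }))
  f <- fitLMM(fr)
  expect_true(f@converged)
  expect_equal(unname(f@beta), c(1, 0.05, 0, 0.02), tolerance = 1e-8)
  expect_lt(f@sigmaEps, 1e-6)
  expect_lt(max(abs(f@residuals)), 1e-8)
  expect_equal(repeatabilityPercent(f), 0, tolerance = 1e-6)
})

test_that("the fit agrees with an independent REML implementation", {
  skip_if_not_installed("nlme")
  set.seed(101)
  for (rep_ in 1:3) {
    fr <- simulateLongitudinal(nPerGroup = c(12, 12),
                               visitTimes = c(0, 1, 2, 3.5))
    f <- fitLMM(fr)
    o <- nlme::lme(y ~ time * dx, random = ~ time | subject, data = fr,
                   method = "REML",
                   control = nlme::lmeControl(opt = "optim",
                                              msMaxIter = 200,
                                              msTol = 1e-9))
    expect_equal(f@logLik, as.numeric(stats::logLik(o)), tolerance = 1e-4)
    expect_equal(unname(f@beta), unname(nlme::fixef(o)), tolerance = 1e-4)
    vc <- as.numeric(nlme::VarCorr(o)[, "StdDev"])
    expect_equal(f@sigmaB0, vc[1], tolerance = 1e-2)
    expect_equal(f@sigmaEps, vc[3], tolerance = 1e-2)
  }
})

test_that("group separation is the signed Wald ratio of the interaction", {
  set.seed(7)
  fr <- simulateLongitudinal(beta = c(0.3, 0.02, 0.01, 0.04),
                             nPerGroup = c(40, 40))
  f <- fitLMM(fr)
  expect_equal(groupSeparation(f),
               unname(f@beta["time_dx"] / f@se["time_dx"]))
  expect_gt(groupSeparation(f), 0)  # planted positive interaction
  # negating the response flips the sign
  fr2 <- fr; fr2$y <- -fr2$y
  expect_equal(groupSeparation(fitLMM(fr2)), -groupSeparation(f),
               tolerance = 1e-6)
  # equal group slopes, tiny noise -> t near 0
  set.seed(8)
  fr3 <- simulateLongitudinal(beta = c(0.3, 0.02, 0.01, 0),
                              sigmaEps = 1e-4, sigmaB0 = 0, sigmaB1 = 0,
                              rho = 0, nPerGroup = c(30, 30))
  expect_lt(abs(groupSeparation(fitLMM(fr3))), 4)
})

test_that("repeatability approximates the planted residual SD and is scale invariant", {
  set.seed(9)
  fr <- simulateLongitudinal(sigmaEps = 0.02, nPerGroup = c(60, 60),
                             visitTimes = seq(0, 4, length.out = 5))
  f <- fitLMM(fr)
  # many visits -> little shrinkage; 100 * sd(resid) close to 2%
  expect_equal(repeatabilityPercent(f), 2.0, tolerance = 0.35)
  # multiplying raw biomarker values by a constant shifts log intercept only
  fr2 <- fr; fr2$y <- fr2$y + log(3.7)
  expect_equal(repeatabilityPercent(fitLMM(fr2)), repeatabilityPercent(f),
               tolerance = 1e-8)
})

test_that("every reported metric is invariant to shifting one subject's times", {
  set.seed(10)
  base <- data.frame(subject_id = rep(sprintf("p%d", 1:20), each = 3),
                     group = rep(rep(c("CU", "CI"), 10), each = 3),
                     scan_time = as.vector(replicate(20, c(0, 1.1, 2.3))))
  base$value <- exp(0.2 + 0.03 * base$scan_time +
                      0.02 * (base$group == "CI") * base$scan_time +
                      rnorm(nrow(base), 0, 0.02))
  f1 <- fitLMM(centerTime(base))
  shifted <- base
  pick <- shifted$subject_id == "p7"
  shifted$scan_time[pick] <- shifted$scan_time[pick] + 55
  f2 <- fitLMM(centerTime(shifted))
  expect_equal(groupSeparation(f1), groupSeparation(f2), tolerance = 1e-8)
  expect_equal(repeatabilityPercent(f1), repeatabilityPercent(f2),
               tolerance = 1e-8)
  expect_equal(f1@sigmaB1, f2@sigmaB1, tolerance = 1e-6)
})

test_that("the correlation likelihood-ratio test is non-negative with df 1", {
  set.seed(11)
  fr <- simulateLongitudinal(rho = 0.8, nPerGroup = c(40, 40))
  out <- lrtRandomCorrelation(fr)
  expect_gte(out$chisq, 0)  # nested models
  expect_equal(out$df, 1L)
  expect_equal(out$p, pchisq(out$chisq, 1, lower.tail = FALSE))
  expect_gte(out$logLik_correlated, out$logLik_uncorrelated)
})

test_that("correlation test rejects planted correlation and holds its level near rho = 0", {
  ## moderate simulation sizes keep the suite fast; the acceptance study
  ## uses the larger replicate counts
  set.seed(12)
  power_hits <- level_hits <- 0
  n_power <- 30; n_level <- 40
  for (i in seq_len(n_power)) {
    fr <- simulateLongitudinal(rho = 0.8, sigmaB0 = 0.12, sigmaB1 = 0.03,
                               nPerGroup = c(100, 100))
    if (lrtRandomCorrelation(fr)$p < 0.05) power_hits <- power_hits + 1
  }
  expect_gt(power_hits / n_power, 0.8)
  for (i in seq_len(n_level)) {
    fr <- simulateLongitudinal(rho = 0, nPerGroup = c(50, 50))
    if (lrtRandomCorrelation(fr)$p < 0.05) level_hits <- level_hits + 1
  }
  # conservative near the boundary: observed rate at or below ~5%
  expect_lte(level_hits / n_level, 0.15)
})
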