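test_that("tournament selection matches its exact win probability", {
  m <- tinyMeta()
  pop <- lapply(list(c(a = 0, b = 1, c = 1, d = 2),
                     c(a = 0, b = 2, c = 1, d = 1),
                     c(a = 1, b = 0, c = 1, d = 2),
                     c(a = 0, b = 0, c = 1, d = 2)), Genome)
  fits <- c(0.1, 0.4, 0.2, 0.3)
  # with 4 members and 3 picks with replacement,
  # P(best selected) = 1 - (3/4)^3 = 37/64
  set.seed(20)
  n <- 20000
  wins <- 0
  for (i in seq_len(n)) {
    g <- tournamentSelect(pop, fits, k = 3)
    if (identical(g@assignment, pop[[2]]@assignment)) wins <- wins + 1
  }
  p <- 37 / 64
  expect_lt(abs(wins / n - p), 3 * sqrt(p * (1 - p) / n))
  # closure: the winner is always a population member
  keys <- vapply(pop, function(g) paste(g@assignment, collapse = ""), "")
  for (i in 1:20)
    expect_true(paste(tournamentSelect(pop, fits)@assignment,
                      collapse = "") %in% keys)
})

test_that("blend crossover reproduces the analytic allele distribution", {
  # identical parents -> identical child (degenerate interval)
  p1 <- Genome(c(a = 0, b = 1, c = 2, d = 1))
  set.seed(21)
  expect_identical(blendCrossover(p1, p1)@assignment, p1@assignment)

  # parents 0 and 2 at every gene, alpha 0.5: u ~ U(-1, 3), clamp to
  # [0,2], round -> P(0) = P(u < .5) = 1.5/4, P(1) = 1/4, P(2) = 1.5/4
  pa <- Genome(c(a = 0, b = 0, c = 0, d = 0))
  pb <- Genome(c(a = 2, b = 2, c = 2, d = 2))
  set.seed(22)
  n <- 25000  # x4 genes = 1e5 draws
  draws <- unlist(lapply(seq_len(n), function(i)
    blendCrossover(pa, pb, alpha = 0.5)@assignment))
  freq <- tabulate(draws + 1L, 3) / length(draws)
  expected <- c(1.5, 1, 1.5) / 4
  for (k in 1:3)
    expect_lt(abs(freq[k] - expected[k]),
              3 * sqrt(expected[k] * (1 - expected[k]) / length(draws)))
})

test_that("mutation respects its rate and frozen genes; repair is applied when asked", {
  m <- tinyMeta()
  g <- Genome(c(a = 0, b = 1, c = 1, d = 2), frozen = c(d = 2L))
  set.seed(23)
  expect_identical(adaptiveMutate(g, rate = 0)@assignment, g@assignment)
  mut <- adaptiveMutate(g, rate = 1)
  free <- c("a", "b", "c")
  expect_true(all(mut@assignment[free] != g@assignment[free]))
  expect_equal(unname(mut@assignment["d"]), 2L)
  # with metadata the result is always constraint-valid
  for (i in 1:25) {
    mm <- adaptiveMutate(g, rate = 1, meta = m, laterality = "lateral")
    expect_true(isTRUE(validGenome(mm, m, "lateral")))
  }
})

test_that("population initialization is seeded, valid and honours pinned sides", {
  m <- tinyMeta()
  cfg <- GAConfig(populationSize = 16L)
  set.seed(30); pop1 <- initializePopulation(cfg, m, "lateral")
  set.seed(30); pop2 <- initializePopulation(cfg, m, "lateral")
  expect_identical(lapply(pop1, slot, "assignment"),
                   lapply(pop2, slot, "assignment"))
  for (g in pop1) expect_true(isTRUE(validGenome(g, m, "lateral")))

  cfgF <- GAConfig(populationSize = 12L, frozen = c(a = 0L, b = 0L))
  set.seed(31)
  popF <- initializePopulation(cfgF, m, "lateral")
  for (g in popF)
    expect_setequal(names(g@assignment)[g@assignment == 0], c("a", "b"))
})

test_that("brute force enumerates exactly the constraint-valid genomes", {
  # two units, one per side eligible -> a single valid genome
  m2 <- RegionMetadata(data.frame(
    region_id = c("t", "r"), hemisphere = "midline",
    bilateral_pair_id = "none", braak_stage = c("1", "none"),
    reference_candidate = c(FALSE, TRUE), composites = "none",
    stringsAsFactors = FALSE))
  suv <- matrix(c(1.5, 1.0, 1.6, 1.0), nrow = 2,
                dimnames = list(c("t", "r"), NULL))
  d2 <- matrixDataset(suv, subjectId = c("s1", "s1"), group = "CI",
                      scanTime = c(0, 1))
  expect_error(bruteForceSearch(d2, m2, CompositeConfig("mean_suv",
                                                        "lateral"),
                                trialPreset("experiment2"), maxUnits = 1L),
               "refused")
  # the dataset violates the two-subject model requirement, but the
  # enumeration count is computed before evaluation
  bf <- tryCatch(bruteForceSearch(d2, m2, CompositeConfig("mean_suv",
                                                          "lateral"),
                                  trialPreset("experiment2")),
                 error = function(e) e)
  if (!inherits(bf, "error")) {
    expect_equal(bf$nEnumerated, 9)
    expect_equal(bf$nValid, 1)
  }

  # constraint masks cut the count by the exact combinatorial factor:
  # units {a,b}: 3 values; c: {0,1}; d: {1,2}; minus empty-side cases
  g <- generateCohort(cohortPreset("tiny_oracle"), seed = 1)
  bf2 <- bruteForceSearch(g$dataset, g$metadata,
                          CompositeConfig("mean_suv", "lateral"),
                          trialPreset("experiment2"))
  # 2*3*3*3*2*2 (sig1 in {0,1}; refs in {1,2}) minus no-numerator (32)
  # minus no-denominator (16) plus the all-excluded overlap (1)
  expect_equal(bf2$nValid, 216 - 32 - 16 + 1)
  expect_equal(bf2$nEnumerated, 3^6)
})

test_that("the search is deterministic, elitist and adapts its mutation rate", {
  g <- generateCohort(cohortPreset("tiny_oracle"), seed = 2)
  cfg <- GAConfig(generations = 25L, stagnationWindow = 5L, seed = 99L)
  cc <- CompositeConfig("mean_suv", "lateral")
  des <- trialPreset("experiment2")
  s1 <- runSearch(g$dataset, g$metadata, cc, des, cfg)
  s2 <- runSearch(g$dataset, g$metadata, cc, des, cfg)
  expect_identical(s1@bestGenome@assignment, s2@bestGenome@assignment)
  expect_identical(s1@trace, s2@trace)
  expect_equal(s1@bestResult@fitness, s2@bestResult@fitness)

  # elitism: the best-so-far trace never decreases
  expect_true(all(diff(s1@trace$best_fitness) >= 0))
  # stagnation on this small problem must eventually boost the rate
  base_rate <- 1 / 6
  expect_gt(max(s1@trace$mutation_rate), base_rate)
  # reported genomes are valid
  expect_true(isTRUE(validGenome(s1@bestGenome, g$metadata, "lateral")))
  for (t in s1@topN)
    expect_true(isTRUE(validGenome(t$genome, g$metadata, "lateral")))
})

test_that("restricted search with a pinned numerator only explores denominators", {
  g <- generateCohort(cohortPreset("tiny_oracle"), seed = 3)
  frozen <- c(sig1 = 0L, sig2 = 0L)
  cfg <- GAConfig(generations = 10L, seed = 5L, frozen = frozen)
  s <- runSearch(g$dataset, g$metadata,
                 CompositeConfig("mean_suv", "lateral"),
                 trialPreset("experiment2"), cfg)
  expect_setequal(s@bestSpec@numerator, c("sig1", "sig2"))
  bf <- bruteForceSearch(g$dataset, g$metadata,
                         CompositeConfig("mean_suv", "lateral"),
                         trialPreset("experiment2"), frozen = frozen)
  expect_setequal(bf$spec@numerator, c("sig1", "sig2"))
  expect_equal(s@bestResult@fitness, bf$fitness, tolerance = FAST_EVAL_TOL)
})

test_that("the fast search evaluator agrees with the reference evaluation path", {
  g <- generateCohort(cohortPreset("tiny_oracle"), seed = 4)
  cc <- CompositeConfig("mean_suv", "lateral")
  des <- trialPreset("experiment2")
  s <- runSearch(g$dataset, g$metadata, cc, des,
                 GAConfig(generations = 5L, seed = 8L))
  ref <- evaluateCandidate(g$dataset, s@bestSpec, cc, des,
                           meta = g$metadata)
  expect_equal(s@bestResult@fitness, ref@fitness,
               tolerance = FAST_EVAL_TOL)
  expect_equal(s@bestResult@sse, ref@sse)
  expect_equal(s@bestResult@separation, ref@separation,
               tolerance = FAST_EVAL_TOL)
})
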