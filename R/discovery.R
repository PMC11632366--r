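## The constrained genetic algorithm over 0/1/2 genomes, plus a brute-force
## oracle for small unit sets.

#' Initialize a GA population
#'
#' Each member is drawn uniformly over \{0,1,2\} per gene, then repaired;
#' frozen assignments are applied by the repair. Uses R's global RNG
#' stream (seed it, or call through [runSearch()]).
#'
#' @param config a [GAConfig-class].
#' @param meta a [RegionMetadata-class].
#' @param laterality unit mode.
#' @param units precomputed [searchUnits()] table.
#' @return list of [Genome-class] of length \code{populationSize}.
#' @export
initializePopulation <- function(config, meta, laterality = "bilateral",
                                 units = searchUnits(meta, laterality)) {
  lapply(seq_len(config@populationSize), function(i) {
    a <- sample(0:2, nrow(units), replace = TRUE)
    names(a) <- units$unit
    repairGenome(Genome(a, frozen = config@frozen), meta, laterality,
                 units = units)
  })
}

#' Tournament selection
#'
#' Draws \code{k} members uniformly with replacement and returns the one
#' with highest fitness (ties resolved in draw order). Sentinel
#' (\code{-Inf}) fitnesses are allowed and lose every comparison.
#'
#' @param population list of [Genome-class].
#' @param fitnesses numeric vector, one per member.
#' @param k tournament size (default 3 random picks).
#' @return the selected [Genome-class].
#' @export
tournamentSelect <- function(population, fitnesses, k = 3) {
  idx <- sample.int(length(population), k, replace = TRUE)
  population[[idx[which.max(fitnesses[idx])]]]
}

#' Blend crossover on the integer genome
#'
#' Per gene with parent values a and b, a value is sampled uniformly on
#' \code{[min(a,b) - alpha*|a-b|, max(a,b) + alpha*|a-b|]}, clamped to
#' \code{[0, 2]} and rounded to the nearest integer (BLX-alpha adapted to
#' the 0/1/2 alphabet). Identical parents reproduce exactly. When
#' \code{meta} is supplied the child is repaired (which also restores
#' frozen genes).
#'
#' @param parentA,parentB equal-length [Genome-class] parents.
#' @param alpha interval expansion factor (default 0.5).
#' @param meta optional [RegionMetadata-class]; triggers repair.
#' @param laterality unit mode for repair.
#' @return child [Genome-class].
#' @export
blendCrossover <- function(parentA, parentB, alpha = 0.5, meta = NULL,
                           laterality = "bilateral") {
  a <- parentA@assignment; b <- parentB@assignment
  stopifnot(length(a) == length(b))
  lo <- pmin(a, b) - alpha * abs(a - b)
  hi <- pmax(a, b) + alpha * abs(a - b)
  u <- runif(length(a), lo, hi)
  child <- as.integer(round(pmin(pmax(u, 0), 2)))
  names(child) <- names(a)
  g <- Genome(child, frozen = parentA@frozen)
  if (!is.null(meta)) g <- repairGenome(g, meta, laterality)
  g
}

#' Uniform crossover (alternative operator)
#'
#' Each gene is copied from either parent with probability 1/2.
#'
#' @inheritParams blendCrossover
#' @return child [Genome-class].
#' @export
uniformCrossover <- function(parentA, parentB, meta = NULL,
                             laterality = "bilateral") {
  a <- parentA@assignment; b <- parentB@assignment
  stopifnot(length(a) == length(b))
  take <- runif(length(a)) < 0.5
  child <- ifelse(take, a, b)
  names(child) <- names(a)
  g <- Genome(child, frozen = parentA@frozen)
  if (!is.null(meta)) g <- repairGenome(g, meta, laterality)
  g
}

#' Random adaptive mutation
#'
#' Each unfrozen gene is independently resampled uniformly from the two
#' other alleles with probability \code{rate}. The rate itself is adapted
#' by the controller in [runSearch()]: multiplied by \code{mutationBoost}
#' after \code{stagnationWindow} generations without improvement (capped at
#' \code{mutationCap}), reset to base on improvement.
#'
#' @param genome a [Genome-class].
#' @param rate per-gene mutation probability in \code{[0, 1]}.
#' @param meta optional [RegionMetadata-class]; triggers repair.
#' @param laterality unit mode for repair.
#' @return mutated [Genome-class].
#' @export
adaptiveMutate <- function(genome, rate, meta = NULL,
                           laterality = "bilateral") {
  stopifnot(rate >= 0, rate <= 1)
  a <- genome@assignment
  free <- setdiff(names(a), names(genome@frozen))
  hit <- free[runif(length(free)) < rate]
  for (u in hit) a[u] <- sample(setdiff(0:2, a[u]), 1L)
  g <- Genome(a, frozen = genome@frozen)
  if (!is.null(meta)) g <- repairGenome(g, meta, laterality)
  g
}

.genomeKey <- function(genome) paste(genome@assignment, collapse = "")

## Memoized candidate evaluator shared by runSearch and bruteForceSearch.
## For speed the bilateral collapse is done once up front and every
## candidate's model is refitted from one fixed template (same frame, new
## response, fixed optimizer start), which is order-independent and agrees
## with the reference evaluateCandidate() path to optimizer tolerance.
.makeEvaluator <- function(dataset, meta, compositeConfig, design,
                           sseExponent) {
  cache <- new.env(parent = emptyenv())
  hits <- 0L
  evals <- 0L
  laterality <- compositeConfig@laterality
  units <- searchUnits(meta, laterality)
  dsEval <- if (laterality == "bilateral") makeBilateral(dataset, meta)
  else dataset
  s <- suv(dsEval); v <- volumes(dsEval)
  cd <- SummarizedExperiment::colData(dsEval)
  skeleton <- data.frame(subject_id = cd$subject_id,
                         group = as.character(cd$group),
                         scan_time = cd$scan_time, log_value = 0,
                         stringsAsFactors = FALSE)
  frame0 <- centerTime(transform(skeleton, log_value = log(s[1, ])))
  model0 <- fitLMM(frame0)@model

  evaluate <- function(genome) {
    key <- .genomeKey(genome)
    if (!is.null(cache[[key]])) {
      hits <<- hits + 1L
      return(cache[[key]])
    }
    stopifnot(isTRUE(validGenome(genome, meta, laterality, units)))
    spec <- decodeGenome(genome, meta, laterality, units)
    a <- genome@assignment
    res <- tryCatch({
      y <- log(.compositeMatrixValue(s, v, names(a)[a == 0],
                                     compositeConfig@method)) -
        log(.compositeMatrixValue(s, v, names(a)[a == 2],
                                  compositeConfig@method))
      if (is.null(model0)) {
        frame <- frame0; frame$y <- y
        fit <- fitLMM(frame)
      } else {
        m2 <- suppressMessages(suppressWarnings(lme4::refit(model0, y)))
        fit <- .lmmFromMer(m2, REML = TRUE)
      }
      if (!fit@converged) .invalidResult(spec, "model did not converge")
      else {
        sep <- groupSeparation(fit)
        ss <- sampleSizeEstimate(fit, design)
        new("EvaluationResult", spec = spec, sse = ss$sse, rawSse = ss$raw,
            separation = sep, repeatability = repeatabilityPercent(fit),
            fitness = cvrFitness(sep, ss$raw, sseExponent), valid = TRUE,
            fit = fit, message = "")
      }
    }, error = function(e) .invalidResult(spec, conditionMessage(e)))
    evals <<- evals + 1L
    cache[[key]] <- res
    res
  }
  list(evaluate = evaluate,
       stats = function() c(evaluations = evals, hits = hits),
       entries = function() as.list(cache))
}

#' Run the genetic-algorithm biomarker search
#'
#' Elitist generational GA: memoized fitness evaluation, tournament
#' selection (3 random picks), blend (or uniform) crossover, random
#' adaptive mutation and constraint repair, with one elite copy per
#' generation so the best-so-far trace is non-decreasing. Fully
#' deterministic given \code{gaConfig@seed}.
#'
#' @param dataset a [RegionalDataset-class].
#' @param meta a [RegionMetadata-class].
#' @param compositeConfig a [CompositeConfig-class].
#' @param design a [TrialDesign-class].
#' @param gaConfig a [GAConfig-class].
#' @param topN how many distinct top candidates to report.
#' @return A [SearchResult-class].
#' @export
runSearch <- function(dataset, meta, compositeConfig, design,
                      gaConfig = GAConfig(), topN = 5L) {
  set.seed(gaConfig@seed)
  laterality <- compositeConfig@laterality
  ev <- .makeEvaluator(dataset, meta, compositeConfig, design,
                       gaConfig@sseExponent)
  units <- searchUnits(meta, laterality)
  pop <- initializePopulation(gaConfig, meta, laterality, units = units)
  L <- length(pop[[1]]@assignment)
  base_rate <- if (is.na(gaConfig@mutationRate)) 1 / L else
    gaConfig@mutationRate
  rate <- base_rate
  stagn <- 0L
  best_genome <- NULL
  best_fitness <- -Inf
  trace <- vector("list", gaConfig@generations + 1L)

  score <- function(pop) vapply(pop, function(g) ev$evaluate(g)@fitness,
                                numeric(1))
  fits <- score(pop)
  update_best <- function(fits, pop) {
    i <- which.max(fits)
    if (fits[i] > best_fitness) {
      best_fitness <<- fits[i]
      best_genome <<- pop[[i]]
      TRUE
    } else FALSE
  }
  update_best(fits, pop)
  trace[[1]] <- data.frame(generation = 0L, best_fitness = best_fitness,
                           mean_fitness = mean(fits[is.finite(fits)]),
                           mutation_rate = rate)

  for (gen in seq_len(gaConfig@generations)) {
    nxt <- vector("list", gaConfig@populationSize)
    nelite <- min(gaConfig@elitismCount, gaConfig@populationSize)
    if (nelite > 0) nxt[seq_len(nelite)] <- list(best_genome)
    for (i in seq(nelite + 1L, gaConfig@populationSize)) {
      p1 <- tournamentSelect(pop, fits, gaConfig@tournamentSize)
      p2 <- tournamentSelect(pop, fits, gaConfig@tournamentSize)
      child <- if (gaConfig@crossover == "blend")
        blendCrossover(p1, p2, gaConfig@blendAlpha)
      else uniformCrossover(p1, p2)
      child <- adaptiveMutate(child, rate)
      nxt[[i]] <- repairGenome(child, meta, laterality, units = units)
    }
    pop <- nxt
    fits <- score(pop)
    improved <- update_best(fits, pop)
    if (improved) {
      rate <- base_rate
      stagn <- 0L
    } else {
      stagn <- stagn + 1L
      if (stagn >= gaConfig@stagnationWindow) {
        rate <- min(rate * gaConfig@mutationBoost, gaConfig@mutationCap)
        stagn <- 0L
      }
    }
    trace[[gen + 1L]] <- data.frame(
      generation = gen, best_fitness = best_fitness,
      mean_fitness = mean(fits[is.finite(fits)]), mutation_rate = rate)
  }

  entries <- ev$entries()
  fit_all <- vapply(entries, function(r) r@fitness, numeric(1))
  ord <- order(fit_all, decreasing = TRUE)
  top <- lapply(head(ord, topN), function(i) {
    key <- names(entries)[i]
    a <- as.integer(strsplit(key, "")[[1]])
    names(a) <- names(best_genome@assignment)
    list(genome = Genome(a, frozen = gaConfig@frozen),
         result = entries[[i]])
  })
  new("SearchResult", bestGenome = best_genome,
      bestSpec = decodeGenome(best_genome, meta, laterality, units),
      bestResult = ev$evaluate(best_genome),
      trace = do.call(rbind, trace), topN = top, cacheStats = ev$stats(),
      gaConfig = gaConfig, design = design,
      compositeConfig = compositeConfig)
}

#' Exhaustive search over all constraint-valid genomes
#'
#' Brute-force oracle for small unit sets: enumerates every \{0,1,2\}
#' assignment, filters to the constraint-valid ones (non-empty disjoint
#' sides, Braak 1--3 exclusion from the denominator, reference candidates
#' excluded from the numerator, frozen values respected) and returns the
#' fitness argmax.
#'
#' @inheritParams runSearch
#' @param maxUnits refusal threshold on the number of units (default 8).
#' @param frozen optional named integer vector of pinned values.
#' @param sseExponent fitness exponent.
#' @return list: \code{genome}, \code{spec}, \code{result}, \code{fitness},
#'   \code{nEnumerated}, \code{nValid}.
#' @export
bruteForceSearch <- function(dataset, meta, compositeConfig, design,
                             maxUnits = 8L, frozen = integer(0),
                             sseExponent = 2) {
  laterality <- compositeConfig@laterality
  units <- searchUnits(meta, laterality)
  L <- nrow(units)
  if (L > maxUnits)
    stop(L, " units exceed maxUnits = ", maxUnits,
         "; brute force refused (use runSearch)")
  grid <- as.matrix(expand.grid(rep(list(0:2), L), KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- units$unit
  keep <- rowSums(grid == 0) > 0 & rowSums(grid == 2) > 0
  bad_den <- units$unit[!units$denominator_ok]
  bad_num <- units$unit[!units$numerator_ok]
  if (length(bad_den))
    keep <- keep & rowSums(grid[, bad_den, drop = FALSE] == 2) == 0
  if (length(bad_num))
    keep <- keep & rowSums(grid[, bad_num, drop = FALSE] == 0) == 0
  if (length(frozen)) {
    for (u in names(frozen))
      keep <- keep & grid[, u] == frozen[[u]]
    for (side in c(0L, 2L))
      if (any(frozen == side)) {
        unfrozen <- setdiff(units$unit, names(frozen))
        keep <- keep &
          rowSums(grid[, unfrozen, drop = FALSE] == side) == 0
      }
  }
  valid <- grid[keep, , drop = FALSE]
  if (!nrow(valid)) stop("no constraint-valid genome exists")
  ev <- .makeEvaluator(dataset, meta, compositeConfig, design, sseExponent)
  best <- NULL; best_fit <- -Inf
  for (i in seq_len(nrow(valid))) {
    g <- Genome(setNames(valid[i, ], units$unit), frozen = frozen)
    r <- ev$evaluate(g)
    if (is.null(best) || r@fitness > best_fit) {
      best_fit <- r@fitness
      best <- list(genome = g, result = r)
    }
  }
  list(genome = best$genome,
       spec = decodeGenome(best$genome, meta, laterality),
       result = best$result, fitness = best_fit,
       nEnumerated = nrow(grid), nValid = nrow(valid))
}

#' Serialize a SearchResult to JSON
#'
#' @param result a [SearchResult-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSearchResult <- function(result, path) {
  r <- result@bestResult
  jsonlite::write_json(list(
    assignment = as.list(result@bestGenome@assignment),
    numerator = result@bestSpec@numerator,
    denominator = result@bestSpec@denominator,
    method = jsonlite::unbox(result@compositeConfig@method),
    laterality = jsonlite::unbox(result@compositeConfig@laterality),
    metrics = list(sse = r@sse, raw_sse = r@rawSse,
                   separation = r@separation,
                   repeatability = r@repeatability, fitness = r@fitness),
    trace = result@trace,
    cache = as.list(result@cacheStats),
    seed = result@gaConfig@seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
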