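---
title: "Discovering composite-value-ratio biomarkers: models and methods"
author: "CVRseek authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering composite-value-ratio biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CVRseek)
```

## The problem

Longitudinal tau PET studies summarise regional tracer uptake as SUVR: a
target-region standardized uptake value (SUV) divided by the SUV of a
pathology-free reference region. The choice of target and reference is
conventionally fixed a priori. CVRseek generalises the construction to a
*composite value ratio* (CVR): the ratio of two arbitrary multi-region
composite signals,

$$\mathrm{CVR} = \frac{\mathrm{composite}_1(\mathrm{SUV})}
                     {\mathrm{composite}_2(\mathrm{SUV})},$$

and searches for the numerator/denominator region sets that make the best
longitudinal trial endpoint. Because both sides are measured on the same
scan, any per-scan multiplicative factor — dose, scanner calibration,
global signal drift — cancels exactly in the ratio. This is the core
rationale: a ratio needs no pathology-free reference to be stable, it only
needs a denominator whose disease-related change differs from the
numerator's. For the same reason CVRs computed from SUV and from SUVR
inputs are identical, which both the unit tests and the acceptance checks
assert to machine precision.

## The longitudinal model

Every candidate biomarker is scored through one linear mixed-effects model
fitted to the natural log of its per-scan value:

$$y_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2 \mathrm{DX}_j
         + \beta_3\, t_{ij}\,\mathrm{DX}_j + b_{0j} + b_{1j} t_{ij}
         + \varepsilon_{ij},$$

with observation $i$ of subject $j$, $\mathrm{DX}_j = 1$ for cognitively
impaired (CI) subjects and 0 for cognitively unimpaired (CU),
$(b_{0j}, b_{1j})$ bivariate normal with unstructured covariance
(`sigmaB0`, `sigmaB1`, `rho`) and i.i.d. residuals. Time $t_{ij}$ is
centred at each subject's mean scan time, which — together with the
correlated random intercepts and slopes — makes every reported metric
invariant to shifting a subject's visit times by a constant (tested to
1e-8). The fit is by REML through `lme4`; maximum likelihood is used only
for the nested likelihood-ratio test of the intercept–slope correlation
(`lrtRandomCorrelation`), where REML likelihoods would not be comparable.

Three metrics are extracted:

* **Group separation** — the Wald ratio $\hat\beta_3 / SE(\hat\beta_3)$,
  positive when the CI group accumulates faster. No finite-sample df
  correction is applied: only the relative magnitude feeds the search.
* **Repeatability (percent error)** — 100 times the standard deviation of
  the conditional residuals on the log scale. The literal
  residual-of-the-fit reading is the default; the model parameter
  $\hat\sigma_\varepsilon$ is also exposed (`fit@sigmaEps`) since the two
  differ under shrinkage.
* **Sample-size estimate (SSE)** — per-arm subjects for a two-arm,
  1:1, slope-reduction trial with power $1-\beta$ (default 0.80),
  two-sided $\alpha$ (0.05) and detectable effect $\Delta$ equal to
  `pctChange` (0.20) of the trial group's mean slope
  ($\beta_1$ for CU, $\beta_1 + \beta_3$ for CI):

  $$n = \frac{2\,(z_{1-\alpha/2} + z_{power})^2\,
        \left(\sigma_{b1}^2 + \sigma_\varepsilon^2 \big/
        \sum_k (t_k - \bar t)^2\right)}{\Delta^2},$$

  the random-slope (Edland-type) form, with $t_k$ the trial's visit
  schedule (default two visits: 0 and 4.5 years for the preclinical
  preset, 0 and 1.5 years for the clinical preset). The variance
  components are pooled from the joint two-group fit; only the slope is
  group-specific — refitting per group would contradict the single printed
  model. Among the published power formulas for longitudinal designs this
  is the one applicable to a fitted random-slope model with a two-visit
  schedule; a 2000-replicate Monte-Carlo trial simulation at the formula's
  $n$ (in the acceptance suite) confirms empirical power within
  [0.75, 0.85] across variance-component settings. The reported SSE is the
  ceiling of $n$; the search and all tie-breaks use the raw value to avoid
  integer plateaus.

## The search

A candidate is encoded as a vector over *searchable units* with values 0
(numerator), 1 (excluded), 2 (denominator). Units are single regions in
lateral mode, or bilateral pair labels plus midline regions in bilateral
mode. Two biological priors constrain the space: units containing
Braak-stage 1–3 regions (earliest tau involvement) may not serve in the
denominator, and units flagged as conventional SUVR reference regions may
not serve in the numerator. Both lists come from metadata flags, never
from hard-coded names, so any atlas can be plugged in.

The optimizer is an elitist generational genetic algorithm: population 32,
tournament selection with 3 random picks (drawn with replacement; ties to
the first drawn), blend crossover, random adaptive mutation, 300
generations by default. Design choices that the recipe leaves open, and how
we resolved them:

* **Blend crossover on an integer alphabet** is ill-defined as named; we
  implement BLX-$\alpha$ ($\alpha$ = 0.5): per gene, draw uniformly on the
  interval spanned by the parents expanded by $\alpha$ times their gap,
  clamp to [0, 2], round to the nearest integer. A uniform-crossover
  alternative sits behind `GAConfig(crossover = "uniform")`. The allele
  distribution of the blend operator is asserted against its analytic
  interval masses.
* **Adaptive mutation** is interpreted as stagnation-triggered rate
  boosting: base rate $1/L$ per gene, multiplied by `mutationBoost` (2)
  after `stagnationWindow` (10) generations without improvement, capped at
  0.5, reset to base on improvement.
* **Constraint handling is repair, not rejection**: after crossover and
  mutation, prior-violating genes are reset to "excluded", frozen genes are
  restored, and an empty side receives one uniformly chosen eligible unit.
  This keeps the population size fixed and the search efficient; a
  property-based test asserts that repair-then-decode never fails.
* **Elitism (one copy)** makes the best-so-far trace monotone and
  testable.
* **Restricted search** (pinning the numerator or the denominator, as in
  fixed-meta-temporal experiments) is expressed as frozen unit values; a
  side containing a pinned unit is fixed *exactly* — unfrozen units are
  evicted from it — so "fix the numerator" means the numerator is that set
  and nothing else.
* **Memoization**: fitness is cached by genome key; with 32 × 300
  candidate evaluations and heavy revisiting, the cache dominates
  wall-clock behaviour. Inside the search the bilateral collapse is
  performed once and each candidate's model is refitted from a fixed
  template (same design matrices, new response, fixed optimizer start),
  which is order-independent and agrees with the reference
  `evaluateCandidate()` path to optimizer tolerance (~1e-6 relative);
  the equivalence is itself a test.

The fitness is $t_{\beta_3} / n_{raw}^{2}$ — separation divided by the
squared raw sample size. Squaring prioritises trial size over separation;
the exponent is a design choice and is configurable (`sseExponent`).
Including the signed separation forces discovered biomarkers to *increase*
in CI subjects, keeping them interpretable. Invalid candidates
(non-convergent fits, zero slopes) receive a $-\infty$ sentinel and rank
below every valid candidate; nothing raises inside the search loop.

`bruteForceSearch()` enumerates every constraint-valid genome for unit
counts up to 8 and is the oracle for the GA: on 6-unit synthetic fixtures
($3^6$ assignments, 169 valid) the GA's best fitness equals the exhaustive
optimum on every fixture in the suite.

## Baselines, ablation, uncertainty

`enumerateBaselines()` builds the literature-inspired SUVR grid: 10
targets (Braak stages 1–6 as stage-specific sets, meta-temporal,
mesial-temporal, temporoparietal, 'rest') × 11 references (whole
cerebellum, inferior cerebellar grey matter, the composite reference,
eroded subcortical white matter, cerebellum cortex, brainstem, and five
unions of these) × 2 composition methods (mean SUV, volume-weighted SUV) =
220 biomarkers. The arithmetic requires stage-specific (not cumulative)
Braak sets, which is how the shipped metadata encodes them. Combined
references are flat unions of their constituents' region sets; since the
shipped reference structures are single aggregate regions, this reproduces
the "average of the named structures" convention exactly. The
meta-temporal membership (entorhinal, parahippocampal, amygdala, inferior
temporal, fusiform, middle temporal) and the composite-reference
constituents (eroded subcortical white matter, whole cerebellum,
brainstem) are published lists and ship as-is; mesial-temporal,
temporoparietal and 'rest' memberships are **provisional** editable lists,
marked as such here because their sources define them outside the primary
reference — edit `inst/extdata/dk_regions.csv` to match a specific cohort
export.

`ablate()` re-evaluates a biomarker once per single-region removal
(skipping removals that would empty a side), the standard check that no
single region dominates a composite.

`bootstrapCI()` attaches percentile 95% intervals by model-based
parametric bootstrap: holding the design fixed, random effects are redrawn
from the estimated bivariate normal and residuals from
$N(0, \hat\sigma_\varepsilon^2)$, the model is refitted and the metrics
recomputed; non-convergent replicates are dropped and counted, with more
than 20% failures flagging the interval unreliable. Percentile (not
normal-approximation) intervals are used, matching standard mixed-model
bootstrap practice; the replicate count defaults to B = 500. Refits go
through the same fast fixed-template REML path as the search. Coverage is
validated in the acceptance suite: over 200 outer simulations at B = 300,
the interval for the interaction effect must cover its generating value
between 90% and 98% of the time.

## Positivity screening

Amyloid-positivity inclusion is supported two ways: fixed published
cutoffs via `thresholdPositivity()` (boundary inclusive; e.g. 0.78 for
Florbetapir F18, 0.74 for Florbetaben F18 composite SUVR), and a
data-driven rule via `fitGMM2()` — a two-component Gaussian mixture
(EM, unequal variances, via `mclust`) with the cutoff at the
**equal-posterior point**: the location between the component means where
the weighted component densities are equal. Only the resulting cutoff
value of such analyses is usually published, and equal-posterior, density
valley, or $\mu_1 + 2\sigma_1$ could all have produced it; we default to
equal posterior because it is the Bayes decision boundary, keep the other
rules selectable, and solve the boundary in closed form (the quadratic in
$x$ of the log-density equality), so a symmetric mixture yields exactly
the midpoint. An independent numeric root-finder serves as the test
oracle. Degenerate inputs (near-constant samples) return a non-converged
flag rather than an error.

## The synthetic cohort generator

Real tau PET cohorts cannot be redistributed, so the package ships a
generator whose defaults emulate an amyloid-positive longitudinal cohort:
for subject $j$ in group $g$, region $r$, visit time $t$,

$$\log suv_{jr}(t) = m_r + a_j + (s_{r,g} + c_j)\,t + \log g_j(t)
                   + e_{jrt},$$

with $(a_j, c_j)$ bivariate normal (defaults $\sigma_{b0}=0.10$,
$\sigma_{b1}=0.02$, $\rho=0.5$), a lognormal per-scan global scale factor
$g_j(t)$ (SD 0.05) shared by **all** regions of a scan — the synthetic
embodiment of instrumentation-type confounds that ratios cancel — and
independent regional noise (SD 0.02). Signal regions carry group-dependent
slopes (log-scale/year; e.g. entorhinal 0.02 CU / 0.05 CI); stable and
reference regions have zero slope. Subjects have 2–4 visits
(probabilities 0.5/0.3/0.2, our choice of a realistic mix), the first at
time 0, with inter-visit intervals drawn from four bins (≤1.5, 1.5–2.5,
2.5–3.5, >3.5 years) with cohort-style probabilities: 0.61/0.22/0.06/0.11
for the CU-flavoured preset and 0.72/0.17/0.06/0.05 for the CI-flavoured
one. The presets `experiment1_like` and `experiment2_like` both use 76 CU
+ 122 CI subjects, mirroring the discovery-cohort composition;
`tiny_oracle` is a six-region cohort small enough for exhaustive search.
Volumes are region constants with 5% lognormal per-subject jitter, fixed
across a subject's visits.

Generation happens on the log scale so the fitted model is exactly
well-specified under the generator — parameter recovery is then a clean
test. Deliberate consequences and limitations:

* The subject-level $(a_j, c_j)$ are shared across regions, so *any*
  ratio cancels them; ratio fits therefore often sit on the
  $\sigma_{b1} \to 0$ boundary (singular), which the model layer treats as
  valid-with-flag. Real data have region-specific random effects,
  off-target binding, and atrophy-driven partial-volume effects the
  generator does not emulate — passing tests demonstrate the machinery and
  the algebra, not real-data performance.
* First visits at time 0 are harmless because of within-subject centring
  (tested).
* Bilateral SUV averaging is volume-weighted, preserving the identity with
  whole-structure uptake (an open convention; the identity with the
  volume-weighted union composite is asserted to 1e-12). In mean-SUV mode
  a bilateral unit contributes its volume-weighted hemispheric average as
  one vote.

## Numerical and degenerate-input policy

Non-convergent mixed-model fits poison the candidate (sentinel fitness),
never the run. Singular fits are valid with a flag. A zero group slope
maps to an infinite-SSE sentinel; `pctChange` → 0 likewise. Constant
biomarker series produce degenerate fits that are absorbed the same way.
The GMM layer flags rather than fails on degenerate samples. Tournament
ties resolve to the first-drawn member; fitness ties in brute force to the
first enumerated genome. All stochastic components (generator, GA,
bootstrap) are seeded and byte-reproducible; two runs with one seed are
asserted identical.

## Problem sizes used in the shipped studies

The test and acceptance studies are sized for a single CPU: GA runs on the
preset cohorts use 25–60 generations (population 32) — ample on these
landscapes, where the planted optimum is typically found within 15
generations; the mixed-model recovery study uses 100 replicates of 400
subjects × 3 visits; the power validation uses 2000 Monte-Carlo trials per
setting; the bootstrap coverage study uses 200 outer replicates at
B = 300 with 40-subject frames. The package defaults (300 generations,
B = 500) follow the method's own recipe.

## A compact example

```{r example, eval = FALSE}
cohort <- generateCohort(cohortPreset("experiment2_like"), seed = 11)
res <- runSearch(cohort$dataset, cohort$metadata,
                 CompositeConfig("mean_suv", "bilateral"),
                 trialPreset("experiment2"),
                 GAConfig(generations = 50, seed = 1))
res
baselines <- evaluateCatalog(cohort$dataset,
                             enumerateBaselines(cohort$metadata),
                             cohort$metadata, trialPreset("experiment2"))
max(baselines$fitness[is.finite(baselines$fitness)])  # beaten by res
bootstrapCIFromFit(res@bestResult, trialPreset("experiment2"), B = 500,
                   seed = 1)
```
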