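---
title: "Time-aware analysis of longitudinal lupus biomarker trajectories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aware analysis of longitudinal lupus biomarker trajectories: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lupustraj)
```

## The problem

Systemic lupus erythematosus (SLE) is a relapsing–remitting autoimmune
disease with marked between-patient heterogeneity and strong fluctuation of
disease activity over time. Registry cohorts record, at each clinic visit, a
panel of routine laboratory parameters, candidate serum biomarkers and a
composite disease-activity score (SLEDAI-2k). Conventional biomarker
analyses pool visits across patients and ignore the time axis; this package
implements a time-aware alternative built from four components:

1. **Magnitude-based patient clustering.** Each patient's z-scored visit
   series is collapsed to a 17-element summary vector; pairwise Euclidean
   distances feed agglomerative hierarchical clustering, and a cut at 90% of
   the dendrogram height lets the number of groups emerge from the data.
2. **Tempo-aware clustering.** Multivariate open-end dynamic time warping
   (DTW) aligns full visit series before clustering, so two patients whose
   biomarker trajectories follow the same course at different speeds are
   recognised as similar.
3. **Time-agnostic vs time-lagged regression.** SLEDAI-2k is regressed on
   the 17 parameters of the current visit alone (18 free parameters with the
   intercept), or on the current plus the same patient's previous visit
   (35 free parameters). Generalisation is measured by leave-one-patient-out
   (LOPO) cross-validation and by a patient-level 80/20 bootstrap
   (1000 iterations by default), whose paired per-iteration scores yield a
   percentile interval and a two-sided p-value for the difference between
   models.
4. **Association analysis.** Cluster labels are related to per-patient
   binary clinical characteristics through 2×2 odds ratios (cross-product
   estimate, identical to the single-covariate logistic-regression OR), with
   a Wald interval in the regular case and an exact conditional test when a
   characteristic is rare (<5% of the cohort) or a cell is empty.

Because the registry data the method was developed for is not publicly
deposited, the package ships a synthetic-cohort generator whose planted
structure makes every stage testable end to end.

## The distance models

**Euclidean summary distance.** Patients have unequal numbers of visits, so
a fixed-length representation is needed before a Euclidean comparison. How
this reduction should be done is genuinely open; we adopt the per-patient
*mean* of the z-scored visits (a `stat = "median"` switch is provided). The
mean is the natural magnitude summary: it preserves the group-mean shifts
that define the high-cytokine group, and it is the maximum-likelihood
location estimate under the generator's Gaussian noise.

**Open-end multivariate DTW.** For patients $x$ and $y$ with visit vectors
$x_{\cdot,m}$ and $y_{\cdot,n}$, the DTW cost is

$$\min_{P} \sum_{(m,n)\in P}\ \sum_{k=1}^{17} (x_{k,m}-y_{k,n})^2,$$

minimised by dynamic programming over all monotone warping paths with steps
$(1,0)$, $(0,1)$, $(1,1)$, unweighted and unwindowed. Both series start
aligned at their first visits. With open ends (the default) the optimum is
taken over the last row *and* last column of the accumulated-cost grid, so
either patient's series may stop contributing early; this set of endpoints
is symmetric under swapping the two series, which is what hierarchical
clustering requires. Opening the *start* of a series is not permitted —
both patients enter the analysis at their baseline visit. The reported
distance is the raw minimised sum: no square root and no path-length
normalisation is applied, so longer, poorly matching series accumulate
larger costs. Ties between equal-cost paths are broken deterministically
(diagonal step first, then advancing the first series) so that the reported
alignment path is reproducible.

## Clustering and validity

Agglomerative clustering uses complete linkage by default (single and
average are offered); no linkage is canonical for this analysis, and
complete linkage is the default of the standard R implementation the field
uses. The "90% height" cut is interpreted as $0.9 \times$ the *maximum merge
height* — the dendrogram's total height, which is what a horizontal dashed
line at 90% of a plotted dendrogram corresponds to. The alternative reading
(90th percentile of merge heights) would not match that picture and is not
offered.

Two internal validity indices are implemented directly:

- **Connectivity** sums $1/j$ over every observation whose $j$-th nearest
  neighbour ($j \le L$, default $L = 10$) lies in a different cluster;
  0 means every neighbourhood is cluster-pure, and lower is better.
  Nearest-neighbour ties are broken by patient-id order so the index is
  deterministic.
- **Dunn index** is the minimal between-cluster point distance divided by
  the maximal within-cluster diameter; higher is better, and it is
  undefined (an error, not a number) when every cluster is a singleton.

Classical (metric) MDS is the standard double-centring eigendecomposition;
when fewer than two eigenvalues are numerically positive the embedding is
padded with zero coordinates under a warning. Isotonic (nonmetric) MDS
minimises Kruskal's stress-1 and is always initialised from the classical
solution, which makes it deterministic without any random restarts; stress
is reported as a fraction. Zero off-diagonal distances are nudged to a tiny
positive value (with a warning) because rank-based stress is undefined on
them. A `suggest_k()` scan tabulates silhouette, connectivity and Dunn
across candidate cluster counts; it is exploratory plumbing, not part of
the analysis path, which takes $k$ from the height cut.

## Regression design choices

- **Intercept.** Both models include an intercept. The conventional counts
  quoted for these designs (17 vs 35 free parameters) are inconsistent about
  it: 35 equals 34 coefficients *plus* the intercept, while 17 excludes it.
  Both designs here expose their full column counts (18 and 35) and the
  tests assert them.
- **Lagging.** The time-dependent design pairs each visit with the same
  patient's previous visit; each patient's first visit is dropped. No
  zero-filling and no cross-patient lagging is ever done — an imputed lag
  would manufacture information the registry does not contain.
- **Resampling unit.** The bootstrap splits *patients*, never visits:
  visit-level splitting would place visits of one patient on both sides of
  the split and leak patient identity into the test score. Whether the
  original analysis split by patient or by visit is not documented; the
  patient-level choice is the conservative one for clustered data.
- **Prediction scale.** Predictions are left on the continuous linear-model
  scale; residuals are not clamped or rounded even though observed
  SLEDAI-2k is a nonnegative integer.
- **Paired comparison.** `compare_models()` assumes the two score vectors
  came from the same seed, hence the same sequence of patient splits; the
  per-iteration differences then remove split-to-split variance. The
  two-sided bootstrap p-value carries a continuity floor of `1/n_iter` — a
  bootstrap cannot certify a p of zero.

## Association analysis

The odds-ratio point estimate is the cross-product ratio; for a single
binary covariate this is algebraically the logistic-regression estimate, so
no iterative fit is needed. The Wald interval is reported in the regular
case. The printed confidence intervals in published tables of this kind are
often *not* Wald intervals of the 2×2 (the methods behind them vary and are
rarely stated); we therefore treat interval methodology as unresolved,
report Wald explicitly by name, and make no claim of matching any
particular published interval. For rare characteristics (<5% of the cohort)
and degenerate tables the package switches to conditional exact inference
(hypergeometric tail-sum p, conditional maximum-likelihood OR) — the
single-covariate case of exact logistic regression. Zero cells produce
`Inf`/`0`/`NaN` sentinels rather than corrected estimates; a
Haldane–Anscombe +0.5 correction is available behind an explicit flag.

Per-patient biomarker–activity concordance is profiled by sign agreement of
consecutive-visit differences (a tie in both series counts as agreement,
because neither moved); the "synchronised fraction" this yields is one
reasonable formalisation of the published green/red concordance bars, whose
exact rule is not documented — we do not claim to reproduce figure-derived
percentages, and the per-patient Pearson correlation is reported alongside
as a scale-dependent complement.

## The synthetic registry generator

The generator is an *emulation* of the statistical structure the analysis
assumes, not a reproduction of any real cohort. Its defaults are the study
conditions used throughout the tests:

| Parameter | Default | Rationale |
|---|---|---|
| group sizes 1A/1B/2 | 69 / 32 / 9 | the subgroup sizes the analysis is designed around |
| visits per patient | uniform 5–11 | expectation ≈ 7.7, matching ≈ 843 visits across 110 patients |
| visit spacing | uniform 30–120 days | routine rheumatology follow-up cadence; only the order is used downstream |
| cytokine shift (group 2) | 2.5 z | clearly elevated MIF/CCL2/CCL19/CXCL10, the feature that defines the small group |
| sd inflation (group 2) | 2× | the small group is heterogeneous, not just shifted |
| concordance loadings (1A) | 0.6 × 17 | moderate shared loading of labs on latent activity |
| lag loadings (1A) | 0.2 × 17 | a real but not dominant one-visit carry-over effect |
| latent waveform | sinusoid (amp 1, 0.12 cycles/visit) + random walk (sd 0.35) | slow relapse–remission cycles plus irregular drift |
| tempo range | 0.5–2 | patients traverse the waveform at up to 4-fold different speeds |
| measurement noise | sd 0.5 | labs are noisy proxies of activity |
| SLEDAI-2k map | round(max(0, 4 + 1.5·latent)) | nonnegative integer score centred at the cohort-typical adjusted mean of 4 |
| outcome flags | flare OR 3.733 (baseline 0.65), damage 2.631 (0.49), high activity 5.492 (0.64), musculoskeletal 7.68 (0.07) | published-scale effect sizes for the discordant subgroup |

The latent trajectory is a random-phase sinusoid traversed at a
patient-specific tempo plus a Gaussian random walk. The walk is **centred
within each trajectory**: it models within-patient fluctuation, and leaving
its accumulated drift in place would hand every patient a persistent
baseline offset along the shared loading direction, destroying the
compact-Group-1 / separated-Group-2 geometry the generator exists to
emulate. The walk's increments — the dynamics — are unchanged by centring.

Binary outcomes are drawn per patient (they are "during observed period"
flags, not per-visit events): subgroup 1A and group 2 use the baseline
probability, subgroup 1B the probability solving the target odds ratio.

What the generator does **not** emulate: treatment effects and
medication-driven confounding, missing-data mechanisms (downstream code
rejects incomplete rows rather than imputing), assay floor/ceiling effects,
informative visit timing, and correlation *between* the 17 parameters beyond
what the shared latent induces. Passing the planted-structure tests
therefore shows the pipeline recovers the structure it is designed for — it
does not show that real registry data contains that structure.

## Numerical and degenerate-input conventions

- z-normalisation uses the pooled sample sd (n−1 denominator) over all
  visits of all patients; a constant column is zeroed with a warning rather
  than producing NaNs. Re-normalising an already normalised cohort is a
  precondition error, not a silent no-op.
- The DTW local-cost grid is computed by the outer-product identity and
  clamps tiny negative round-off at zero; identical series give costs below
  1e−10 rather than exact zeros.
- Subsetting a normalised cohort (for per-group regression) keeps the
  z-scores of the full cohort; values are deliberately *not* re-normalised
  within groups, so coefficients remain comparable across groups.
- Rank-deficient regression designs raise an error naming the aliased
  columns; inside the bootstrap, aliased coefficients are zeroed so a rare
  degenerate resample scores rather than aborts, and splits with no test
  rows are redrawn and counted.
- All stochastic entry points (`simulate_cohort()`, `bootstrap_error()`,
  `run_full_pipeline()`) take explicit seeds, restore the caller's RNG
  state, and reproduce byte-identical artifacts under the same seed.

## Problem sizes used by the checks

The package's validation suite exercises: exhaustive DTW path enumeration
on 500+ random series pairs of length ≤ 5; brute-force re-implementations
of connectivity, Dunn, linkage, adjusted Rand and the exact hypergeometric
test on 200+ random instances of n ≤ 15; 50 seeded 110-patient cohorts for
planted-group recovery; 20 + 20 seeded 69-patient cohorts (500 bootstrap
iterations each) for lag-structure detection and its type-I control; and
the full 7-stage pipeline run twice per seed for bit-reproducibility. These
sizes are the package's validation conditions; the analysis functions
themselves impose no such limits.

## Known limitations

- The open-end DTW cost is not a metric (no triangle inequality), and the
  raw summed cost grows with series length; clustering results therefore
  mix trajectory shape with observation length. This mirrors the analysis
  the package implements rather than a correctable defect.
- The height-fraction cut inherits the instability of complete linkage
  under outliers; `suggest_k()` is provided to inspect alternatives, but
  the default path deliberately reproduces the single-cut design.
- OLS with 35 parameters on small subgroups can be infeasible; the pipeline
  reports such subgroups as `NA` rather than regularising, since shrinkage
  would change the model class.
- Exact conditional inference on 2×2 tables is conservative, and the Wald
  interval is anti-conservative for small cells; both are reported with
  their method tag so downstream users can tell which was used.
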