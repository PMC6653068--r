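# lupustraj

Time-aware clustering and regression of longitudinal biomarker trajectories
in systemic lupus erythematosus (SLE).

## What problem this solves

SLE registry cohorts record, per clinic visit, 13 routine laboratory
parameters (with anti-dsDNA expressed as fold above the assay's upper limit
of normal), 4 serum cytokines (MIF and the type I interferon-inducible
chemokines CCL2, CCL19, CXCL10), and the SLEDAI-2k disease-activity score.
Disease activity fluctuates strongly over time and at different tempos in
different patients, so analyses that pool visits and ignore the time axis
can miss clinically meaningful patient subsets. `lupustraj` implements a
time-aware analysis pipeline for such cohorts, aimed at biostatisticians
and registry analysts:

- **Magnitude-based clustering** — per-patient mean z-score vectors,
  pairwise Euclidean distances, agglomerative (complete-linkage)
  clustering, and a cut at 90% of the dendrogram height, with internal
  validity scored by connectivity and the Dunn index and 2-D views from
  classical and isotonic MDS.
- **Tempo-aware clustering** — multivariate open-end dynamic time warping
  (DTW). For patients $x, y$ the distance is
  $\min_P \sum_{(m,n)\in P} \sum_k (x_{k,m}-y_{k,n})^2$ over monotone
  warping paths $P$ with steps (1,0), (0,1), (1,1); open ends let either
  series stop contributing early, so patients with similar courses at
  different speeds cluster together.
- **Time-agnostic vs time-lagged regression** — ordinary least squares of
  SLEDAI-2k on the current visit's 17 parameters (18 free parameters with
  intercept) or on current + previous visit (35 free parameters), validated
  by leave-one-patient-out (LOPO) cross-validation and compared by a
  patient-level 80/20 bootstrap with paired percentile intervals.
- **Association analysis** — 2×2 odds ratios of cluster labels against
  binary clinical characteristics (Wald interval; conditional exact test
  for rare characteristics or empty cells), plus per-patient
  biomarker/activity concordance profiles.
- **A synthetic registry generator** — planted patient groups (a compact
  concordant subgroup with lagged effects, a discordant subgroup, a small
  high-cytokine high-variance group) and per-patient outcomes with
  configurable odds ratios, so the whole pipeline is testable without
  access to real registry data.

## Worked example

```r
library(lupustraj)

# a 110-patient synthetic registry with a planted 9-patient high-cytokine group
sim    <- simulate_cohort(sim_config(seed = 42))
cohort <- z_normalize(filter_cohort(sim$cohort))

# magnitude-based clustering
dmat   <- euclidean_distance_matrix(summarize_patients(cohort))
labels <- cut_at_height_fraction(agglomerative_cluster(dmat), 0.9)
table(labels)
#> labels
#>   1   2
#> 101   9
connectivity(dmat, labels)      #> 4.035714
dunn_index(dmat, labels)        #> 0.7317644

# the cut isolates exactly the planted group
truth2 <- setNames(ifelse(sim$truth$labels == "2", "2", "1"),
                   names(sim$truth$labels))
truth_alignment_score(labels, truth2)
#> [1] 1

# does the previous visit add predictive information in the main group?
g1  <- subset_cohort(cohort, names(labels)[labels == 1])
sa  <- bootstrap_error(g1, "time_agnostic",  n_iter = 500, seed = 42)
sd_ <- bootstrap_error(g1, "time_dependent", n_iter = 500, seed = 42)
compare_models(sa, sd_)
#> mean MSE 3.67 (time-agnostic) vs 1.12 (time-dependent)
#> mean_diff 2.55, 95% CI [1.68, 3.41], p = 0.002
```

The clustering isolates the 9 planted high-cytokine patients from the 101
others (adjusted Rand index 1), the low connectivity / high Dunn values say
the two groups are cleanly separated, and the lagged model roughly threefolds
the out-of-sample accuracy because the generator plants a one-visit
carry-over effect.

Association of subgroup labels with clinical characteristics uses 2×2
counts; with the bundled worked-example counts for a concordant (n = 69)
vs discordant (n = 32) subgroup split:

```r
r <- odds_ratio(12, 20, 5, 64)   # musculoskeletal involvement, 1B vs 1A
r$or                              #> 7.68  (Wald CI 2.41-24.44, p 6e-4)
head(subgroup_odds_ratios(), 4)
#>   characteristic        or    ci_low  ci_high          p        method
#> 1         female 1.7818182 0.5362724 5.920268 0.34575008 wald_logistic
#> 2           male 0.5612245 0.1689113 1.864724 0.34575008 wald_logistic
#> 3      caucasian 0.4615385 0.1954030 1.090146 0.07787617 wald_logistic
#> 4          asian 1.8826531 0.8064803 4.394878 0.14354351 wald_logistic
```

`run_full_pipeline(pipeline_config(...))` chains all seven stages
(preprocess → magnitude clustering → per-group regression → lagged
regression → DTW clustering → per-subgroup regression → association) and
writes every intermediate artifact plus a machine-readable `report.json`;
the same seed reproduces every artifact byte for byte.

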