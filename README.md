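# cllstrat

Multi-factor stratification of chronic lymphocytic leukemia (CLL) donors
from mixed clinical and functional T-cell measurements, plus single-cell
motility metrics on micropatterned activating surfaces.

## The problem

T cells from CLL patients expand poorly and unpredictably ex vivo, a
practical obstacle for autologous cell therapies. No individual biomarker —
percent PD-1+ cells, micropattern alignment, IL-2 secretion, Rai stage,
age, sex, IgVH mutation status — cleanly predicts a donor's maximum
population doublings. `cllstrat` implements the multi-factor alternative:
stratify donors into groups from the joint factor table, and check that the
groups organise proliferative potential.

## The method

For a donor table **X** of p = 7 mixed-type factors (doublings held out as
the evaluation outcome):

1. **Imputation** — chained equations with predictive mean matching
   (pool k = 5, 10 sweeps, seeded); categorical targets use a logistic
   draw. Imputed values are always observed values.
2. **FAMD** — z-score numeric factors, mid-rank-then-z-score the ordinal
   Rai stage, weight each categorical level indicator by 1/√proportion and
   centre; SVD of the design matrix Z/√n gives eigenvalues λₛ, donor
   scores, and per-factor contributions ctr(j, s) = 100·Σ loadings².
3. **Factor selection** — combined contribution to Dim1+Dim2,
   ctr(j) = (ctr(j,1)λ₁ + ctr(j,2)λ₂)/(λ₁+λ₂); keep factors strictly above
   the equal-contribution threshold 100/p % (14.3% for p = 7).
4. **k-medoids** — Euclidean PAM on the selected factor columns; the
   cluster number comes from the elbow (maximum second difference of the
   cost curve, k = 1..8). Tiny instances (n ≤ 10) are solved exactly.
5. **Stability** — B = 500 bootstrap or 90%-subsample replicates of the
   entire analysis, cluster labels reconciled to the reference by
   exhaustive permutation search; per-donor assignment frequencies and a
   percentile interval for the Dim1+Dim2 variance share.
6. **Statistics** — permutation Kruskal–Wallis (tie-corrected H, add-one
   p-value, N = 10⁶), one-way ANOVA gating Tukey–Kramer pairwise
   comparisons, Welch/pooled t-tests, and the PD-1 low/high designation
   against the healthy donors' 95% interval.

The motility side computes, from centroid tracks on a square lattice of
2-μm activating features at 15-μm pitch: average speed before stopping,
the number of features crossed before the stop (distinct entry events into
encounter discs, interpolated between frames), and time to stop, where a
stop is ≥ 3 min of confinement within 2 μm while on a feature.

A synthetic-data module generates donor cohorts (three latent CLL groups +
healthy reference, truncated-normal readouts, MCAR missingness,
group-independent Rai stage) and persistent-random-walk trajectories with
per-encounter stop hazards, so the whole pipeline is testable end to end
without any external data.

## Worked example

```r
library(cllstrat)

cohort <- generate_cohort(seed = 42)
cohort
#> Synthetic donor cohort: 47 donors (42 CLL, 5 healthy), 11 missing cells

strat <- stratify_donors(cohort, k = "elbow", seed = 42)
strat
#> Donor stratification: 42 CLL donors in 3 groups
#> Dim1 + Dim2 variance: 45.0% (Dim1 23.2%, Dim2 21.9%)
#> Selected factors (> 14.3%): pd1_pct, alignment_pct, il2
#> group
#>  1  2  3
#> 15 16 11

stab <- resample_stability(cohort, scheme = "subsample90", B = 100,
                           reference = strat, seed = 42)
stab
#> Stability over 100 subsample90 resamples (100 used, 0 skipped)
#> Dim1+Dim2 variance 95% interval: 43.6-48.1%
#> Minimum modal-assignment frequency: 0.580 (donor D40)
```

Reading this: the first two FAMD dimensions carry 45% of the cohort's
variance; PD-1, alignment and IL-2 each contribute more than the 14.3%
equal-share threshold and drive the clustering; the elbow picks three
groups, renumbered so Group 1 has the highest mean doublings. Under
resampling most donors keep their group; the least stable donor (D40) sits
on a group boundary and keeps its modal group in 58% of subsamples — the
per-donor frequency table is in `stab$freq`.

Motility metrics work the same way from simulated (or imported) tracks:

```r
lat <- lattice()                       # 2 um features, 15 um pitch
trs <- simulate_trajectories(default_group_specs()[[1]], lat,
                             n_cells = 25, seed = 42)
summarize_motility(trs, lat)$summary
#>   donor_id pd1_label n_cells n_stopped speed_mean features_mean time_to_stop_mean
#> 1      D01   unknown      25        25          6          2.08              8.76
```

`run_pipeline(pipeline_config(...), "run_dir", seed = 1)` executes all
stages and writes one CSV per output plus a JSON manifest (config, seeds,
versions, checksums) that suffices to reproduce the run byte-for-byte.

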