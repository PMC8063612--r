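---
title: "Stratifying CLL donors from mixed T-cell measurements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying CLL donors from mixed T-cell measurements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cllstrat)
```

T cells from chronic lymphocytic leukemia (CLL) patients expand poorly ex
vivo, which matters directly for autologous cell therapies. No single
biomarker predicts which donor's cells will expand: PD-1 expression,
micropattern alignment, IL-2 secretion, Rai stage, age, sex and IgVH
mutation status each correlate weakly or non-monotonically with the maximum
number of population doublings a culture reaches. `cllstrat` implements a
multi-factor route to a single donor-level label: ordinate the mixed-type
factor table, keep the factors that dominate the first two dimensions,
cluster donors on those factors, and check that the grouping survives
resampling. The package also quantifies single-cell motility on
micropatterned activating surfaces, the assay behind the alignment factor.

This vignette explains each stage's model, its tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The donor table and its factor roles

One row per donor: identifiers (`donor_id`, `status`), two categorical
factors (`sex`; `igvh`, the immunoglobulin heavy-chain mutation status, a
CLL prognostic marker), one ordinal factor (`rai`, clinical stage 0–4,
defined only for CLL donors), and four numeric factors (`age_dx`, years at
diagnosis; `pd1_pct`, percent PD-1+ cells; `alignment_pct`, percent of
cells aligning with activating micropattern features; `il2`, secreted IL-2
in arbitrary fluorescence units). `max_doublings` is the outcome the groups
are evaluated against; it is never a clustering factor and never a
predictor during imputation, so the stratification cannot leak it. Missing
cells are allowed anywhere in the numeric CLL entries; a healthy donor's
Rai stage is structurally missing, not imputed.

## Imputation

`impute_cohort()` fills missing cells by chained equations. Each incomplete
column is regressed on all other factors (numeric plus indicator-coded
categorical; `max_doublings` excluded); for numeric targets the model
prediction selects the `pmm_k = 5` observed donors with the closest
predictions and one of their observed values is drawn (predictive mean
matching), so imputed values are always real observed values — percents
stay in [0, 100] and imputed Rai stages stay in {0..4} with no extra
machinery. Binary categorical targets use a logistic draw, falling back to
an observed-frequency draw (and logging it) if the fit fails. Ten sweeps
over the columns are ample for these small tables; the chain is seeded and
deterministic. One completed table feeds the pipeline (`m = 1`); `m > 1`
completions are available for sensitivity analysis, and the package's own
evaluation of imputation error averages the per-cell squared error over
`m = 10` completions so that a single unlucky donor draw does not dominate.

## Factor analysis of mixed data

`famd_preprocess()` builds the standard FAMD design matrix: numeric factors
z-scored; the ordinal Rai stage mid-rank transformed (ties get their
average rank) and then z-scored, so only its ordering matters; each level
of a categorical factor becomes an indicator column divided by the square
root of the level proportion and centred. This weighting gives every
factor, numeric or categorical, unit total inertia, so neither type
dominates the ordination. `famd_fit()` takes the SVD of the design matrix
divided by √n (population convention — the PCA cross-checks in the test
suite use the same convention); eigenvalues are squared singular values,
donor scores are projections on the right singular vectors, and a factor's
contribution to a dimension is its summed squared loading in percent.

Two numerical conventions are fixed for reproducibility: each dimension's
largest-magnitude loading is made positive (SVD signs are otherwise
arbitrary), and singular values below 1e-12 are reported as exactly zero
rather than failing on rank-deficient input. Contributions on
zero-eigenvalue dimensions are an arbitrary rotation of the null space and
should not be interpreted.

The combined contribution to dimensions 1 + 2 is the eigenvalue-weighted
average `(ctr1·λ1 + ctr2·λ2) / (λ1 + λ2)`. `select_factors()` keeps factors
whose combined contribution strictly exceeds `100/p` percent — the level a
factor would have if all p factors contributed equally; with the seven
donor factors the threshold is 14.3%. Strict inequality is a deliberate
choice (a factor exactly at parity carries no excess signal); with exactly
uniform contributions nothing is selected and the function directs the user
to the scree rather than silently clustering on everything.

## k-medoids grouping and the elbow

`pam_cluster()` clusters donors with Euclidean distance on the selected
(weighted, centred) factor columns. Tiny problems (n ≤ 10) are solved
exactly by enumerating every medoid subset: descent heuristics can stall in
swap-neighbourhood local optima even at n = 6 (we verified instances where
no single medoid exchange improves a suboptimal configuration), and
exactness is cheap there. Larger problems use classical deterministic PAM
(BUILD + SWAP) from the `cluster` package. The rule depends only on n, so a
cost-versus-k curve never mixes solvers, and exact optimal costs are
provably non-increasing in k. Assignments are recomputed as
nearest-medoid with ties to the lowest medoid index, making results a pure
function of the input row order; no seed is involved.

`elbow_select()` runs the cost for k = 1..8 and picks the k maximising the
discrete second difference `cost(k−1) − 2·cost(k) + cost(k+1)` — the
sharpest bend — with ties to the smallest k. `stratify_donors()` finally
renumbers groups by decreasing mean `max_doublings`, so "Group 1" is always
the most proliferative; downstream consumers never rely on raw label
identity (reconciliation handles that), the convention is purely for
readability.

## Resampling stability

`resample_stability()` repeats the whole analysis — re-imputation, FAMD,
factor selection, k-medoids — on B = 500 bootstrap samples (size n, with
replacement) or 90% subsamples (without replacement), reconciles each run's
arbitrary cluster labels to the reference assignment by exhaustive search
over the k! relabelings (ties to the lexicographically smallest
permutation), and reports how often each donor lands in each group among
the resamples containing it. k is held at the reference value: re-running
the elbow would make label reconciliation ill-posed across differing k.
Factor selection, in contrast, is re-run inside every resample, because the
resample must experience the same pipeline the original data did. A donor
drawn several times into one bootstrap sample contributes a single
assignment (its first sampled row); resamples in which a selected factor
degenerates are skipped and counted.

Two behaviours of this design are worth knowing. First, bootstrap
resampling perturbs the eigenstructure enough that, when only three of
seven factors are informative, the factor *selection* occasionally differs
from the reference — the signal's second eigenvalue (at most 1.5 when three
unit-inertia factors span two dimensions) overlaps the largest of the noise
eigenvalues at cohort sizes of 40–60 — and those resamples can move a few
boundary donors. With the factor set held fixed we observe no flips at all,
so assignment instability under bootstrap is essentially selection
instability. The 90% subsampling scheme perturbs the spectrum far less and
is correspondingly stabler. Second, the percentile interval for the
Dim1 + Dim2 variance share is an *upward-shifted sampling band*, not a
bias-corrected population statement: the top-two eigenvalue share is
upward-biased at cohort scale (sampling variance concentrates in the top
eigenvalues), and resampling n-from-n compounds the effect, so the interval
brackets values at and above the cohort's own estimate. Interpret it as
"how much the estimate moves under resampling", which is also all a
percentile bootstrap can promise here.

## Group statistics

`kruskal_wallis_perm()` computes the tie-corrected Kruskal–Wallis H and a
permutation p-value over N = 1e6 random label permutations by default,
chunked so memory stays modest. The add-one correction
`p = (1 + #{H* ≥ H}) / (1 + N)` keeps p strictly positive, as a permutation
p-value must be. Because H is rank-based, the p-value is invariant under
monotone transformation of the data. `anova_tukey()` gates on one-way
ANOVA at α = 0.05 and reports Tukey–Kramer adjusted pairwise p-values
(unequal group sizes supported) with tier markers at α ∈ {0.05, 0.005,
0.0005, 0.0001}. `ttest2()` defaults to Welch's unequal-variance form with
a pooled-variance option. `pd1_designation()` labels a donor "high" only if
its PD-1+ percentage exceeds the healthy donors' 95% interval; the default
reads that interval as the confidence interval of the healthy *mean*
(t multiplier), with a reference-range reading (mean ± 1.96 SD) available
because the phrase is genuinely ambiguous; boundary values classify as
"low".

## Motility on micropatterned lattices

The lattice is a square array of circular activating features (default
2 μm diameter at 15 μm pitch). A cell encounters a feature when its contact
footprint can overlap it, so the encounter radius is the feature radius
plus a cell contact radius (default 4 μm, a typical T-cell footprint);
defaults keep encounter discs disjoint. Paths between frames are linearly
interpolated, so a fast cell cannot tunnel through a feature between
samples.

A *stop* is a cessation of overall motion for longer than 3 minutes while
on a feature: the earliest frame whose whole forward window of
`stop_min_duration = 3` min stays within `stop_tolerance = 2` μm (one
feature diameter) of the window's first position, that position lying
inside an encounter disc. Pauses shorter than the window, and confinement
away from any feature, are not stops (off-feature confinement is reported
separately). Average speed is the mean frame-to-frame displacement over
frames strictly before the stop onset. Features crossed counts distinct
entry events into encounter discs before the stop, excluding the stop
encounter itself; re-entering the same feature counts again, and starting
on a feature counts as an encounter at time zero — whether re-encounters
should count separately is not determined by the assay description, so the
distinct-entry-event rule is a documented choice. Cells that never stop are
censored for time-to-stop, never imputed. The lamellipodia inclusion
criterion is not computable from centroid tracks and enters as a per-track
flag.

## What the synthetic generator emulates

`generate_cohort()` draws donors from three latent CLL groups plus a small
healthy reference, using truncated normal distributions
(resample-until-valid, so bounds carry no point mass). The default group
means encode the qualitative orderings the stratification is designed to
recover — maximum doublings Group 1 > Group 2 > Group 3, alignment peaking
in Group 2, PD-1 ordered differently from doublings, IL-2 ordered like
doublings — with healthy doublings at 5.5 ± 0.4 (n = 5). The exact means
are configuration values, not estimates of any real cohort; cohort size
defaults to 42 CLL + 5 healthy donors, in the middle of the intended
range, since no donor counts per group are fixed by the study design. Rai
stage is drawn independently of the latent group (the stratification
assumes no Rai–proliferation dependence, and the independence makes "Rai is
uninformative" a testable property), as are sex, IgVH and age. Missingness
is completely at random, on numeric CLL cells only, at 5% by default —
nothing in the emulated assay suggests an informative mechanism, though
real missingness may well be informative.

Trajectories are constant-speed persistent random walks (heading diffusion
with persistence time per group); on each entry into an encounter disc the
cell halts permanently with a per-group hazard, settling onto the feature
centre with sub-tolerance residual jitter. This is the minimal motility
model consistent with speed/persistence coupling; it makes no mechanistic
claim. Ideal centroid tracks only: no imaging noise, pixelation,
segmentation error, cell shape, or cell–cell interaction. Passing tests on
this generator therefore demonstrate that the pipeline recovers structure
*of the kind it assumes*, not that real donor data contain such structure.

## Problem sizes and determinism

The test suite exercises the pipeline at the scales the methods are meant
for: cohorts of 40–60 CLL donors, B = 40–200 resamples in unit tests and
B = 100–500 in the end-to-end script, permutation tests at N = 999 for
calibration studies (2,000 null simulations) and N = 1e6 for single
analyses, and 100–250 simulated cells for geometric and hazard checks.
Every stochastic stage takes an explicit integer seed; the pipeline derives
per-stage seeds from one global seed by stage-name hashing, so enabling or
disabling one stage never perturbs another's random stream, and a run
directory's manifest (configuration, seeds, versions, checksums) suffices
to reproduce it exactly.

## Known limitations

- The equal-contribution selection is intrinsically noisy near the
  threshold at cohort sizes of 40–60; bootstrap stability reports inherit
  that noise by design (see above). Well-separated groups are recovered
  perfectly, but selection-set churn is visible in resampling output.
- The Dim1 + Dim2 variance share is upward-biased at these n, and the
  bootstrap interval shares the bias.
- PAM above n = 10 is a descent heuristic; its cost can exceed the global
  optimum on adversarial configurations (it provably cannot happen for
  n ≤ 10, where the solver is exact).
- The imputation model is linear/logistic; strongly non-linear
  factor relationships would be imputed poorly.
- Tukey–Kramer p-values assume approximate normality within groups; the
  permutation Kruskal–Wallis path is the distribution-free alternative.
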