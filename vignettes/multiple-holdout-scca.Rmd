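---
title: "Rank-weighted sparse CCA under multiple hold-out validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-weighted sparse CCA under multiple hold-out validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mhscca` implements a doubly-multivariate analysis linking high-dimensional
functional-connectivity features to a small set of psychiatric symptom
scales in multi-site developmental cohorts. The question it answers is not
only "is there a linked brain–behavior dimension?" but "does that dimension
survive projection onto sites — and cohorts — the model never saw?". This
vignette explains the model, the validation machinery, the synthetic cohort
generator the test suite runs on, and the numerical and design choices that
were genuinely open.

## The model

Given a brain block $X_{n \times k}$ (principal-component scores of
connectivity edges) and a behavior block $Y_{n \times q}$ ($q = 8$ syndrome
sum scores), sparse CCA seeks loading vectors $u$ and $v$ maximizing the
cross-block covariance of the canonical variates $Xu$ and $Yv$ subject to

$$\|u\|_2 = \|v\|_2 = 1, \qquad
  \|u\|_1 \le c_x\sqrt{k}, \qquad \|v\|_1 \le c_y\sqrt{q},$$

with $c_x, c_y$ on a 0–1 grid. The combination of a unit $\ell_2$ ball and
an $\ell_1$ budget is the elastic-net-style constraint set of the penalized
matrix decomposition: the $\ell_1$ budget drives coordinates of the loading
vectors to exactly zero, which is what makes an 8-dimensional behavior
loading readable. The behavior-side grid value is constrained to exceed
0.5 so the symptom loadings stay dense enough to interpret.

`scca_fit()` realizes this by alternating soft-thresholded power
iterations on the cross-covariance $C = X^\top Y/(n-1)$:
$u \leftarrow \mathcal{S}(Cv, \delta_u)/\|\cdot\|_2$, then symmetrically
for $v$, where each threshold $\delta$ is solved exactly (sorted segments
plus a closed-form quadratic, Newton-polished) so the $\ell_1$ constraint
is active precisely when it binds. Iteration starts from the leading
singular pair of $C$ and stops when the largest loading change falls below
`1e-6` (at most 200 sweeps; non-convergence is a warning and a flagged
component). Further components are extracted after deflating the rank-one
term $d\,uv^\top$ from the cross-covariance — deflation on the
cross-covariance rather than on the data keeps components comparable
across penalty settings. Columns are sign-fixed so each loading's
largest-magnitude entry is positive; because that convention leaves the
*relative* orientation of a $(u, v)$ pair arbitrary, cross-repetition
summaries align every repetition to a non-negative training correlation
and apply the same (training-determined) flip to its test correlation.

When the $\ell_1$ bound mapped from a grid value falls below 1 — which no
unit vector can violate meaningfully — it is clamped to 1, the maximally
sparse vertex, so the whole printed grid is usable rather than erroring.

## Rank-based weighting before PCA

Plain PCA summarizes the connectivity block without looking at behavior.
To tilt the retained subspace toward subjects with the phenotype of
interest, each subject is ranked by their total symptom score (rank 1 =
highest burden; ties get average fractional ranks) and receives the
pre-weight

$$\tilde w_i = \ln n - \ln r_i,$$

normalized to $w_i = \tilde w_i / \sum_j \tilde w_j$. The least symptomatic
subject gets pre-weight exactly zero. Columns of the residualized
connectivity matrix are demeaned (unweighted means — the weighted variant
sits behind a flag, as the defining phrase "demeaned and adjusted with the
normalized weights" does not pin the centering down), rows are scaled by
$w_i$, and the eigenvectors of the scaled matrix are extracted by SVD.
Scaling rows by $w_i$ rather than $\sqrt{w_i}$ follows the same literal
reading; the $\sqrt{w}$ variant (under which the spectrum estimates a
weighted covariance) is available via `row_scale = "sqrtw"`. The rank
*direction* is likewise a choice: descending (most symptoms, largest
weight) matches the scheme's purpose and is switchable.

Held-out data are projected onto the training eigenvectors with no
re-centering: residuals are near-zero-mean by construction, and
re-centering by training means would be a second, unnecessary contact
between test data and training statistics.

The default of $k = 100$ retained components mirrors the scale of the
original design (100 PCs from 60,726 edges); 50 and 200 are exposed for
sensitivity analyses, and the synthetic studies in this package use
$k = 10$–$20$ against $p = 60$–$150$ features, keeping the same ratio
regime at desk scale.

## The multiple hold-out framework

`run_multiple_holdout()` repeats, for each of `n_reps` (default 30)
repetitions:

1. sample `n_test_sites` (default 3 of 21) sites as the held-out set —
   uniformly, independently across repetitions, so a site can recur in
   different test sets (`make_disjoint_folds()` provides the
   no-repetition 5-fold variant used as a sensitivity arm);
2. residualize the brain features of the training and test sets
   *separately*, each on its own covariates (age, sex, categorical
   education), so no regression coefficient crosses the split;
3. compute rank weights from the *training* symptom totals, fit the
   weighted PCA on training residuals, and project both sets;
4. select the penalty pair by an inner resampling search: 100 random
   80/20 splits of the training set, each pair scored by the mean first
   canonical correlation on the inner validation sets; ties break toward
   the sparser pair, brain side first;
5. fit the sparse CCA on the training blocks, project loadings onto the
   test blocks;
6. test significance by permutation in both sets: training sets *refit*
   the model to row-shuffled behavior (same penalties), test sets
   *re-project* fixed loadings. The test-set choice is deliberate — a
   refit on test data would itself be a training step and would breach
   the full train/test separation.

P-values use the add-one estimator $p = (1 + b)/(B + 1)$ on the
two-sided exceedance $|r_{\text{null}}| \ge |r_{\text{obs}}|$ (raw
one-sided exceedance sits behind a flag), with Benjamini–Hochberg FDR
across the tested components. Only components whose share of total
absolute cross-block covariance exceeds the mean share are carried into
permutation testing; a component is "validated" in a repetition when its
test-set $q < 0.05$.

The inner 80/20 resampling is drawn at the subject level without site
stratification, and permutations shuffle behavior rows globally rather
than within site — in both cases the plainer reading of the procedure.

`bootstrap_stability()` quantifies sampling variability: subjects are
resampled with replacement, the model is refitted with the reference
penalties, and each bootstrap solution is aligned to the reference by the
one-to-one assignment of components maximizing total $|\cos|$ between
behavior-side loading columns (solved exactly by enumeration, $d \le 8$),
with signs flipped so matched cosines are non-negative. The same matcher
aligns components across cohorts and across repetitions
(`mean_feature_loadings()`).

## Out-of-study generalizability, two ways

`gold_standard_test()` projects every repetition's full training chain —
eigenvectors, then canonical loadings — onto an independent target cohort
that has been residualized only on its own covariates, and assesses the
resulting external correlations with project-mode permutations. Nothing of
the target ever touches the source fit.

`qualitative_replication()` instead trains independently in each cohort
with a shared penalty pair (typically `most_selected_penalties()` of the
source run), matches components across cohorts on the behavior loadings,
and correlates cross-projected variate scores with natively trained ones
in both directions, each correlation tested by permutation (default
$B = 5000$). A component is flagged generalizable only when both
directions are significant. The flag is based on the behavior-side score
correlations — behavior is the view whose scale is shared across cohorts
and the side on which components are matched; brain-side correlations are
computed and reported alongside. The two procedures answer different
questions, and the package's regression tests include a construction
(shared behavior loadings, disjoint brain supports) on which replication
succeeds while the gold-standard projection finds nothing — the
qualitative and gold-standard notions of external validity genuinely
dissociate.

## The synthetic cohort generator

Real multi-site cohorts of this design are access-restricted, so the test
suite runs end-to-end on `simulate_two_view()`. Per planted component, a
pair of standard-normal latent scores with the configured correlation
drives both views: the brain view adds sparse unit-norm loadings
(disjoint supports across components, hence exactly orthogonal), per-site
feature shifts, linear covariate effects, and Gaussian noise; the symptom
view adds covariate effects and noise to its latent block and then passes
through a monotone shifted-exponential transform rounded to non-negative
integers, reproducing the zero-inflated right skew of caregiver-reported
syndrome scales (means well below SD × range). Site effects touch only
the brain view (scanner-driven); covariates touch both, so residualization
is a non-trivial step to test. The truth slot stores the loadings, latent
scores, and the pre-transform symptom matrix — the count transform
attenuates Pearson correlations by a known lognormal factor, so planted
correlation checks are made against the latent matrix.

Default scales — `noise_sd = 0.5`, `site_effect_sd = 0.25`,
`covariate_effect_sd = 0.25` — were fixed once, a priori: at the studied
$n/p$ ratios the planted signal eigenvalue $1 + \sigma^2$ must clear the
Marchenko–Pastur edge of the noise spectrum for PCA to retain the signal
direction, which $\sigma = 0.5$ satisfies comfortably while leaving the
problem non-trivial, and the site/covariate scales produce between-site
and demographic variance fractions of the order seen in multi-site
pediatric imaging.

What the generator does *not* emulate: hemodynamics and temporal
autocorrelation, scanner-specific artifact structure, non-linear
brain-behavior links, longitudinal drift, and site-by-covariate
confounding. Passing tests therefore certify the statistical machinery —
leakage-free validation, calibrated inference, recoverability of planted
sparse structure — not the effect sizes to be expected in any real cohort.

## Numerical choices and degenerate inputs

- Correlations are clipped to $1 - 10^{-7}$ before the Fisher transform,
  keeping self-similar edge pairs finite.
- Constant residual time series, rank-deficient confound or covariate
  designs, unseen factor levels at transform time, zero-variance loading
  updates (over-thresholding), and infeasible loading sparsity all raise
  errors naming the offending object; zero-variance features in
  `edge_contributions()` degrade to a warning and contribution 0.
- All randomness flows from explicit seeds; nested stages draw derived
  sub-seeds so that, e.g., mutating held-out rows cannot shift the
  training stream (the leakage metamorphic tests assert byte-identical
  serialized training fits).
- CBCL-style scoring prorates a scale as mean of answered items × scale
  length when fewer than 25% of its items are missing, and flags it
  unavailable otherwise; a subject with more than 25% overall missingness
  is flagged for exclusion. Proration by mean × length is the standard
  reading of "accounting for missing items".
- Motion QC uses strict inequalities (mean FD > 0.25 mm, or > 20% of
  volumes with FD > 0.2 mm), so boundary subjects are retained.
- Module z-scores in `aggregate_modules()` are computed over the unique
  module cells (upper triangle including the diagonal) within one
  dimension; aggregation sums absolute contributions so opposing-sign
  edges cannot cancel (a signed variant is a flag away), and the top-20%
  mask is taken over all edges globally.

## Problem sizes used in the shipped studies

The test suite and `scripts/acceptance.R` exercise the pipeline at
$n = 240$–5000 subjects, $p = 30$–150 brain features (plus one
$p = 3000$ spectrum check), 4–10 sites, 2–5 repetitions, inner searches
of 8–20 resamples over reduced grids, and 50–500 permutations or
bootstraps per test — sizes chosen so each study still has the power to
discriminate its hypothesis while the whole suite runs on one CPU in a
few minutes. The full-scale defaults (30 repetitions, $k = 100$, 100
inner splits, $B = 2000$ permutations, $B = 1000$ bootstraps, $B = 5000$
replication permutations) remain the package defaults.

## Known limitations

- The alternating scheme converges to a stationary point; for strongly
  non-sparse optima under tight bounds it can, like any penalized power
  iteration, stop at a local solution. The brute-force mesh comparisons
  in the tests bound this risk at small scale.
- Classical CCA (`classical_cca()`) requires full-rank within-view
  covariances and more observations than total variables; it exists as
  the unpenalized sensitivity arm, not as the workhorse.
- The component matcher enumerates permutations and is intended for
  $d \le 8$ components.
- `run_multiple_holdout()` parallelism is left to the caller (the
  repetitions are independent); the implementation is deliberately
  single-threaded and deterministic.
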