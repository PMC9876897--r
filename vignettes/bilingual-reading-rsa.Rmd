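---
title: "Relating reading-component dissimilarity structure to local fMRI pattern geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating reading-component dissimilarity structure to local fMRI pattern geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the approach

Readers of a logographic script (Chinese characters), an alphabetic
script (English), and a phonetically transparent script for the same
spoken language (Chinese pinyin) engage visual, phonological and
semantic processing in different mixtures. `readrsa` implements a
representational similarity analysis (RSA) pipeline that asks, voxel by
voxel, *which linguistic component's* dissimilarity structure a local
neural pattern carries, separately for each writing system — and then
quantifies, classifies and correlates the resulting per-region
"cognitive loads".

The pipeline has six stages, each a package module exercised by a
numbered script under `analysis/`:

1. **Synthetic data** (`simulate_dataset`): the study design —
   3 conditions × 40 trials of trial-wise beta volumes per subject — with
   representational geometry planted at known effect sizes.
2. **Behavioral RDMs** (`build_behavioral_rdm`): three model
   dissimilarity matrices per writing system.
3. **Searchlight RSA** (`searchlight_map`): partial Spearman correlation
   of each 6-mm sphere's neural RDM with each behavioral model,
   controlling the other two; Fisher r-to-z.
4. **Group inference** (`one_sample_t_map`, `cognitive_load`,
   `overlap_map`): one-tailed t maps with cluster-extent thresholding,
   per-subject load summaries, cross-language overlap.
5. **Classification** (`loso_svr_foldwise`, `rfe_rank_and_select`):
   leave-one-subject-out SVR on (region, component) loads with
   fold-specific masks, plus absence-rMSE recursive feature elimination.
6. **Association** (`rm_anova_two_way`, `load_rt_partial_correlation`):
   repeated-measures ANOVA on loads and partial correlations with
   adjusted reaction times.

## Behavioral dissimilarity models

Each stimulus is decomposed three ways:

* **Logo-grapheme units** — the smallest semantically indivisible visual
  units of a Chinese character; single letters (plus tone symbols) for
  pinyin and English. Dissimilarity between two stimuli is one minus the
  overlap ratio,
  $$d(a, b) = 1 - \frac{s}{|a| + |b|},$$
  where $s$ is the multiset intersection (each repeated unit counts with
  its multiplicity, each matched pair counts once). A 6-unit and a
  5-unit word sharing 2 units give $1 - 2/11 = 0.818$; two 6-unit pinyin
  transcriptions sharing one unit give $1 - 1/12 = 0.917$. Note the
  formula assigns $0.5$, not $0$, to identical multisets; RDM diagonals
  are forced to zero by convention and excluded from every analysis, so
  only the off-diagonal ordering matters.
* **Phonetic units** — initials, finals and tones (position-free) for
  Chinese words and pinyin; vowels and consonants for English — scored
  with the same overlap formula.
* **Semantic embeddings** — word vectors consumed as inputs (the
  upstream corpus training is provenance, not computation); dissimilarity
  is one minus cosine similarity, in $[0, 2]$.

Unit tokens are compared by string equality after Unicode NFC
normalization, because decompositions arrive as text and the same
diacritic can be encoded two ways.

## Searchlight partial rank correlation

For every voxel inside the analysis mask (after discarding voxels whose
across-trial SD is below 1/8 of their absolute mean response — the
"variation" in that rule is not defined more precisely upstream, and SD
is the reading used here), the 6-mm sphere (boundary inclusive; on a
2-mm grid, the 123 lattice offsets with $i^2+j^2+k^2 \le 9$) provides a
voxels × trials pattern matrix. The neural RDM is one minus Spearman's
rho between trial patterns. Each behavioral model is then tested by
partial Spearman correlation: lower triangles are vectorized
($m = n(n-1)/2 = 780$ pairs at $n = 40$), rank-transformed with average
ranks on ties, and the partial Pearson correlation of the ranked neural
vector with the ranked target given the two ranked controls is computed
by residual regression. The one-tailed p for a positive correlation uses
the t approximation with $m - 2 - k$ degrees of freedom; a permutation
alternative (joint row/column shuffles of the neural RDM, `perm = N`) is
available for small runs. Correlations pass through Fisher's
$z = \operatorname{atanh}(r)$ before any averaging across subjects.

Spheres with fewer than 10 in-mask voxels are skipped (rank correlations
over a handful of voxels are unstable; the value is `NaN` and counted in
a log message). At a radius below the voxel size every sphere degenerates
to a single voxel and the whole map is `NaN` — the documented degenerate
case. Because every step from betas to p-values is rank-based, the maps
are invariant under any strictly increasing transform of the betas and
under relabelings that permute trials and RDM rows together; both
invariances are asserted in the test suite.

Subject-level significance keeps voxels with $p < 0.05$ in connected
clusters strictly larger than 10 voxels. Cluster connectivity defaults
to 18 (faces + edges), configurable to 6 or 26; 18 is the convention of
the software family this analysis style comes from.

## Cognitive load and group inference

A subject's *cognitive load* for one (condition, component) is the sum
of Fisher-z values over their significantly positive voxels — and the
voxel count is carried alongside as the validation variant, so the
robustness check is free. Loads are non-negative by construction
(one-tailed positive significance) and exactly zero when the mask is
empty.

Group maps are voxel-wise one-tailed one-sample t-tests across subjects
($p < 0.05$ uncorrected, cluster $> 10$, applied with the same strict
inequality as at the subject level). Cross-language overlap is the
voxel-wise AND of two group significance masks, summarised per atlas
region with peak coordinates mapped through the affine (the peak is the
voxel with maximum t in the cluster — "peak" is not defined upstream, so
this choice is recorded on the output). The subsampling stability check
redraws subject subsets and correlates the 9-cell group load profile
with the full-sample profile. The age-of-acquisition comparison uses a
permutation test whose statistic — the difference in group-map
significant-voxel extent, each group's map computed from its own
subjects — is an assumption (the upstream description names no
statistic) and is flagged in the output.

## Classification and feature elimination

Each subject contributes three samples (one per condition), with one
feature per (region, component): the sum of the subject's z values
inside the region intersected with the component's group significance
mask. With 30 regions this is the 90-dimensional feature vector; the toy
atlas default gives 10 × 3 = 30. Labels are ordinal integers (Chinese
word 1, English word 2, pinyin 3). Cross-validation is
leave-one-subject-out, and the group masks are rebuilt per fold from the
training subjects only — the held-out subject's features use the
training-derived mask, and a mutation test asserts that corrupting the
held-out maps changes nothing on the training side.

The SVR is linear with cost 1 and epsilon 0.1, features standardized on
the training fold; these hyperparameters are fixed (no nested search) to
keep the model deterministic and the feature elimination interpretable.
Regression outputs are mapped to the nearest valid label. For the
recursive feature elimination the protocol switches to a unified
(all-subject) mask and leave-one-sample-out validation: each feature's
importance is the rMSE incurred by its absence; features are removed one
by one in ascending absence-rMSE order, negative rMSE is recorded at
every remaining-feature count, and the knee of that curve — the point of
maximum perpendicular distance from the chord joining the endpoints,
after normalizing both axes — selects the feature count. A curve that
never deviates from its chord by more than the flatness tolerance
(0.02 normalized) is reported as having no informative knee. Ties in
absence-rMSE break by feature name for determinism.

## Loads, behavior, and their association

The two-way repeated-measures ANOVA (condition × component, both within
subject) uses the classical error strata; sphericity is assumed by
default, matching the upstream analysis, with a Greenhouse–Geisser
option behind `gg = TRUE`. Post hoc contrasts are paired t-tests between
components within each condition, Bonferroni-corrected over the whole
9-test family (the family size is recorded in the table).

Adjusted reaction times remove additive subject offsets: a fixed-effects
fit of RT on condition plus subject, with the sum-to-zero subject
effects subtracted. In the balanced complete case this is exactly
subject-mean-centering plus the grand mean. The unshrunken fixed-offset
form was chosen over random-intercept BLUPs deliberately: shrinkage
would leave a fraction of each subject's offset in the adjusted values,
whereas the fixed form removes it entirely (up to a common constant that
no correlation downstream can see).

The load–RT association is, per (condition, component), the partial
Pearson correlation across subjects between load and the condition's
adjusted RT, controlling the other two components' loads in the same
condition. The control set is an assumption (only "partial correlation"
is specified upstream) and is written into every output row, as is the
Bonferroni family (default 3, the components within a condition).

## The synthetic-data generator

Real trial-wise betas for this design are not publicly available, so the
generator is a first-class module: every acceptance-level claim about
the pipeline is a parameter-recovery claim against planted truth.

For each (region, condition, component) entry of the effect map, the
target behavioral RDM is embedded into a latent configuration by
classical metric MDS with $\min(10, n-1)$ dimensions (a non-metric,
rank-preserving embedding is the logged fallback when the RDM is too
non-Euclidean for `cmdscale`); the axes keep their eigenvalue scaling,
since whitening them would destroy the embedded distance geometry. Each
in-region voxel receives a random linear readout of the latent
coordinates, standardized, and is mixed with white noise:
$x = \sqrt{\lambda}\,s + \sqrt{1-\lambda}\,\varepsilon$. The expected
rank correlation between the local neural RDM and the target is an
increasing but analytically intractable function of $\lambda$, so
$\lambda$ is calibrated by bisection against a 200-draw Monte-Carlo
estimate (common random numbers, tolerance ±0.05) at the sphere size of
the analysis radius. Targets above the geometry's achievable ceiling
(rank correlations cannot reach 1 through a noisy embedding of a
tie-heavy overlap RDM) clamp $\lambda$ at 1 with a warning; monotonicity
in the requested effect size is preserved and tested at
$r \in \{0, 0.3, 0.6, 0.9\}$. Between-subject variability scales
$\lambda$ proportionally (SD `subject_sd`).

Out-of-region voxels are white noise. The mask is the union of the atlas
regions and a compact background block (default 500 voxels) — a block
rather than scattered voxels so that searchlights centred there are
valid and the false-positive behaviour of the pipeline can be measured
on it. Reaction times are log-normal with condition means ordered
Chinese word < English word < pinyin (750/900/1050 ms) and a subject
random offset on the log scale; accuracy is binomial at p = 0.98,
emulating the ceiling performance typical of an implicit reading task.
Identical config and seed reproduce the dataset bit for bit.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: no BOLD time series, HRF convolution
or first-level GLM (betas are emitted directly); no spatial noise
correlations or physiological artifacts (noise is white, so real-data
smoothness is only partially mimicked by sphere overlap); no anatomical
geometry (the toy atlas is spherical blobs on a small grid); and no
built-in coupling between loads and reaction times, so the association
stage on synthetic data measures calibration rather than recovery.

## Problem sizes and numerical choices

The shipped analysis runs 20 subjects on a 20×20×20 2-mm grid with 10
regions and 40 trials per condition — rich enough that every stage has
structure to find, small enough to run end to end in minutes on one CPU.
The test suite uses the same generator at reduced sizes (typically 11³
or 12³ grids, 10–15 trials, 2–20 subjects), sizes chosen as the smallest
at which the tested property is not noise-dominated.

Numerical conventions worth knowing: RDM symmetry is enforced to 1e-10
and diagonals forced to zero; Fisher z clamps |r| ≥ 1 to ±(1 − 1e-7)
with a warning; residual norms at numerical zero (relative 1e-8) are
treated as fully-explained variables (partial correlation 0) rather than
producing 0/0 noise; the zero-variance ANOVA limit reports F = 0, p = 1;
and a zero across-subject SD in a t map produces an infinite-t sentinel
with p = 0 or 1 by the sign of the mean.

## Known limitations

The uncorrected p < 0.05 & cluster > 10 regime is intentionally
faithful to the upstream analysis and intentionally lenient: searchlight
maps are smooth (neighbouring spheres share most voxels), so a small
isolated region can cross the voxel threshold wholesale by chance and
the extent rule gives little protection — visible in the shipped run as
modest spurious group clusters alongside the planted ones. The
parametric p for partial Spearman treats the 780 RDM pairs as
independent, which they are not exactly; the measured null rejection
rate is close to nominal (≈ 0.053 at 4000 draws) but the permutation
option exists for exactness. Finally, achievable planted effect sizes
are bounded by the embedding ceiling of each behavioral RDM; requests
above the ceiling are clamped, not met.
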