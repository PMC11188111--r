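---
title: "Methods: linking in-scanner experience reports to resting-state connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking in-scanner experience reports to resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures the package implements, the
choices made where the methodology left the design open, and what the
synthetic-data module does and does not emulate.

## The scientific setting

Resting-state fMRI scans are acquired without a task, and participants'
inner experience during the scan — whether they thought in images or words,
about themselves or others, with positive or negative valence — is usually
unmeasured. The pipeline implemented here asks three questions of a dataset
in which every scan is annotated with a short retrospective questionnaire
(11 items on thought form and content plus one wakefulness item, each scored
0–100):

1. Do participants return to similar thought patterns across repeated scans?
2. Do scans that differ systematically in thought content show significant
   differences in functional connectivity (FC)?
3. Can FC predict individual experience scores?

The package provides every analysis stage as a tested function, and a
synthetic-data module that generates data with the statistical structure the
analysis assumes, so the full pipeline runs and is verifiable without any
restricted data.

## Bounded confound-aware factorization

Questionnaire responses `M` (scans × items, entries in [0, 100]) are
decomposed as

    M ≈ [W, C] · [Q, Qc]′

where `W` (scans × d, entries in [0, 1]) holds per-scan loadings on `d`
latent thought patterns, `C` is a known scans × 5 confound matrix (an
intercept, a 2-bit binary encoding of the ordinal age bin, and a one-hot
gender encoding), and `Q`, `Qc` (items × d and items × 5, entries in
[0, 100]) carry item weights. The fit minimises

    ‖M − [W,C][Q,Qc]′‖²_F + β_W‖W‖₁ + β_Q(‖Q‖₁ + ‖Qc‖₁)

subject to the box constraints. Non-negativity plus bounds makes the
loadings directly interpretable (a scan's position along each thought
pattern), which is why this model class is preferred over PCA for bounded,
non-Gaussian response data.

**Optimizer.** The reference implementation of this model class uses ADMM
with stochastic gradients. This package instead uses deterministic
column-wise block descent (HALS-style): with all but one factor column held
fixed, the objective is an elementwise separable box-constrained quadratic,
so each column update is an exact minimisation — the least-squares solution
shifted by the L1 weight and clipped to its box. Every update is therefore
guaranteed not to increase the objective, the whole fit is reproducible
bit-for-bit, and the monotonicity of the objective trace is asserted in the
test suite. The objective and constraints are identical to the reference
formulation; only the optimisation route differs.

**Identification of the W/Qc split.** The free per-scan loadings `W` can
imitate any column of `C`, so the attribution of shared structure between
`W` and the confounds is only identified through the L1 penalty on `W`
(moving C-explainable structure from `W` into `Qc` preserves the fit and
saves β_W·‖W‖₁). Block descent cannot migrate structure between the two
blocks once settled, so `fit_icqf()` runs two deterministic starts — one
seeding the factors from the raw responses, one regressing the confounds
out first — and returns the fit with the lower final objective. An
objective-guarded re-attribution step additionally proposes moving the
C-explainable part of `W` into `Qc` during the fit. A paired synthetic test
verifies the consequence: data generated purely from confounds yields
factor loadings with ≤ 5% of the variance seen when the same signal is
injected through `W`. Note this identification is only active when
β_W > 0; at β_W = 0 the split is genuinely arbitrary.

**Hyperparameters.** The supported grid is d ∈ {1, 2, 3, 4} and
β_W, β_Q ∈ {0.0, 0.01, 0.1, 1, 2, 3}; defaults d = 2, β_W = 0.0,
β_Q = 0.01 follow the values selected on the original data, used here only
as defaults. Selection is by cross-validated held-out reconstruction error
with ties broken toward smaller d, then smaller penalties.

**Cross-validation scheme (an open design point).** Holding out whole scans
and re-inferring their loadings at fixed `Q`, `Qc` scores nested models on
the very entries used for the inference, so held-out error can only
decrease with d and the scheme cannot select the true dimensionality. The
default is therefore entry-masking (Wold-style) cross-validation: a random
fold of matrix *entries* is masked, the model is fitted on the remaining
entries (the masked fit weights residuals by an observation mask), and
squared error is scored on the masked entries only. Extra dimensions that
absorb noise then worsen the score. The scan-fold scheme remains available
as `method = "scan"` for comparison. On synthetic data generated with two
latent patterns and response noise sd 5, entry-masking CV selects d = 2
from the full 144-point grid with a wide margin.

**Numerical settings.** Outer iterations stop when the relative objective
change falls below 1e−6 (cap 500 iterations; the fit warns and reports
`converged = FALSE` rather than stopping silently). Per-fold CV fits use a
looser tolerance (3e−4, cap 80) because selection depends only on error
differences an order of magnitude larger. The CV fold assignment and all
other randomness derive from integer seeds; fits themselves are
deterministic.

## Grouping scans into thought-pattern sets

Scans are partitioned with Ward-linkage agglomerative clustering on the
Euclidean distances between loading rows, k = 3 by default: two "extreme"
sets at opposite corners of the loading space and one intermediate set. The
linkage and metric are the defaults of the implementation the original
analysis used. Sets are named from centroid geometry (highest TP1 − TP2 →
`Image-Pos-Others`, highest TP2 − TP1 → `Surr-Neg-Self`, remainder
`Intermediate`); the original study named sets by inspection, and the
centroid rule reproduces that labelling deterministically. Because factor
column order is arbitrary, `orient_factors()` anchors TP1 to the item
loading highest on imagery before naming.

Within-subject consistency is summarised over subjects with at least three
scans: the fraction whose scans all fall in one set, all but one, or split
(an even two-set split counts as split). Confound matching between the two
extreme sets uses a two-sample equal-variance t test and a Mann-Whitney U
for continuous covariates (wakefulness, mean head motion), a paired t and
Wilcoxon signed-rank over age-bin counts, and reports gender as counts.
Zero-variance covariates are flagged as undefined rather than propagating
NaN.

## Connectivity, motion censoring and graph summaries

FC matrices are Pearson correlations between node (ROI) time series; values
are kept as raw r. Whether a Fisher z-transform was applied upstream in the
original analysis is unstated; since both the edge t statistics and the CPM
sums operate on "connectivity strength" and the transform is monotone and
nearly linear in the observed range, raw r is used and documented here.

The motion-censoring rule: any volume with relative displacement above
0.3 mm is invalid, together with the preceding volume and the two
following; neighbours beyond the trace boundary are ignored; a scan with
30% or more invalid volumes is rejected (boundary inclusive).

Edge indexing is fixed package-wide: upper triangle, i < j, row-major,
1-based node ids. Graph summaries over a significant-edge set include the
laterality index (LL − RR)/(LL + RR) over intra-hemispheric edges (−1
right-dominant, +1 left-dominant; undefined — not zero — when no
intra-hemispheric edges exist), within/between-network pair counts
(conserving the edge count), and node degree.

## Network-Based Statistic

Edge-level statistics come from an ordinary least-squares model of edge
strength on an intercept, the set indicator, and subject dummies (one
reference subject dropped). The exact design layout of the original
analysis is in supplementary material not reproduced in the text; the
GLM-with-subject-dummies reading implemented here reduces exactly to the
classical equal-variance two-sample t when no subject dummies are supplied,
which the tests assert to 1e−10. When every subject's scans fall in a
single set, the set effect is collinear with subject identity; the pipeline
then drops the subject dummies (between-subject design) and records that
choice. A saturated design requested explicitly is an error, not a silent
fallback.

Suprathreshold edges (one-sided p < 0.001 by default) form a graph whose
maximal connected components are the inferential units, each scored by its
extent (edge count). Significance is by permutation: group labels are
freely permuted across scans (subject dummies fixed — the stated reading of
"permutations of scan labels"; the exchangeability caveat for
repeated-measures data applies and is the reason the pipeline reports the
design it used), the maximum component extent is recorded per permutation,
and a component's family-wise-error p is `(count(null ≥ observed) + 1) /
(n_perm + 1)` — never zero. Both contrast directions run with independent
derived seeds. Component finding uses igraph; the permutation loop uses a
union-find maximum-extent routine, and both are tested for equality against
an independent breadth-first-search oracle. A two-sample fast path
vectorises all permutations through matrix products when no subject dummies
are present.

## Connectome-based predictive modeling

Targets are residualized against mean head motion once, on the full sample,
before any model fitting — matching the stated order of operations
("residualized … before training the models"); the within-fold alternative
trades that fidelity against a small leakage and is not the default. Each
CPM iteration partitions *subjects* (never scans) into 10 folds (shuffled,
dealt round-robin); training-set edges correlating with the target at
two-sided p < 0.01 (exact t transform of Pearson r) are split by sign, and
the model

    y_pred = β₀ + β₁·ΣX_pos + β₂·ΣX_neg

is fitted by OLS on the training scans and applied to the test scans.
Constant edges are excluded from selection; an empty selection set drops
its regressor (coefficient 0); both sets empty yields an intercept-only
model with a warning. Out-of-fold predictions are pooled over all scans and
accuracy is their Pearson correlation with the observed values; the whole
CV repeats 100 times with fresh fold draws. A leakage assertion (no subject
on both sides of any split) runs inside every fold.

Significance is non-parametric: the target is permuted at the subject level
(each subject's scans receive one shared permuted value — the subject mean
reassigned — respecting the grouping the CV enforces; the original text
says only "randomized labels"), the full CPM pass is rerun per draw, and

    p = (Σ[r_null > median(r_obs)] + 1) / (n_null + 1).

Whether the original 10,000 null runs used one CV repetition or 100 per
draw is unstated; one repetition per draw is used for tractability.
Benjamini-Hochberg FDR is applied across the family of prediction targets
(14 in the full pipeline: wakefulness, TP1, TP2 and the 11 items). The
consensus model keeps edges included in at least 90% of the fold ×
iteration fits, boundary inclusive, separately by sign.

## The synthetic-data module

The generator emulates the statistical structure the analysis assumes, at
desk scale, with every draw derived from one integer seed:

- **Questionnaire.** Subjects belong to one of three latent profiles
  (high-TP1, high-TP2, intermediate); each scan's true loadings jitter
  (sd 0.06) around the subject's profile centre, reproducing within-subject
  consistency without claiming a mechanism for it. Responses are
  `clip([W★,C][Q★,Qc★]′ + truncated-Gaussian noise, 0, 100)` — bounded and
  non-Gaussian after clipping. Default noise sd is 5 response units.
- **Connectivity.** Node time series (660 timepoints, matching a ~15.5 min
  scan at TR 1.4 s) are drawn from a scan-specific latent correlation
  matrix: seven equal cortical network blocks plus a small subcortical
  block (within-block r = 0.35), a shift on a planted 30-edge connected
  subgraph for high-TP2-profile scans, and a contribution proportional to
  the standardised behavioural score on 10 designated behaviour edges.
  Shifts are calibrated analytically against the sampling sd of an
  empirical correlation, so the realised group Cohen's d matches the
  requested value (audited to ±0.25) and the edge-sum/behaviour correlation
  matches the requested aggregate r. The default aggregate r of 0.7
  concentrated on 10 edges is chosen so that the *edge-level* selection
  step of CPM has power at the fixture's sample size: a weaker, more
  diffuse relation is invisible to a method that sums only individually
  significant edges.
- **Motion.** Baseline displacement stays below the 0.3 mm threshold;
  spikes above it occur independently per volume (default rate 0.01, which
  leaves all scans below the 30% rejection bound).

What the generator does **not** emulate: volumetric images and atlas
operations, physiological noise and scanner drift, sleep architecture,
item-level ordinality, heavy-tailed motion bursts, and any genuine
neurocognitive coupling between questionnaire responses and connectivity
beyond the planted linear relations. Passing tests therefore certify the
statistical machinery — calibration, power on planted effects, exact
arithmetic, leakage control, determinism — not the neuroscientific claims
that only the real data can support. Headline numbers from the original
study (590 significant connections, laterality −0.17, the published
accuracy table, the 47/36/17 consistency split) depend on the restricted
dataset and are intentionally not reproduction targets.

## Problem sizes and reproducibility

The test suite and the acceptance script run the pipeline at fixture scale,
chosen as the smallest sizes at which the planted effects are comfortably
detectable: 50 subjects × 3 scans and 60 nodes for end-to-end runs; 80
scans/group with 500–1000 permutations for NBS calibration (100 null
datasets) and power (50 replicates); 100–1000 permutation nulls for CPM
stages. The analysis scripts under `analysis/` use 5000 NBS permutations
and 1000 CPM nulls. Every stage derives its seed deterministically from a
master seed, and rerunning the pipeline with the same configuration
produces byte-identical outputs, which the acceptance suite checks with
file hashes.

## Known limitations

- The optimizer reaches a stationary point of a non-convex objective; the
  two deterministic starts hedge the main attribution ambiguity but global
  optimality is not guaranteed.
- Free permutation of scan labels in NBS assumes exchangeability across
  scans of different subjects; with strong subject effects the subject
  dummies absorb the repeated-measures structure, but a subject-level
  restricted permutation scheme is not implemented.
- The age "hashing encoding" of the original confound matrix is not fully
  specified; the 2-bit binary encoding used here matches the stated column
  count and range.
- The laterality index and network summaries describe significant-edge
  sets and inherit whatever selection effects the thresholding step
  carries.
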