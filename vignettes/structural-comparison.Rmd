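---
title: "Structural comparison of similarity matrices: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural comparison of similarity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(strucomp)
```

## The problem and the model

Many studies observe the *same* set of `d` subjects — genetic loci, languages,
countries, samples — through two different lenses, each summarised as a
`d x d` (dis)similarity matrix: `Y1` (the *reference*) and `Y2` (the
*target*). The matrices typically live on different scales and are built from
unrelated features, so entrywise comparison (or a single global correlation)
answers the wrong question. What a scientist usually wants to know is whether
the two datasets share *structure*: do the same groupings, gradients and
low-dimensional relationships organise both matrices, and if not, which
subjects deviate?

strucomp answers this with a quadratic low-rank factorization. At every
complexity `k = 1..k_max` a **structure** `A_k` (a `d x k` matrix) and a
**relationship** `X1^(k)` (`k x k`) are learned from the reference by
minimising the Frobenius error of

```
Y1  ~  A_k X1^(k) A_k' .
```

The target is then predicted *conditional on the reference structure*: `A_k`
is held fixed and only a new relationship is refit,

```
X2^(k) = A_k^+ Y2 (A_k^+)',      R2^(k) = Y2 - A_k X2^(k) A_k' ,
```

which for a full-column-rank structure equals projecting `Y2` onto the column
space of `A_k` from both sides (`fit_relationship()` implements exactly this
pseudo-inverse solve). Because the relationship is free, differences in scale,
"branch lengths", or the relative importance of components are *not* evidence
of structural difference; only subjects whose residuals `R2^(k)` stay large
across a range of complexities are. The per-subject summary is the **residual
persistence**

```
P[i, k] = sum_j R2^(k)[i, j]^2 ,
```

displayed as a heatmap over `(i, k)` by `render_persistence_chart()` /
`autoplot()`. At `k = d` any full-rank dataset predicts any other, so the
signal is in which structures are explained *late* — persist — not in whether
they are eventually explained.

## The two solvers

**Spectral (`svd_scan`)**: unconstrained. For symmetric input the singular
value decomposition coincides with the eigendecomposition up to signs, so the
solver eigendecomposes `Y1`, orders components by decreasing `|eigenvalue|`
(ties broken by original index) and fixes each vector's largest-magnitude
entry to be positive, making output fully deterministic. `X1^(k)` is the
diagonal matrix of the leading signed eigenvalues; by the Eckart–Young theorem
the fit loss at `k` is the tail norm `sqrt(sum_{j>k} sigma_j^2)`, which the
tests verify in closed form. This is the recommended default: it is exact,
fast (one eigendecomposition for the whole scan) and stable, with perturbation
bounds discussed below.

**Mixture (`mixture_fit` / `mixture_scan`)**: rows of `A` are constrained to
the probability simplex, so each subject is a mixture over `k` latent
clusters and `X` is the similarity between those clusters — far more
interpretable for hierarchical data, at the price of a non-convex fit. The
solver alternates multiplicative updates: for `A`, entrywise multiplication by
`N / D` with `N = Y1' A X + Y1 A X'`, `D = A X A'A X' + A X' A'A X`, followed
by row renormalization; for `X`, the multiplicative rule with numerator
`A' Y1 A` and denominator `A'A X A'A`.

Numerical choices that matter here, all established on planted block models
during development:

* **X update during iteration.** Interleaving an *exact* pseudo-inverse solve
  for `X` with the multiplicative `A` step traps a large fraction of random
  starts in merged-cluster local optima; keeping `X` in the positive cone via
  its multiplicative rule avoids this. The exact solve is applied once at
  termination, where it can only lower the loss, so the reported solution
  still satisfies the projection identity above.
* **Monotone guarded steps.** Multiplicative updates for this quadratic model
  carry no descent guarantee. Each joint step is therefore backtracked (the
  update ratios are raised to an exponent that is halved until the loss does
  not increase) and over-relaxed (the exponent grows up to 8 while full steps
  keep succeeding, which substantially accelerates the slow terminal phase).
  The recorded loss trace is non-increasing by construction; a step that
  cannot be repaired is rejected and the stall counter ends the fit with
  status `"stalled"`.
* **Initialization.** Zeros are absorbing, so starts are strictly positive:
  symmetric Dirichlet(1) rows for random restarts. `mixture_scan` adds two
  structured candidates per complexity — a warm start from the `k - 1`
  solution with one extra column seeded at the worst-fit subject, and a
  one-hot start from cutting an average-linkage hierarchical clustering of
  `Y1` into `k` groups (floored at 1e-3 and renormalized). The clustering
  start is what makes recovery reliable on strongly hierarchical data, where
  purely random starts find merged clusters.
* **Defaults.** `tol = 1e-8` (relative loss change, tested only after an
  accepted step), `max_iter = 5000`, `patience = 20`, `restarts = 3`,
  denominator guard `eps = 1e-12`, and an absolute stop at
  `1e-10 * ||Y1||_F` for noiseless inputs.

The constrained optimum can never beat the unconstrained one, and the test
suite checks `mixture loss >= svd loss` at every `k`.

## Self-similarity and the diagonal

The diagonal of a similarity matrix answers "how similar is a subject to
itself?", which is rarely on the same footing as between-subject entries (a
distance matrix has an exact zero diagonal that no low-rank quadratic form
can reproduce). Two corrections are provided:

* `remove_diagonal()` replaces each diagonal entry by the row's most extreme
  off-diagonal value (maximum for similarities, minimum for dissimilarities),
  then re-symmetrizes with `(M + M')/2`. The extreme is taken **per row**
  rather than globally because it preserves row scale; either reading is
  compatible with the one-line description the correction comes from, and the
  per-row choice is the one that behaves sensibly when rows live on different
  scales.
* `diagonal_model_fit()` fits `Y ~ A X A' + D` with `D` diagonal by
  alternating the structure fit on `Y - D` with the exact update
  `D <- diag(Y - A X A')`. It is slower but lets `D` be part of the model;
  `predict_target()` refits a target diagonal the same way and then computes
  persistence on off-diagonal residuals only, since `D` absorbs the diagonal
  by construction.

`crossvalidate_k()` applies the next-extreme correction to both folds and
computes its error over off-diagonal entries only. This is not cosmetic: left
uncorrected, the impossible diagonal dominates the cross-validation error,
which then decreases monotonically in `k` and the complexity estimate
degenerates at `k_max`.

## Significance by split-half resampling

With feature-derived similarities, `significance_pipeline()` builds, per
replicate, a *sampled reference* and a *sampled target* from two disjoint
halves of the reference features, and a *downsampled true target* from half
of the target features (matching noise levels). The sampled reference is
scanned; both the sampled target (the null: same generative structure, fresh
noise) and the true target are scale-aligned to it (`align_scale()`, matching
off-diagonal mean and standard deviation — the diagonal follows the
self-similarity policy, so it is excluded from the moments) and predicted
from the same scan. The persistence p-value of cell `(i, k)` is the
regularized empirical exceedance

```
p = (1 + #{replicates: null persistence >= observed persistence}) / (1 + n_bs)
```

so every p-value lies in `[1/(1+n_bs), 1]` and small p means the target's
persistence exceeds what resampling the reference alone produces. Observed
and null statistics are computed inside the same replicate, from the same
sampled-reference scan, so they share structure and the comparison is paired.

Because a high persistence at a complexity that carries no reproducible
signal is meaningless, the pipeline also estimates, by cross-validation on
the target's own features, how many complexities are supported:
`k_hat = argmin_k` of the held-out error when fold 2 is predicted by the
*full* fold-1 model (structure and relationship both from fold 1; refitting
the relationship to fold 2 would make the error non-increasing in `k` and the
estimate vacuous). The exceedance proportions `p(k)` of the `n_bs` estimates
and the per-cell persistence p-values combine into

```
p_c[i, k] = 1 - p(k) * (1 - p_persist[i, k]) ,
```

which is small only when complexity `k` describes reproducible structure
(`p(k)` near 1) *and* the cell's persistence beats the null (`p_persist`
small). Two conventions here are worth stating because they are easy to get
backwards: exceedance counting is in the direction that makes *small* p
significant, and the `p_c` algebra is the product form above — both follow
the procedure's verbal contract, and the serialized manifests record the
direction so downstream consumers need not guess. No multiple-testing
correction is applied: cells are strongly correlated and the map of p-values
is meant to localise a difference, not to test for the existence of one. A
whole-matrix Frobenius statistic (`p_global`) is reported for the latter.

For similarities that are not feature-derived (bespoke pipelines), the same
machinery accepts externally bootstrapped replicate matrices via
`resample_set()`.

## What the simulators emulate

**Tree mixtures (`simulate_tree_pair`)**: `k` clusters related by a random
coalescent tree (via `ape::rcoal`; expected height `2(1 - 1/k)`), cluster
traits drifting by Brownian motion along the tree (implemented exactly
through the Cholesky factor of the phylogenetic covariance `rate^2 * vcv`),
subjects assigned one-hot to clusters (evenly, extras to low-indexed
clusters) with Gaussian feature noise `sigma0`, and Euclidean distance
matrices. Targets: scenario **A** multiplies every branch length by an
independent `U(0.1, 2)` draw — a pure relationship change; scenario **B**
additionally reroutes a fraction `r` (rounded half-up) of one cluster's
subjects to the mixture `(1-beta, beta)` between their own cluster and a
donor tip at least the median patristic distance away — a structural change;
scenario **null** regenerates only the subject noise. The Brownian
innovations are drawn once and shared between the two trees, so the pair is
coupled: with unit multipliers and `sigma0 = 0` reference and target are
identical, and scenario contrasts are not diluted by fresh trait noise.
Defaults follow the study conditions: `d = 100`, `k = 10`, `L = 2000`,
`sigma0 = 0.05`, `beta = 0.5`, `r = 0.5`, `rate = 1`. The scenario-B mixture
is deliberately a *row-level* operation on the affected subjects' assignment
rows: with `beta = 0.5` and `r = 0.5`, half of the recipient cluster becomes
an even mixture of recipient and donor, while the rest of the matrix is
untouched.

**Methylation/expression (`simulate_methex`)**: 300 hypo- and 700
hyper-methylated loci with class means `U(0.1, 0.4)` / `U(0.55, 0.85)`;
tumour samples draw uniformly with class-specific half-widths (`mu/2` and
`(1-mu)/2`), controls shift their locus mean 0.2 towards the middle (sign
random for mid-range loci) and use the same width rule around the shifted
mean; draws are clamped to `[0, 1]` (the hypo control shift can exceed the
support). Expression is observed on an *independent* cohort: a fresh
methylation realization is drawn for it — including its own random shift
signs, since the two experiments are independent — and raw expression is
`Normal(-m', sigma_i^2)` with `sigma_i ~ U(0.5, 0.9)`, then centred and
scaled per locus. The negative conditioning reflects methylation's repressive
action on transcription and is what produces the weak negative average
association (about −5% per-locus correlation at the default cohort sizes of
50 tumour + 50 control, which are this package's choice; the source material
does not print them). Anomalies flip `e -> -2e` for the tumour samples of one
random 10-locus segment and the control samples of another; these loci are
the planted ground truth that the persistence chart should isolate.

What these simulators do *not* emulate — and hence what passing tests do not
establish about real data: batch and platform effects, heavy-tailed or
correlated feature noise, missingness, uneven cluster sizes beyond the
rounding rule, more than one mixture edge, multifurcating trees, and any of
the bespoke similarity pipelines real studies use upstream. Results on real
data depend on those choices; the simulations validate the machinery, not the
measurement process.

## Problem sizes used by the checks

The test-suite replications run at deliberately reduced scale, chosen so the
qualitative contrasts are stable across seeds: structure recovery at
`d = 100, k = 10, L = 500, sigma0 = 0.005` over 20 seeds (`mixture_scan` with
one random restart and `max_iter = 1000`, which converges well before the cap
at this noise level); scenario discrimination with 50 replicates at
`L = 500, sigma0 = 0.05`, summarising excess persistence and donor–recipient
group residuals over the intermediate band `k in [5, 15]` around the true
`k = 10`; anomaly detection with 20 replicates of the full 1000-locus
simulator, ranking mean persistence over `k in [5, 30]`; and null calibration
with 20 pipeline runs at `n_bs = 99`. The simulator calibration check
averages 50 replicate simulations at the default sizes.

## Known limitations

* The mixture solver is a local optimizer; the clustering/warm/random start
  portfolio makes it reliable on hierarchical data but offers no global
  guarantee, and `A` is only identifiable up to column permutation (and not
  pushed towards vertices by the loss — only by initialization).
* The stability guarantees for the spectral structure degrade with the
  eigengap `delta_k = lambda_k - lambda_{k+1}`; at near-degenerate gaps the
  learned subspace, and hence the residual map, can rotate freely. The
  property tests condition on `delta_k > 1e-6` for exactly this reason.
* The resampling null assumes features are (pseudo-)independent and that
  signal and noise scale together under downsampling; similarities built from
  strongly dependent features need externally constructed replicates.
* Asymmetric inputs are rejected beyond a 1e-8 relative tolerance rather than
  handled; symmetrise first if your builder produces one-sided estimates.
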