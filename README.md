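# strucomp

Structural comparison of (dis)similarity matrices over a shared set of
subjects.

## The problem

Two datasets often describe the *same* subjects — genetic loci, languages,
countries, samples — through completely different features, each summarised as
a d × d similarity or dissimilarity matrix `Y1` (reference) and `Y2` (target).
Entrywise comparison or a global correlation cannot tell whether the two
matrices are organised by the same *structure*, nor which subjects break the
correspondence. strucomp implements a structural comparison:

1. **Learn structure from the reference.** At each complexity k, find a
   structure `A_k` (d × k) and relationship `X1^(k)` (k × k) minimising
   ‖Y1 − A_k X1^(k) A_kᵀ‖_F. Two solvers: an unconstrained spectral scan
   (`svd_scan`, truncated eigendecomposition, Eckart–Young optimal) and a
   simplex-constrained mixture factorization (`mixture_scan`, multiplicative
   updates), whose rows are interpretable as memberships in latent clusters.
2. **Predict the target conditional on that structure.** Keep `A_k`, refit
   only the relationship: `X2^(k) = A_k⁺ Y2 (A_k⁺)ᵀ` (`predict_target`).
   Scale and "branch-length" differences are absorbed by `X2` and are not
   evidence of structural change.
3. **Read the residuals that persist.** The residual persistence
   `P[i, k] = Σ_j R2^(k)[i, j]²` flags subjects that stay poorly predicted
   across a range of complexities (`persistence_matrix`, `excess_persistence`,
   `group_residual_summary`, `render_persistence_chart`).
4. **Attach significance if needed.** Split-half resampling of the features
   yields regularized empirical p-values for every persistence cell, a
   cross-validated complexity estimate `k̂`, the complexity support curve
   `p(k)`, and the combined p-value `p_c = 1 − p(k)·(1 − p_f)`
   (`significance_pipeline`); small `p_c` needs both reproducible structure at
   k and an exceedance over the resampling null.

Two generative simulators ship with the package so every component is testable
without external data: a coalescent-tree / Brownian-motion hierarchy with
relationship-only and structure-changing targets (`simulate_tree_pair`), and a
methylation–expression case-control model with planted anomalous loci
(`simulate_methex`).

## Worked example

Simulate a 6-cluster hierarchy in which half of one cluster ("recipient" t3)
secretly becomes a 50/50 mixture with a distant "donor" cluster (t1) in the
target, then ask whether the reference structure still predicts the target:

```r
library(strucomp)

sim <- simulate_tree_pair(d = 60, k = 6, L = 400, sigma0 = 0.05,
                          scenario = "B", seed = 42)
y1 <- remove_diagonal(sim$y1)   # self-similarity correction
y2 <- remove_diagonal(sim$y2)

scan <- svd_scan(y1, k_max = 12)
tidy(scan)
#> # A tibble: 12 x 4
#>       k fit_loss method status
#>   <int>    <dbl> <chr>  <chr>
#> 1     1     473. svd    <NA>
#> 2     2     278. svd    <NA>
#> 3     3     181. svd    <NA>
#> 4     4     111. svd    <NA>
```

The fit loss falls as the scan allows more complexity. Predicting the target
with the reference structure leaves residual loss that does *not* vanish at
moderate k — the first sign of a structural difference:

```r
cmp <- predict_target(scan, y2)
glance(cmp)
#> # A tibble: 1 x 5
#>   n_subjects k_max method loss_first_k loss_last_k
#>        <int> <int> <chr>         <dbl>       <dbl>
#> 1         60    12 svd            463.        105.

recipient <- names(sim$truth$cluster)[sim$truth$cluster == sim$truth$recipient]
excess_persistence(cmp, recipient)
#> # A tibble: 12 x 2
#>       k excess
#>   <int>  <dbl>
#> 1     1 -2456.
#> 2     2   560.
#> 3     3   544.
#> 4     4   714.
#> 5     5   521.
#> 6     6   601.
```

From k = 2 onwards the recipient cluster carries hundreds of units more
persistence than the average other subject: exactly the planted anomaly. (At
k = 1 a single component cannot separate clusters, so the contrast is not yet
meaningful.) `autoplot(cmp)` draws the persistence heatmap. Resampling makes
the call formal:

```r
sig <- significance_pipeline(sim$d1, sim$d2, n_bs = 99, k_max = 12, seed = 1)
sig
#> <structure_significance: 60 subjects, k = 1..12, n_bs = 99>
#>   median k_hat = 7; cells with p_c < 0.05: 37.5%
#>   convention: small p = observed persistence exceeds the resampling null
```

Cross-validation supports about 7 complexities of reproducible signal
(k̂ = 7 ≈ the 6 planted clusters plus the mixture edge), and a large share of
persistence cells beat the split-half null — under a matched null scenario
(`scenario = "null"`) this fraction stays near zero.
`render_persistence_chart(sig$p_c < 0.05, ...)`-style charts shrink
non-significant cells; `tidy(sig)` returns the per-cell table.

A command-line wrapper over the same functions is installed at
`inst/cli/strucomp.R` with subcommands `scan`, `predict`, `significance`,
`simulate-tree`, `simulate-methex` and `chart`.

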