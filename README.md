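# funcEquiv

Discrete Bayesian-network tools for detecting **functional collapse** in
ecological community time series and transferring models between
communities that realise the same functional structure with different
species.

The motivating setting is annual trawl-survey biomass: one table per
region, one row per year, one column per species.  Some exploited
communities undergo a persistent step change in their dependence
structure (e.g. the groundfish collapses of the late 1980s / early
1990s), and different seas can express the same functional topology
through different species.  funcEquiv asks three questions of such data:

1. **Which species are implicated in the collapse?**  The collapse is a
   binary class node `C` (pre/post a given year).  Species are ranked by
   a bootstrap *filter* (the Cooper–Herskovits family score of the
   `C`–species edge, averaged over resamples) and a *wrapper* (the
   proportion of resamples in which a greedy-K2-learned classifier links
   the species with `C` — its confidence).
2. **Which species in another region play the same roles?**  Algorithm:
   simulated annealing over injective slot-to-species assignments
   (1000 iterations, `t_start = 1000`, cooling ×0.9; accept iff
   `dscore ≥ 0` or `U < exp(dscore/t)`), scoring each assignment by how
   well the second region's data fit the donor network — by default the
   log-likelihood under the donor-parametrized model, with refit BIC
   (`log L̂ − Dim_G/2 · log M`) and K2 joint scores
   (`log c + Σᵢ Σⱼ [log Γ(rᵢ) − log Γ(F_ij+rᵢ) + Σₖ log Γ(F_ijk+1)]`)
   also available.
3. **Can we predict the other region's target species and its regime?**
   A two-slice dynamic Bayesian network with a binary latent regime node
   `H` (autoregressive link `H_{t−1} → H_t`, emissions
   `P(xₜ | lagged parents, Hₜ)`) is fitted by Baum–Welch EM on the donor
   region, then carried — structure *and* parameters — onto the mapped
   species for one-step-ahead prediction and smoothed/Viterbi inference
   of the latent collapse trajectory.

A synthetic two-region generator with known ground truth (shared
functional structure, hidden species relabelling, independent distractor
species, regime shift as a conditional-table switch) makes every stage
testable; see the methods vignette (`vignettes/functional-equivalence.Rmd`)
for the model details and design rationale.

## Worked example

```r
library(funcEquiv)

pair <- generateRegionPair(syntheticScenario(), seed = 42)
res <- runTransferPipeline(pair$regionA, pair$regionB,
                           collapseYearA = 1988,
                           target = pair$truth$target,
                           collapseYearB = 1992,
                           schedule = annealingSchedule(seed = 42),
                           seed = 42)

head(res$ranking, 4)
#>   species confidence rank
#> 1   spA01      1.000    1
#> 2   spA04      0.835    2
#> 3   spA03      0.735    3
#> 4   spA02      0.635    4

res$equivalence
#> EquivalenceResult: 7 slots, best score -622.8601 (final -622.8601), 45/1000 moves accepted
#>   spA01 <- spB04
#>   spA04 <- spB12
#>   spA03 <- spB11
#>   spA02 <- spB02
#>   ...

evaluateRecovery(res$equivalence, pair$truth)
#> $mappingRecovery
#> [1] 0.8
evaluateRecovery(res$transfer, pair$truth)
#> $hiddenAccuracy
#> [1] 1
#> $oneStepAccuracy
#> [1] 0.7272727
detectRegimeShift(res$transfer$mapState, res$transfer$year, 1992)
#> $switchYear
#> [1] 1992
#> $postStability
#> [1] 1
```

Reading: the wrapper flags the collapse-linked species of region A with
high confidence (the four true core species head the ranking); the
annealed mapping assigns 4 of the 5 true functional roles to the correct
region-B species (`mappingRecovery` counts correct slots over the number
of true roles); the transferred model — parametrized entirely on region A
— predicts region B's target one year ahead well above the deranged
baseline, and its Viterbi latent path switches exactly at region B's 1992
collapse and stays collapsed thereafter (`hiddenAccuracy` is the per-year
agreement with the true regime after label alignment).

Per-year output lives in `res$transfer` (`year`, `observed`, `predicted`,
smoothed regime posterior, Viterbi state, ...) and can be written with
`writePredictionSeries()`.

A thin command-line front end over the same functions is included at
`inst/scripts/funcequiv.R` (subcommands `simulate`, `discretize`,
`select`, `map`, `predict`).

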