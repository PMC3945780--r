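# survscreen

Screening and evaluating gene-gene interaction effects in
high-dimensional right-censored survival data.

## The problem

In molecular survival studies (expression profiling of tumor cohorts,
n ≈ 150, p ≈ 1000), two-way interactions on the log-hazard scale are
nearly invisible to main-effect selectors: a product term `x_a * x_b`
whose component variables carry no main effect leaves no marginal trace,
and enumerating all p(p−1)/2 products is statistically and
computationally hopeless. `survscreen` implements a multi-stage strategy:

1. **Main-effect detection** by componentwise likelihood-based boosting
   of the Cox model: starting at β = 0, each step updates the single
   coefficient maximizing the penalized score statistic
   `U_j² / (I_j + ρ)` by `θ̂ = U_j / (I_j + ρ)`, with
   `ρ = (Σδ_i)(1/ν − 1)` and relative step size ν = 0.05; the step count
   is cross-validated (predictive partial likelihood).
2. **Interaction pre-selection** with random survival forests: unpruned
   log-rank trees on 0.632 subsamples, Nelson–Aalen terminal cumulative
   hazards, permutation importance against out-of-bag concordance. On
   each of S inner subsamples, every pair of covariates with positive
   importance is recorded; the R most frequent pairs (ties at rank R
   included) become candidates. Optionally the covariates are first
   **orthogonalized** — residualized on the detected main effects — to
   unmask interaction signal (strategy `rsf-VIF-res`; ablations
   `rsf-VIF`, `cb-VIF`, `cb-crossp` drop orthogonalization, the forest,
   or the subsampling).
3. **Final model**: boosting over main effects plus the candidate product
   columns.
4. **Evaluation**: IPCW Brier score curves
   `Err(t) = n⁻¹ Σ W_i(t) (δ_i(t) − π̂(t, x_i))²` on a held-out 0.632
   split, integrated (IPEC) and reported relative to the Kaplan–Meier
   reference (rIPEC).

A simulation engine generates the twelve built-in study scenarios
(`Sim42`, `Sim22_0.25` … `Sim22_2.5`, `Sim22_bin`,
`Sim22_corr01` … `corr07`): standard-normal, binary or block-correlated
covariates, exponential event and censoring times with baseline hazard
1/20, and known ground truth for scoring selection sensitivity.

## Worked example

```r
library(survscreen)

sp <- builtin_scenarios()$Sim42   # 4 mains (3,3,-3,-3), 2 interactions (5,-5)
sp$p <- 200L                      # trim for a quick run
sim <- generate_dataset(sp, seed = 301)

cfg <- strategy_config("rsf-VIF-res", S = 5, R = 2000, ntree = 100)
res <- run_strategy(sim$data, cfg, outer_seed = 55)
res
#> strategy_result (rsf-VIF-res): |M| = 9, IntScreen = 4463
#>   final model: 4 main + 24 interaction terms; rIPEC 0.323 (CoxBoostM 0.168)
```

Read: the first-pass boosted Cox model detected 9 main-effect
candidates; screening kept 4463 candidate pairs (ties at the rank-R
inclusion frequency are always kept, which pushed the count past
R = 2000); the final model retained 4 main effects and 24 products; it
improves integrated prediction error over the Kaplan–Meier reference by
32%, versus 17% for the main-effects-only model — the interaction terms
carry real predictive signal here.

Score against the generating truth:

```r
score_replicates(list(res), list(sim$truth))
#> metrics over 1 replicates:
#>   IntScreen 4463.00 | IntSensiA 0.50 | VarsTotal 28.00 | MainSensi 0.500 (NA) | IntSensi 0.500 (NA)
#>   rIPEC main 0.168 final 0.323
```

A command-line wrapper covers the same workflows
(`inst/cli/survscreen simulate|fit|forest|screen|evaluate|reproduce-table`),
e.g.

```sh
inst/cli/survscreen simulate --scenario Sim22_1.0 --replicates 5 --seed 7 --out sims/
inst/cli/survscreen screen --data sims/Sim22_1.0_rep001.tsv \
    --strategy rsf-VIF-res --S 10 --R 2000 --ntree 250 --seed 1 --out run1/
```

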