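# ascotbws

Best-worst scaling (BWS) valuation of the **ASCOT-Carer** instrument — the
seven-attribute, four-level measure of informal carers' social care-related
quality of life (SCRQoL). The package implements the full pipeline used to
derive national preference weights for the instrument, and ships the
published Finnish estimates both as simulation ground truth and as the
input from which the published value set is reproduced.

The pipeline:

1. **Design** — a 32-run orthogonal main-effects plan (OMEP) for 7 four-level
   attributes, built by expansive replacement over GF(2)^5 and verified by
   brute-force balance/orthogonality counting; 4 blocks of 8 profiles;
   foldover mirrors; between-respondent attribute-order randomisation.
2. **Synthetic cohort & choices** — respondents with the study's covariate
   margins; exploded sequential best/worst choices (set sizes 7/6/5/4)
   sampled from the softmax probabilities of a scale-heterogeneity MNL.
3. **Estimation** — exploded-logit maximum likelihood (Newton–Raphson with
   analytic gradient/Hessian): plain MNL with position constants, S-MNL with
   multiplicative scale factors `gamma = exp(theta)` for health, education,
   completion time and the learning effect, optional taste interactions;
   cluster-robust sandwich standard errors; LR tests and pseudo-R²(0).
4. **Value set** — post-stratification taste adjustment toward population
   margins, normalisation by the largest coefficient, anchoring so the best
   state scores 1 and the worst 0:
   `v_jk = (beta_jk − mu) * alpha`, `mu = Σ_j min_k beta_jk / 7`,
   `alpha = 1 / (Σ_j max_k − Σ_j min_k)`; the self-care level-1/2 switch;
   additive state scoring.

## Worked example

Reproduce the published Finnish value set from the reported taste-adjusted
S-MNL coefficients and score two states:

```r
library(ascotbws)
weights <- preference_weights(finnish_carer_estimates("III*")$beta)
score_state(weights, "3442434")   # a poorer state
#> [1] 0.204
score_state(weights, "1231321")   # an improved state
#> [1] 0.808
weights$table[weights$table$attribute == "CONT", c("label", "normalized", "index")]
#>   label normalized       index
#> 5 cont1  1.0000000  0.16779044
#> 6 cont2  0.9412278  0.15635864
#> 7 cont3  0.4666861  0.06405530
#> 8 cont4  0.0000000 -0.02672003
```

The index values are the anchored preference weights: moving a carer from
state `3442434` to `1231321` is a SCRQoL gain of 0.604 on the 0–1 scale.
`cont4` ("I have no control over my daily life") is the only reference
level and carries a negative index value, i.e. it is worse than the average
worst level.

A full synthetic-study run — design, 1005 respondents, 32,160 simulated
choice occasions, MNL and S-MNL fits, adjustment, anchoring, artifacts plus
manifest on disk:

```r
res <- run_pipeline(list(seed = 1), out_dir = "artifacts")
res$fit_smnl$gamma      # recovered scale factors, incl. learning
res$report$rho2_0_smnl  # fit against the uniform-choice null
```

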