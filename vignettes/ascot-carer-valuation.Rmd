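---
title: "Valuing carer quality of life from best-worst scaling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing carer quality of life from best-worst scaling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascotbws)
```

## The problem

The ASCOT-Carer instrument describes an informal carer's social care-related
quality of life (SCRQoL) with seven attributes — occupation, control over
daily life, self-care, personal safety, social participation, space-and-time,
and feeling supported — each at four ordered levels from "ideal state"
(level 1) to "high needs" (level 4). To use the instrument in economic
evaluation, each of the 28 attribute levels needs a preference weight on a
common scale, so that any of the 4^7 = 16,384 states can be scored by adding
its seven level weights and the best state maps to 1 and the worst to 0.

`ascotbws` implements the full valuation pipeline for profile-case
best-worst scaling (BWS) data: experimental design, synthetic cohort and
choice simulation, exploded sequential logit estimation with scale
heterogeneity, post-stratification, and anchoring into the index. The
package ships the published Finnish estimates
(`finnish_carer_estimates()`), both as the default truth for the simulator
and as the input from which the published value set is reproduced.

## The choice model

In a BWS task a respondent sees one profile (one level per attribute,
displayed in seven rows) and sequentially picks the best, worst,
second-best and second-worst level. The partial ranking is *exploded* into
four independent conditional-logit choices over shrinking availability sets
of sizes 7, 6, 5 and 4. For item $j$ with display row $r(j)$, the
systematic utility in the two stage families is

$$V_j^{best} = \lambda_{it}\,(\beta_j + \pi^B_{r(j)} + \delta' x_i\,1\{j\}),
\qquad
V_j^{worst} = \lambda_{it}\,(-\beta_j + \pi^W_{r(j)} - \delta' x_i\,1\{j\}),$$

where $\beta_j$ is the utility of the attribute level relative to the
reference `cont4` ("I have no control over my daily life", fixed at 0),
$\pi^B, \pi^W$ are position constants for display rows 2–7 (row 1 fixed at
0) capturing order bias, and the $\delta$ terms are observed-covariate
taste interactions. Choice probabilities are softmax over the available
set, computed with max-subtraction.

The scale multiplier
$\lambda_{it} = \prod_k \gamma_k^{z_{ik}} = \exp(\theta' z_{it})$ carries
the S-MNL part: between-group differences in error variance. The default
scale covariates are good self-assessed health (`hgood`), higher education
(`eduhigh`), long completion time (`tmlong`) and `learning`, the indicator
of the second sequence of four tasks ($\gamma_{learning} > 1$ means more
consistent choices late in the experiment, i.e. learning rather than
fatigue; the split after task 4 is the default, `first_seq_len` exposes the
1/7, 2/6 and 3/5 alternatives). $\lambda$ multiplies the whole systematic
index including the position constants; since the exact algebraic placement
is a modelling choice, `scale_applies = "beta"` provides the variant where
position constants stay unscaled. Taste terms ride with $\beta$ (they flip
sign in worst-type stages): this is what makes the later post-stratification
step $\beta^*_j = \beta_j + \sum_m s_{g(m)}\hat\delta_m$ coherent, because the
adjusted $\beta^*$ must enter best and worst stages with opposite signs just
as $\beta$ does.

## Experimental design

Profiles come from a 32-run orthogonal main-effects plan (OMEP) for seven
four-level attributes, `generate_omep()`. The construction is expansive
replacement over the regular two-level 32-run design indexed by GF(2)^5:
each attribute is assigned a closed triple $\{a, b, a+b\}$ of nonzero
vectors, the triples pairwise disjoint (seven disjoint lines in PG(4,2),
found by a seeded restart-greedy search), and the two-level pair
$(x_a, x_b)$ is recoded to a level 1–4 with a random relabelling per
column. Disjointness of closed triples makes any four defining vectors
from two different triples linearly independent, so every pairwise level
combination appears exactly twice — strength-2 orthogonality holds by
construction, and `verify_design()` checks it by brute-force counting.
The 32 profiles are randomly divided into four blocks of eight;
each respondent receives one block. `foldover_mirror()` ($l \mapsto 5-l$)
and `foldover_pairs()` expose the foldover structure as a report rather
than a design constraint: a 4^7 OMEP needs at least 22 runs, so a 16+16
foldover construction is impossible and the mirror property is treated as
diagnostic. Attribute display order is randomised between but not within
respondents (`randomize_attribute_order()`).

## Synthetic data

The original survey data are confidential, so the package generates
synthetic stand-ins at the study's geometry: 1005 respondents, 8 tasks
each, 4 choices per task — 32,160 choice occasions. Respondent covariates
are independent Bernoulli draws at the sample shares reported for the
study (`default_margins()`: hgood 0.539, eduhigh 0.302, tmlong 0.750,
renter 0.464, lowedu 0.108, noreligion 0.379); only marginal shares are
published, so independence is an explicit assumption, and a `joint`
argument accepts user-supplied dependent draws. Choices are sampled stage
by stage by inverse-CDF on the softmax probabilities (equivalent to
stage-wise Gumbel-utility argmax), with an RNG substream per respondent so
datasets are reproducible under cohort reordering.

What the simulator does *not* emulate: inattention and lexicographic
heuristics, response-time processes beyond the `tmlong` indicator,
panel-recruitment mechanics, and any taste heterogeneity beyond the
configured interaction terms. Passing parameter-recovery tests therefore
show that the estimator inverts the assumed data-generating process at the
study's size — not that the model is correctly specified for real survey
behaviour.

## Estimation

`fit_model()` maximises the exploded log-likelihood by safeguarded
Newton–Raphson with analytic gradient and Hessian. With scale factors the
likelihood is only locally concave, so the fitter first solves the concave
conditional-logit subproblem ($\theta = 0$), then runs full Newton with a
Levenberg-style ridge whenever the Hessian is not negative definite, and a
step-halving line search. Convergence is declared at gradient max-norm
below `gtol` (default 1e-6); near the optimum, where log-likelihood
improvements fall below the double-precision floor of an LL of magnitude
~40,000, a step is also accepted when it halves the gradient norm without
materially lowering the LL. Scale factors are estimated as
$\theta = \log\gamma$ (unconstrained, enforcing positivity) and reported as
$\gamma$ with delta-method standard errors. Standard errors are
cluster-robust sandwich estimates $H^{-1}(\sum_c g_c g_c')H^{-1}$ with
respondents as clusters, from analytic per-cluster scores. Worst-stage
attribute-specific constants (`include_worst_asc`) support the exploratory
taste-model step; they are excluded from final models. Tests validate the
gradient and Hessian against finite differences of the independent
`dataset_loglik()` implementation, and the sandwich against a hand-solved
one-parameter logit and an exact cluster-duplication scaling law.

## From coefficients to the value set

`adjust_for_population()` applies modified post-stratification:
$\beta^*_{jk} = \hat\beta_{jk} + \sum_m s_{g(m)}\hat\delta_m$ over the
interactions touching level $jk$, with fixed population shares $s_g$
(renters 0.274, lower-secondary-or-below education 0.188, no religion
0.267), and fixed-weight standard errors $\sqrt{w'\hat\Sigma w}$. The exact
interaction list of the original study is unpublished; the mechanism is
fully generic and `default_interactions()` ships a labelled synthetic
placeholder touching the four levels the published table flags as
adjusted (occu3, safe4, soci1, supp4).

`normalize_weights()` divides by the largest coefficient (`cont1` = 1).
`anchor_index()` maps $\beta$ affinely so the seven per-attribute maxima
sum to 1 and the seven minima to 0:
$v_{jk} = (\beta_{jk} - \mu)\,\alpha$ with $\mu = \sum_j \min_k \beta_{jk}/7$
and $\alpha = 1/(\sum_j \max_k - \sum_j \min_k)$; individual values may be
negative. Because the estimated self-care (PERC) levels 1 and 2 came out
in reversed need order, the published weights exchange them
(`apply_level_switch()`); the switch is applied to the published table
only, never to the fitted model, and is an involution. `score_state()`
sums unrounded internal weights and rounds the final value to 3 decimals —
the published worked sums match unrounded arithmetic, not the sum of the
printed 3-decimal addends.

```{r}
weights <- preference_weights(finnish_carer_estimates("III*")$beta)
score_state(weights, "3442434")
score_state(weights, "1231321")
```

## Numerical and design choices

* **Reference constraints** (`cont4` = 0, row-1 position constants = 0,
  reference-group $\lambda$ = 1) are structural, never estimated.
* **Degenerate inputs** raise errors rather than returning NaN: all-zero
  coefficients in normalisation, coinciding best/worst states in
  anchoring, non-finite utilities in the likelihood (named by occasion).
* **Ties** in the anchoring max/min are harmless: `tapply` max/min are
  well-defined and the affine map does not depend on which maximiser is
  used.
* **Seeding**: all randomness flows from one root seed through named
  31-bit substreams (design, relabelling, blocking, cohort, per-respondent
  choices), so artifacts are bit-reproducible and independent of ordering.
* **Problem sizes in the test suite** are the package's own choices: the
  840-sequence uniformity check runs at 21,000 replicates, stage-frequency
  agreement at 20,000, margin convergence at n = 100,000, and the
  parameter-recovery study at 20 replicates of the full n = 1005 geometry,
  which recovers $\gamma_{learning}$ to within 0.03 of the generating
  1.069 and nominal-level confidence coverage of the 27 free utilities.

## Known limitations

* Observed-covariate heterogeneity only: no random-coefficient mixed
  logit or continuously distributed scale (G-MNL), and no ranked-order
  models with worst utilities other than the sign flip.
* Independence of synthetic covariates; the real joint distribution is
  unknown.
* The published 32-profile plan itself is not available; any plan passing
  `verify_design()` is treated as equivalent, and plans can be loaded from
  CSV for exact replication when one is available.
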