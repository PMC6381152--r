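---
title: "Modelling schema updating in continuous-report memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling schema updating in continuous-report memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemup)
```

## The scientific problem

Spatial schemas — here, the knowledge that most items of a category appear
within one 90° quadrant of a circle — bias what people reproduce in a
continuous-report (delayed-estimation) memory test. `schemup` models the
distribution of signed circular response errors to ask two questions: do
responses cluster on the *schema mean* in addition to the trial's target, and,
after one category's schema is shifted 90° clockwise, do participants who had
time to consolidate the original schema update it more completely than
participants who learned the shifted material immediately?

The package provides the full analysis chain for a two-group design
(no-consolidation vs consolidation, 32 participants each): a synthetic-data
generator for the design, five mixture models of response error, pooled and
single-subject maximum-likelihood fitting with AIC/BIC comparison, trial-level
posterior attribution, a participant-level permutation test, and
schema-strength correlational analyses.

## The mixture models

Responses are angles on the circle; the error of interest is the signed
circular deviation of the response from a component centre, in degrees in
\[-180, 180). All models combine:

* a **von Mises** (circular normal) component centred on the trial's target
  with concentration $\kappa$, capturing memory for the studied location;
* a **uniform** component, capturing guessing.

That standard mixture has 2 free parameters ($p_{guess}$ and $\kappa$; the
target weight is the complement). Three variants add a third free parameter,
the weight of a second von Mises — with the *same* $\kappa$, as dictated by
the parameter count — centred on a schema mean:

| model | schema component centred on | data it is meant for |
|---|---|---|
| M1 | — | consistent category, Final Test critical items |
| M2 | (current) schema mean | consistent category, Final Test critical items |
| M3 | — | inconsistent category, Final Test critical items |
| M4 | *original* (superseded) schema mean | inconsistent category |
| M5 | *new* schema mean (in force at learning) | inconsistent category |

Densities are expressed per degree (the von Mises density in radians is
multiplied by $\pi/180$), so log-likelihoods from different implementations
are comparable only under the same convention; the uniform density is
$1/360$. Internally all trigonometric work is done in radians for numerical
stability of the Bessel-function evaluations.

Evidence of schematization is M2 beating M1 by AIC/BIC on the consistent
category; evidence of reversion to the old schema is M4 beating both M3 and
M5 on the inconsistent category. Comparison tables are oriented "alternative
minus preferred", so positive differences favour the winning model.

## Fitting

`fit_model()` maximizes the pooled log-likelihood directly: Nelder–Mead on
transformed parameters (multinomial-logit mixing weights; $\kappa$ mapped to
\[0, 200\] through a scaled logistic) from 10 random starts by default,
followed by monotone EM refinement. The EM operates on the same likelihood,
so the refinement can only improve the optimum, and it leaves the fit at an
EM fixed point — which guarantees the identity, used by the attribution
analyses, that the mean posterior responsibility of each component equals its
mixing weight. An EM-only engine (`engine = "em"`) reaches the same optimum
(this is asserted by a test) and is used where thousands of refits are
needed. The hot loops (mixture likelihood and EM iterations) are implemented
in C++.

Numerical choices:

* $\kappa$ is capped at 200: beyond that the von Mises is narrower than about
  1° SD, finer than the response dial resolves. Fits at the cap are flagged
  degenerate with a warning.
* Convergence tolerance is $10^{-6}$ on the log-likelihood; the EM polish
  runs to $10^{-10}$.
* The multinomial-logit transform keeps the weights strictly inside the
  simplex during optimization; boundary solutions (e.g. $p_{schema}=0$) are
  reached to within the transform's resolution and then sharpened by EM.
* $\kappa$'s M-step inverts $A_1(\kappa)=I_1(\kappa)/I_0(\kappa)$ by Fisher's
  rational approximation plus Newton steps.

A brute-force grid search over weights (step 0.01) and 50 log-spaced
$\kappa$ values serves as an independent oracle in the test suite: the
optimizer must attain at least the grid optimum.

## Attribution and the permutation test

At the fitted parameters, each trial's response gets a posterior probability
(responsibility) of having arisen from each component. The group statistic is
the mean old-schema responsibility of a *pooled* per-group M4 fit. Group
inference permutes participant labels (preserving group sizes), refits the
pooled model per relabelled group, and compares the observed group difference
with the permutation null; the two-tailed p is the proportion of iterations
whose absolute null difference reaches the observed one (ties count as
reaching it, the conservative choice). An add-one corrected p is reported
alongside for the cases where the plain proportion is 0. All fits inside the
test — observed and permuted — use EM warm-started at a multi-start fit to
the combined data, so the observed statistic is exchangeable with the null
ones; a simulation test confirms type-I error at the nominal 5% level.

## Schema strength analyses

Initial schema strength is the difference in mean absolute error between
outside- and inside-quadrant test trials of the Initial Study phase, in
degrees, per participant and category. Downstream analyses relate it to
single-subject M4/M2 schema weights at Final Test via Pearson correlations
per group, compare the two groups' correlations with the Fisher r-to-z test
for independent samples
($z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/\sqrt{1/(n_1-3)+1/(n_2-3)}$;
this method reproduces both printed worked examples, $z = 2.12$ and
$z = 0.306$, which pins it down among the candidate tests), and fit a
standardized two-predictor regression of Final-Test old-schema responding on
initial schema strength and New-Learning old-schema responding.

## The synthetic-data generator

No participant data accompany the design, so the generator is a first-class
module that emulates the experiment: 2 groups × 32 participants; four
categories with quadrant centres 90° apart, counterbalanced per participant;
Initial Study of 4 × 28-trial blocks over the two relevant categories (22
inside-quadrant and 6 outside-quadrant trials per block, outside targets at
least 30° beyond the quadrant edge, uniform over their allowed arcs — the
maximum-entropy choice given only the stated margin); one New Learning phase
re-using the relevant categories with the inconsistent category's schema
shifted exactly 90° clockwise (negative degrees in our convention), the other
introducing the irrelevant categories; and a Final Test re-testing all 336
studied items in 6 blocks of 56. Items studied in the relevant New Learning
phase (56 per category) are the *critical* items, learned 48 h before Final
Test.

Responses are drawn from the same mixture family the models assume, with
cell-specific weights (group × category role × phase). Where the design
itself fixes a value we use it; the remaining defaults were chosen once as
realistic for delayed-estimation location memory and are not revisited:
$\kappa = 15$ (circular SD ≈ 15°) everywhere, guessing 0.10, old-schema
weights 0.49 vs 0.32 at Final Test and 0.03 vs 0.00 at New Learning for the
no-consolidation vs consolidation groups, schema weight 0.10 during Initial
Study, 0.30 for the consistent category at Final Test, and 0.20 for
irrelevant categories at Final Test. Timeouts are a configurable missing-
response probability, default 0. A single top-level seed drives deterministic
per-participant child streams, so any participant's data can be regenerated
in isolation.

What the generator deliberately does **not** emulate: participant-level
heterogeneity in the mixing weights (every simulated participant in a group
shares one parameter set), response times, stimulus-identity effects, and
learning within a phase. Two consequences matter when reading test output.
First, pooled group estimates are far more stable than in a real cohort, so
the permutation test can flag even the tiny New-Learning asymmetry (0.03 vs
0.00) that a real sample would not resolve. Second, the schema-strength
correlations have no built-in participant-level signal, so their synthetic
values hover near zero and only the *machinery* (correlation, r-to-z
comparison, regression) is validated against closed forms and simulation
oracles, not against any particular effect size. Passing tests therefore
demonstrate correctness of the estimator and inference chain under the
model's own assumptions, not realism of any specific dataset.

## Problem sizes used by the simulation tests

The validation suite scales simulations to keep runs short while leaving the
statistical checks well-powered; these sizes are the package's own choices:

* parameter recovery: pooled M4 fits on 64 × 56 trials, 20 replicates per
  weight variant, tolerance ±0.03 on weights and ±15% on $\kappa$;
* model-selection recovery: 100 replicates at 32 × 56 trials (M4 data), and
  50 replicates of the nested null (M3 data) for the penalty-margin bound;
* permutation calibration: 200 replicates × 500 iterations with 8
  participants × 28 trials per group under the null; power at the
  0.49-vs-0.32 alternative with 32 × 28 per group, 50 replicates
  (5000 iterations remain the analysis default).

## A short worked example

```{r example, eval = FALSE}
trials <- simulate_experiment(design_config(n_per_group = 8), seed = 1)
res <- analyze_experiment(trials, n_iter = 1000, seed = 2)
res
res$updating$no_consolidation$table
res$attribution$permutation_ft
```

## Known limitations

* Single shared $\kappa$ per model is an assumption inherited from the
  parameter counts; differently precise target and schema memories are not
  separable here.
* No hierarchical pooling: single-subject fits on 56 trials are noisy, and
  boundary estimates ($p_{schema} = 0$) are common in weak-schema cells.
* The optional 2-SD performance exclusion filter is provided but off by
  default; synthetic cohorts contain no genuinely aberrant participants.
* Only the target/schema/uniform component family is implemented — no
  swap-to-other-item components, wrapped-normal alternatives, or circular
  regression.
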