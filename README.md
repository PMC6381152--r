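# schemup

Circular mixture-model analysis of schema formation and updating in
continuous-report (delayed-estimation) memory experiments.

## What problem this solves

In a continuous-report location memory task, participants reproduce where on
an invisible circle an item appeared, and the signed circular error (degrees,
in [-180, 180)) carries far more information than a correct/incorrect score.
When most items of a category cluster in one 90° quadrant (a *location
schema*), responses are pulled toward the schema mean; and when a schema is
shifted 90° clockwise mid-experiment, responses may revert to the old,
superseded mean. `schemup` is for researchers who want to quantify these
biases, and in particular to test whether a consolidation delay before
learning schema-inconsistent material changes how completely the old schema
is updated.

The core machinery is a family of mixture models of response error

```
p(e) = p_target · vM(e; target, κ) + p_schema · vM(e; schema mean, κ) + p_guess / 360
```

where `vM` is the von Mises (circular normal) density, per degree. The base
model (target + uniform; 2 free parameters, `p_guess` and `κ`) is compared
against variants adding a schema component (3 free parameters) centred on the
current schema mean (M2), the *original* superseded mean (M4), or the *new*
mean in force at learning (M5), via AIC/BIC on pooled or single-subject fits.
Group inference uses trial-level posterior attribution (responsibilities) and
a participant-level permutation test on pooled-fit group differences.
Schema-strength analyses (outside- minus inside-quadrant absolute error in
initial study) feed per-group correlations, a Fisher r-to-z comparison of
independent correlations, and a standardized regression.

Because the motivating design's participant data are not deposited, the
package ships a first-class synthetic-data generator
(`build_design()`/`simulate_responses()`) that emulates the full two-group,
four-phase experiment (2 × 32 participants, 336 studied items each, 28-trial
blocks with 22 inside- and 6 outside-quadrant trials, one category's schema
shifted 90° clockwise at new learning) from the generative mixture above.

## Worked example

```r
library(schemup)

trials <- simulate_experiment(design_config(n_per_group = 8), seed = 1)
res <- analyze_experiment(trials, n_iter = 1000, seed = 2)
res
#> Schema-updating analysis
#>   16 participants, 10752 trials (seed 2)
#>   Schematization (consistent FT): preferred M2 / M2
#>   Updating (inconsistent FT): preferred M4 / M4
#>   Mean old-schema responsibility (FT): 0.504 vs 0.348, p = 0.001

res$updating$no_consolidation
#> Model comparison (preferred by AIC: M4)
#>  model k      logL      AIC      BIC     dAIC     dBIC
#>     M3 2 -2529.806 5063.613 5071.822 532.4255 528.3207
#>     M4 3 -2262.594 4531.187 4543.502   0.0000   0.0000
#>     M5 3 -2529.806 5065.613 5077.927 534.4255 534.4255

res$attribution$permutation_ft
#> Permutation test (1000 iterations)
#>   group stats: A = 0.504, B = 0.348
#>   observed diff = 0.156, p (two-tailed) = 0.001 [add-one: 0.001998]
```

Reading this output: both groups' Final Test data on the *consistent*
category are better described once a schema component is added (M2 over M1) —
participants formed schemas. On the *inconsistent* category, the model with a
component on the old, superseded schema mean (M4) beats both the plain
mixture (M3, dAIC ≈ 532) and the new-schema variant (M5): a subset of
responses reverts to the old schema. The mean posterior probability of an
old-schema response is higher in the no-consolidation group (0.504) than in
the consolidation group (0.348) — the generative asymmetry for this simulated
cohort — and the participant-level permutation test rejects equality
(p = 0.001 at 1000 iterations).

`write_trial_table()`/`read_trial_table()` round-trip the long-format CSV
that all analysis functions accept, and `inst/cli/schemup.R` is a thin
command-line wrapper (`simulate`, `analyze`) over the same functions.

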