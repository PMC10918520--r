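# wutdiag

Diagnostic accuracy of the **WUT Venn diagram** — the weight / urine
colour / thirst composite used for practical hydration assessment in
field settings (sport, military, occupational health).

## The problem and the model

At a spot assessment, each of three field markers is tested against its
dehydration criterion:

| marker | criterion (dehydration-positive) |
|---|---|
| **W** — body-mass loss vs baseline | BML > 1 % (strict) |
| **U** — urine colour, 8-point chart | ≥ 5 |
| **T** — thirst, 1–9 Likert | ≥ 5 |

The baseline is the mean of the subject's three euhydrated first-morning
masses, and BML is loss-positive:
`BML = (baseline − mass) / baseline × 100`. Criteria met are counted,
giving WUT0–WUT3; two markers read as *likely dehydrated*, three as
*very likely dehydrated*.

The count is then evaluated as a diagnostic test against three reference
standards dichotomised at their ACSM thresholds — urine specific gravity
(USG) ≥ 1.020, urine osmolality > 700 mOsm/kg, plasma osmolality
> 290 mOsm/kg. For each threshold k ∈ {1,2,3} (test-positive when
`wut_count ≥ k`), stratum (morning/afternoon × euhydrated/free-living,
poolable) and standard, the package computes the 2×2 table, sensitivity
= TP/(TP+FN), specificity = TN/(TN+FP), PPV, NPV, the three-point ROC
operating set with (0,0)/(1,1) anchors, and a cut-off determination value
(Youden's J = sens + spec − 1, or distance to the (0,1) corner), with a
configurable 0.800 practical-significance flag. Undefined metrics (zero
denominators, e.g. no reference-positive visits in a euhydrated stratum)
are reported as `NA` with an explicit reason, and missing plasma values
propagate to missing calls excluded listwise per marker.

Because no subject-level data are published for this design,
`simulate_cohort()` generates synthetic cohorts with the same geometry
(24 subjects × 2 conditions × 3 days × 2 timepoints = 288 visits), a
latent dehydration state that induces the cross-marker correlation, a
rejection-sampled euhydration screen (`usg < 1.020`), and stratified
plasma missingness (6+4+4+3 = 17, leaving 271 plasma-analysable records).
See `vignettes/wut-hydration-accuracy.Rmd` for the full model and its
assumptions.

## Worked example

```r
library(wutdiag)
cfg    <- sim_config(rng_seed = 1)
visits <- inject_missingness(simulate_cohort(cfg), cfg)
wut    <- score_wut(visits)            # baselines from EUH mornings
ref    <- classify_reference(visits)
metrics <- evaluate_accuracy(wut, ref)
subset(metrics, timepoint == "both" & condition == "both")
```

which prints (pooled over strata, seed 1):

```
  marker k TP FP FN  TN sensitivity specificity   ppv   npv cutoff_value cutoff_k
1    USG 1 44 32  2 210       0.957       0.868 0.579 0.991        0.869        2
2    USG 2 43 16  3 226       0.935       0.934 0.729 0.987        0.869        2
3    USG 3 37  7  9 235       0.804       0.971 0.841 0.963        0.869        2
4   UOSM 1 37 39  2 210       0.949       0.843 0.487 0.991        0.831        2
5   UOSM 2 36 23  3 226       0.923       0.908 0.610 0.987        0.831        2
6   UOSM 3 33 11  6 238       0.846       0.956 0.750 0.975        0.831        2
7   POSM 1 35 37 14 185       0.714       0.833 0.486 0.930        0.620        2
8   POSM 2 35 21 14 201       0.714       0.905 0.625 0.935        0.620        2
9   POSM 3 28 13 21 209       0.571       0.941 0.683 0.909        0.620        2
```

Read it as a screening-test table: specificity climbs with k, so WUT2/WUT3
rule dehydration **in** (high specificity against all three standards),
while the high WUT1 sensitivity for the urinary standards means WUT0 rules
it **out**; plasma osmolality tracks the score most weakly. `cutoff_value`
is the best Youden J over the three operating points, attained here at
k = 2 throughout.

The same pipeline, as a narrated analysis writing its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R   # cohort.csv (+ truth copy): 288 visits, 271 plasma
Rscript analysis/02_score.R      # baselines.csv, wut.csv, reference_calls.csv
Rscript analysis/03_evaluate.R   # metrics.csv, roc_points.csv
Rscript analysis/04_report.R     # report.txt (starred 0.800-rule flags)
```

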