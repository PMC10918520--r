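---
title: "Methods: the WUT hydration score and its diagnostic-accuracy evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the WUT hydration score and its diagnostic-accuracy evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wutdiag)
```

## The measurement problem

Field practitioners — coaches, military medics, occupational-health staff —
need a hydration check that requires no laboratory. The WUT Venn diagram
combines three such markers per spot assessment:

* **W** — body-mass loss (BML) relative to a euhydrated baseline,
  dehydration-positive when the loss is *strictly greater than* 1 % of
  baseline;
* **U** — urine colour on the validated eight-point chart, positive at a
  value of **5 or darker**;
* **T** — thirst on a 1–9 Likert scale (1 = "not thirsty at all",
  9 = "very, very thirsty"), positive at **5 or higher**.

Each criterion met contributes 1 to a count of 0–3. Two markers met reads
as *likely dehydrated*, three as *very likely dehydrated*. The baseline
mass is the arithmetic mean of the subject's three euhydrated first-morning
masses, and BML is reported loss-positive,
$\mathrm{BML} = (m_\text{base} - m)/m_\text{base} \times 100$, which is the
orientation under which the "> 1 %" criterion is coherent (the change-
relative-to-baseline convention carries the opposite sign; we document the
negation rather than emit negative losses).

The score is evaluated as a diagnostic test against three laboratory
reference standards, each dichotomised by its ACSM dehydration threshold:
urine specific gravity (USG) **≥ 1.020**, urine osmolality (U~OSM~)
**> 700 mOsm/kg**, plasma osmolality (P~OSM~) **> 290 mOsm/kg**. The
mixture of inclusive and strict comparators is deliberate and tested at
the exact boundaries. For USG the inclusive form is the one consistent
with the euhydration screen (usg < 1.020) partitioning the scale; the
strict variant is available via
`reference_thresholds(usg_comparator = ">")` for reproducing the other
convention seen in summary-table captions.

## Diagnostic-accuracy machinery

For a threshold $k \in \{1,2,3\}$ a visit is *test-positive* when
`wut_count >= k`; *reference-positive* means dehydrated under the given
standard. Within each stratum (morning/afternoon × euhydrated/free-living,
each poolable to "both") `build_contingency()` forms the 2×2 table, and
`compute_metrics()` reports

$$\text{sens} = \frac{TP}{TP+FN},\quad
  \text{spec} = \frac{TN}{TN+FP},\quad
  \text{PPV} = \frac{TP}{TP+FP},\quad
  \text{NPV} = \frac{TN}{TN+FN}.$$

Interpretation follows the SpPin/SnNout reading: high specificity at
WUT ≥ 2 or 3 means a positive call rules dehydration *in*; high sensitivity
at WUT ≥ 1 means a negative call (WUT0) rules it *out*, i.e. determines
euhydration.

Three numerical choices matter here:

* **Undefined metrics are surfaced, never silently 0.** Any zero
  denominator yields `NA` plus a reason column (e.g. a euhydrated-condition
  stratum can contain no USG-positive visits, making sensitivity
  undefined — the report prints `NA (no reference-positive visits)`).
  Missing plasma values propagate to missing calls and are excluded
  listwise *per marker*, so urinary tables keep full totals while plasma
  tables shrink.
* **The ROC "curve" is three points.** A 0–3 count admits exactly the
  operating points $k = 1, 2, 3$; `roc_points()` returns them in
  (1 − specificity, sensitivity) coordinates framed by the trivial anchors
  (0, 0) and (1, 1). No interpolation or AUC is computed — none would be
  meaningful for three points.
* **Cut-off determination.** The source literature cites a cut-off method
  without printing its formula, so both standard candidates are
  implemented: Youden's $J = \text{sens} + \text{spec} - 1$ (maximised
  over $k$; the default) and the Euclidean distance to the perfect corner
  (0, 1) (minimised). The criterion used is always echoed in the output.
  Ties break toward the larger $k$ — the more specific call — using a
  1e-9 tolerance so that algebraically tied $J$ values are ties despite
  floating-point rounding. The practical-significance flag marks a
  sensitivity or specificity that **reaches** the cut-off value
  (inclusive, so a perfect classifier whose $J$ equals its sensitivity is
  flagged) **and exceeds** 0.800 (configurable).

## What the synthetic cohort emulates

No subject-level data are published for this design, so
`simulate_cohort()` generates cohorts with the study's geometry: 24
subjects (half men, mass $\sim N(81.0, 15.9^2)$ kg; half women,
$N(68.8, 15.2^2)$, truncated at 40 kg), free-living (FL) then euhydrated
(EUH) conditions, 3 days × morning/afternoon — 288 visits. Afterwards
`inject_missingness()` removes plasma values in the observed 6/4/4/3
pattern (EUH-morning/EUH-afternoon/FL-morning/FL-afternoon), leaving 271.

The generative mechanism is intentionally the simplest structure that
induces the cross-marker correlation the analysis assumes:

1. latent state $D \sim \text{Bernoulli}(p_{\text{cond},\text{tp}})$;
2. latent deficit $z = s\,D + \varepsilon$, $\varepsilon \sim N(0, 0.25)$,
   with coupling $s$ = `latent_deficit_scale` (default 1);
3. monotone linear marker maps plus Gaussian noise, rounded/clipped to
   instrument scales (USG to 3 decimals on 1.000–1.040, osmolalities to
   whole mOsm/kg, colour/thirst to their charts, mass to 0.01 kg);
4. EUH visits are **rejection-sampled** until `usg < 1.020`, mirroring the
   enrolment screen structurally instead of shifting distributions.

Defaults are documented assumptions, not calibrated values — the study's
marker summary table is not machine-readable in our source text. Chosen
once on physiological plausibility: dehydration probability 0.50/0.40
(FL morning/afternoon) vs 0.05/0.10 (EUH), so dehydration is rarer under
enforced euhydration and rarest on EUH mornings; at $z = 1$ the maps give
roughly USG 1.022, U~OSM~ 750 mOsm/kg, P~OSM~ 292 mOsm/kg, colour 5.5,
thirst 6 and 1.5 % mass loss — i.e. a typically dehydrated visit sits just
beyond every threshold, a euhydrated one (USG 1.010, U~OSM~ 400, P~OSM~
285, colour 2, thirst 2.5) well inside. Noise SDs (0.004 USG, 80 and 3
mOsm/kg, 0.7/0.8 scale units, 0.15 kg) approximate instrument plus
short-term biological variability.

What the generator does **not** emulate: fluid-balance physiology (sweat,
renal dynamics), within-day carry-over, food/fluid logs, menstrual-cycle
effects, or the afternoon body-mass confound (meals raise afternoon mass
independently of hydration; the baseline is applied unchanged to afternoon
visits, as in the emulated protocol, and the known inaccuracy of W in
afternoon settings is a documented limitation, not corrected). Passing
tests therefore certify the *pipeline* — scoring, tabulation, metrics —
and the qualitative recoverability of a strong latent signal, not the
study's empirical accuracy values, which cannot be reproduced without the
raw data.

## Worked example

```{r pipeline}
cfg <- sim_config(rng_seed = 1)
visits <- inject_missingness(simulate_cohort(cfg), cfg)
wut <- score_wut(visits)                 # baselines from EUH mornings
ref <- classify_reference(visits)
metrics <- evaluate_accuracy(wut, ref)
dplyr::filter(metrics, timepoint == "both", condition == "both")[,
  c("marker", "k", "sensitivity", "specificity", "cutoff_value", "cutoff_k")]
```

With the default (moderate) coupling the expected pattern appears:
specificity rises with $k$ and is high at WUT ≥ 2 and ≥ 3 for all three
standards, sensitivity at WUT ≥ 1 is high for the urinary standards and
weakest for plasma osmolality — the same qualitative shape the tool shows
on real data.

## Test and verification sizes

The test-suite problem sizes are chosen to make stochastic properties
sharp while keeping the default run quick: the design-accounting and
determinism checks use the full 288-visit cohort; marker-monotonicity uses
1008 visits; metric correctness is checked against an independent
brute-force recount (plain loops over raw rows) on 100+ randomised
fixtures of 15–80 visits; the latent-signal recovery check uses 576 visits
(48 subjects) with coupling 1.5, at which every marker separates by at
least two noise SDs and specificity at WUT ≥ 2/3 and urinary sensitivity
at WUT ≥ 1 all exceed 0.9. `pROC` serves as an external cross-check of the
operating points on one simulated cohort.

## Known limitations

* Marker maps are linear in the latent deficit; real dose–response curves
  saturate (urine concentration plateaus near maximal antidiuresis).
* The latent state is binary; graded hypohydration is only represented
  through the Gaussian deficit noise.
* Baselines computed from fewer than three euhydrated mornings are flagged
  (`baseline_flag`) but still used, so truncated datasets remain scorable;
  supply `baselines` explicitly for free-living-only data.
* Probabilities and effect sizes are assumptions; any quantitative
  agreement with published accuracy values would be coincidental and is
  not claimed or tested.
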