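# dyadphys

Autonomic physiology features and rating prediction for dyadic
visuomotor-tracking experiments.

## The scientific problem

Pairs of participants (dyads) perform a joint target-tracking task, each
partner controlling one of two perpendicular axes of a ball on a screen,
either collaboratively (one shared ball and target) or individually. After
each 120-s trial, each participant rates on a 1–9 scale their own
performance (R1), their partner's performance (R2) and, after collaborative
trials, the collaboration itself (R3). Two non-exclusive hypotheses exist
about where those subjective ratings come from:

* **objective route** — the rater tracks the actual error (cumulative
  ball–target distance in pixels) and reports it;
* **interoceptive route** — the rating reflects a *feeling* about the
  performance that is carried by the state of the autonomic nervous system,
  observable in heart rate variability (HRV), respiration and electrodermal
  activity (EDA).

`dyadphys` implements the full analysis that discriminates these routes:
23 autonomic parameters per subject-trial, a quadratic discriminant
classifier (QDA) predicting rating levels either from the aggregated
autonomic feature vector or from the matched tracking error, macro-F1
scoring under two cross-validation schemes, backward feature selection,
permutation feature importance, label-permutation significance tests, and
the supporting correlation statistics — plus a fully seeded synthetic
cohort generator, so every stage is testable without access to any human
recordings.

## The statistics at the core

For an NN-interval series the package computes the standard time-domain
indices (mean NN, SDNN, RMSSD, NN50, pNN50), the Poincaré-plot geometry
(SD1, SD2, r_RR, with SD1 = RMSSD/√2 exactly under the population-moment
convention used throughout), and Burg autoregressive band powers
(VLF 0.009–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz, total power, LF/HF, LFnu,
HFnu). Respiration yields the instantaneous breathing-rate mean/SD from
zero-crossings of the 0.05–0.5 Hz band-passed trace and normalised
mid/high-frequency band powers. EDA is decomposed into tonic (SCL) and
phasic (SCR) components by nonnegative deconvolution against a
bi-exponential Bateman kernel; both are integrated over 10-s windows
(iSCL/iSCR mean and SD).

Classification is QDA with empirical priors and per-class
maximum-likelihood covariances (ridge-regularised), scored by the macro
F1 = 2 / (1/recall + 1/precision), where recall and precision are
class-averaged TPₗ/Pₗ and TPₗ/(TPₗ+FPₗ). Cross-validation is
leave-one-sample-out or leave-one-subject-out (the "population model").
Significance is assessed by label permutation with the add-one-corrected
p = (1 + #{F1<sub>perm</sub> ≥ F1<sub>obs</sub>}) / (n<sub>perm</sub> + 1),
with Benjamini–Hochberg control across cells.

## Worked example

```r
library(dyadphys)

cfg <- run_config(
  cohort = cohort_config(n_dyads = 3, days = 1,
                         trials_per_condition_per_day = 7, seed = 42),
  n_perm = 99, run_selection = FALSE, run_importance = FALSE, L = 4)
res <- run_pipeline(cfg)
report_tables(res)$sample[, 1:6]
```

```
  rating     condition f1_autonomic p_autonomic prec_autonomic recall_autonomic
1     R1 collaborative    0.2443820        0.14      0.2390110        0.2500000
2     R2 collaborative    0.2123483        0.33      0.1770833        0.2651515
3     R3 collaborative    0.1834633        0.47      0.1515837        0.2323232
4     R1    individual    0.2543066        0.10      0.3598485        0.1966346
```

Each row is one analysis cell (rating × condition). `f1_autonomic` is the
leave-one-sample-out macro F1 of the QDA trained on all 23 autonomic
parameters; `p_autonomic` its label-permutation p-value (99 permutations,
so the floor is 0.01). At this deliberately tiny demo scale (6 subjects,
42 collaborative samples) the full 23-parameter QDA is heavily overfit and
hovers near chance — exactly why the pipeline's backward feature selection
(`run_selection = TRUE`) exists: on the reduced parameter set the
autonomic F1 separates cleanly from the objective-error column and from
the permutation null, which is what the acceptance suite verifies over
seeded cohorts. A full-scale run (14 dyads, 2 days, 784 subject-trials)
uses the same call with the default `cohort_config()`.

The command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/dyadphys-pipeline --dyads 3 --days 1 --seed 42 \
    --n-perm 99 --no-selection --no-importance --out results/
```

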