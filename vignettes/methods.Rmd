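---
title: "Models, parameters and design choices in dyadphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in dyadphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dyadphys` asks whether subjective performance ratings in a dyadic
tracking task are better predicted from the rater's autonomic state (heart
rate variability, respiration, electrodermal activity) or from the
objective tracking error. This vignette documents the models, the tunable
parameters, and the choices made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## The analysis model

Each subject-trial contributes a 23-dimensional autonomic feature vector
(15 HRV, 4 respiration, 4 EDA parameters) and three cumulative tracking
errors (own axis, partner axis, Euclidean). For each analysis cell —
rating kind (R1/R2/R3) crossed with condition (collaborative/individual;
R2 and R3 exist only after collaborative trials, giving four cells) — the
pooled features are min–max normalised to [0, 1], ratings are
outlier-corrected and restricted to the `L = 6` most frequent levels, and
a quadratic discriminant classifier predicts the rating level from either
the aggregated autonomic vector or the single matched error column.
Performance is the macro F1 under leave-one-sample-out and
leave-one-subject-out cross-validation; significance comes from label
permutation.

### QDA conventions

* Per-class covariances use the maximum-likelihood divisor *n*. This is
  the convention under which duplicating every sample leaves the model
  exactly invariant, and it is what the Gaussian-density derivation of QDA
  gives directly.
* Covariances are regularised as Σ + λ·(tr Σ/d)·I with λ starting at 1e-6
  and escalating tenfold until the Cholesky factorisation succeeds. With
  class counts below the feature dimension (common at reduced simulation
  scales) the ridge is what keeps the discriminant defined; it is a
  numerical floor, not a tuning parameter.
* Priors are empirical class frequencies. Ties in the discriminant are
  broken toward the lowest class index, making predictions reproducible.
* A cross-validation fold whose training remainder leaves any class with
  fewer than two samples is skipped and counted; the original analysis
  does not state how such folds were handled, and skipping is the only
  choice that neither fabricates a covariance nor silently drops a class.

### Scoring

Macro recall and precision average TPₗ/Pₗ and TPₗ/(TPₗ+FPₗ) over the L
classes, with empty denominators contributing zero — this keeps the score
defined on skewed folds. F1 is their harmonic mean, zero when both vanish.

### Feature selection and importance

Backward selection greedily removes the parameter whose omission yields
the strongest *strict* increase in leave-one-sample-out F1, and stops when
no removal improves the score. Strictness matters: with a discrete score
on a finite sample, accepting ties would walk through plateaus and remove
arbitrary features. Permutation importance substitutes, for each held-out
sample, the target feature's value from every other sample — N(N−1)
evaluations from N trainings, the tractable reading of leave-one-out on
the substituted dataset; a `max_variants` cap exists for large N. The
permutation significance test uses the add-one-corrected
p = (1 + #{F1\_perm ≥ F1\_obs})/(n\_perm + 1), so p is never zero and its
floor is 1/(n\_perm + 1).

## Signal processing choices

* **Tachogram and spectra.** NN intervals are cubically interpolated at
  4 Hz (Nyquist comfortably above the 0.4-Hz HF edge), demeaned, and
  fitted with a Burg autoregressive model of order 16 (order is
  configurable; only "autoregressive modelling" is prescribed). Band
  powers are numerical integrals of the one-sided AR spectrum. A 120-s
  trial barely covers one VLF period (0.009 Hz ⇒ 111 s), so VLF carries a
  `vlf_low_confidence` attribute rather than being suppressed — it is
  computed regardless, as in the emulated analysis.
* **Poincaré algebra.** SD1² is the uncentred half-mean-square of
  successive differences, which makes SD1 = RMSSD/√2 an exact identity
  rather than an approximation; SD2² = 2·Var(NN) − SD1² (population
  variance), floored at zero. A constant series yields SD1 = SD2 = 0 and
  an explicit `NA` for r\_RR — never a silent zero.
* **pNN50 denominator** is the number of successive pairs (n−1); "total
  number of intervals" is ambiguous by one, and the pair count is the
  quantity the numerator is drawn from.
* **Respiration.** The band-pass (0.05–0.5 Hz) is a 4th-order Butterworth
  applied forward–backward. Instead of reflection padding, the signal is
  demeaned, cosine-tapered at the edges and zero-padded: reflection
  padding injects an in-band artefact at the junction whenever the trace
  carries energy far outside the band, whereas a tapered, zero-padded
  signal has an exact zero-state response. The taper rescales amplitudes
  near the edges but cannot move zero-crossings; the first and last breath
  intervals (partially observed) are dropped. Breaths are rising
  zero-crossings; intervals at or below 0.5 s are artifacts (the boundary
  is inclusive so an exactly-2-Hz oscillation is excluded). A trace whose
  band-passed energy is below 10⁻⁴ of its total is rejected as containing
  no respiration signal.
* **EDA decomposition.** The exact continuous decomposition analysis of
  the original toolbox is unspecified; the package substitutes a
  documented alternative validated against generator ground truth: the
  tonic level is a smoothed sliding-window 10th-percentile baseline
  (bias-corrected upward by the robust noise SD, since a lower quantile of
  a noisy trace sits qnorm(0.1) noise-SDs below the level), and the
  nonnegative residual is deconvolved against a Bateman kernel
  (τ_rise = 0.75 s, τ_decay = 2 s, configurable) by Lawson–Hanson
  nonnegative least squares on a 0.5-s driver grid. SCR is the
  re-convolved nonnegative driver, SCL is defined as trace − SCR, so
  additivity is exact and SCR ≥ 0 by construction. Known limitation: a
  strongly trending tonic leaks slightly into the phasic component, as in
  any quantile-baseline method.
* **Windowed integrals** use the trapezoidal rule on 10-s windows, with
  the trace extended by one sample (constant continuation) so every
  window spans exactly 10 s; partial trailing windows are dropped.

## Rating preprocessing choices

* Outlying raters are detected on per-subject *medians* with Tukey fences
  (1.5 IQR beyond the quartiles, quartiles by linear interpolation) and
  shifted by the difference to the other subjects' median of medians,
  rounded and clipped to the 1–9 scale — labels must remain integer
  levels.
* Level selection keeps the six most frequent levels per cell; frequency
  ties at the boundary go to the level closer to the grand median, then to
  the lower level (deterministic). Levels with fewer than two samples are
  additionally dropped at small simulation scales — a class without two
  samples cannot contribute a covariance.

## The synthetic cohort: what it emulates and what it does not

The generator reproduces the *structure* the analysis assumes: 14 dyads,
2 days, 7 trials per condition per day, 120-s trials (784 subject-trials),
10-Hz respiration/EDA, R-peak surrogates, pixel trajectories with a
constant-speed, randomly reversing target, and integer ratings with R2/R3
only after collaborative trials.

A latent standard-normal arousal per subject-trial modulates chronotropy
(mean NN −50 ms per SD), the LF/HF balance (±0.10 variance fraction per
SD), respiration rate (+0.025 Hz per SD) and electrodermal phasic activity
(+2 SCR/min per SD); ratings are
round(6 + 2·c_a·arousal − 2·c_e·z(log error) + subject offset + noise),
clipped to 1–9. The couplings c_a (`coupling_autonomic`, default 0.6) and
c_e (`coupling_error`, default 0.2) are the experiment's manipulated
variables: c_a = c_e = 0 gives a null world in which ratings are
unpredictable from either source. `subject_heterogeneity` (default 0.5)
scales stable between-subject offsets in both physiology baselines and
rating usage; `rating_noise_sd` defaults to 0.8 rating units, which
reproduces the qualitative feature that raters use about five adjacent
levels of the scale, concentrated in its upper half. No distributional
description of the original signals exists, so these defaults are chosen
once as physiologically plausible values and varied only through the
configuration, never per test.

The NN process is a sinusoidal LF (0.1 Hz) plus HF (at the respiration
rate) modulation with white noise — the simplest process whose band powers
are controllable and auditable — not an integral-pulse-frequency model;
partners' ratings are generated independently (matching the observed weak
between-partner correlation). Ground truth (arousal, subject offsets, SCR
events) travels in a separate attribute that no analysis function reads.

What a green test therefore establishes: the pipeline recovers structure
that is present by construction, at the stated couplings and scales. It
does not establish anything about real physiology, about the magnitude of
real-data F1 scores, or about features of real signals the generator lacks
(ectopic beats, movement artifacts, nonstationary baselines, rater drift).

## Acceptance-test design notes

* The permutation-calibration criterion sets `subject_heterogeneity = 0`
  in addition to zero couplings: with heterogeneity, subject-constant
  offsets enter both features and ratings, the pooled sample genuinely
  carries in-sample association, and a calibrated test *should* reject —
  that world is not a null.
* The structure-recovery and heterogeneity-ordering criteria score the
  backward-selected parameter set, as the emulated analysis does for its
  reported tables (both cross-validation schemes are applied to the same
  reduced parameter sets). At the reduced cohort sizes the full
  23-parameter QDA is
  overfit to near-chance, and the selected set is the quantity the design
  actually reports.
* The noise-pruning criterion uses six classes of 15 samples with modest
  separation: pruning only manifests where noise features genuinely hurt a
  class-covariance classifier, which is the small-sample many-class regime
  the rating data occupy.
* Simulation scales are reduced (2–4 dyads, 1–2 days) to keep the suite
  inside its runtime budget; counts and thresholds are otherwise as
  stated.

## Known limitations

* No QRS detection: the package consumes R-peak times directly.
* No ectopic-beat cleaning beyond positivity checks.
* The EDA decomposition is validated against synthetic ground truth, not
  against the original toolbox's output.
* VLF estimates from 120-s trials are low-confidence by construction.
* Backward selection re-scores the full cross-validation per candidate;
  whether the original analysis re-used fold assignments is unknown.
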