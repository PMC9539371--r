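---
title: "Conservative EEG-based classification of behavioral impairment during spike-wave discharges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservative EEG-based classification of behavioral impairment during spike-wave discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdclass)
```

## The problem

Spike-wave discharges (SWDs) are the generalized 2.5–5 Hz EEG signature of
absence epilepsy. Behavior during an individual SWD can range from complete
unresponsiveness to no detectable deficit, and the difference matters
clinically — for driving safety, treatment decisions, and the question of
when a patient with persisting discharges can be considered functionally
seizure-free. Behavioral testing during discharges is rarely available in
routine practice, so `swdclass` implements a purely EEG-based classifier
that labels each SWD *spared* (responsiveness preserved) or *impaired*.

The design objective is deliberately asymmetric: an impaired SWD must never
be classified as spared. Formally the classifier targets a spared
predictive value (SPV) of 100% — zero false discoveries for the spared
class — and maximizes spared sensitivity subject to that constraint. A
timid classifier that calls nothing spared trivially satisfies the
constraint; all of the method's machinery exists to recover as many truly
spared SWDs as possible without ever breaking it.

## The model

For each SWD, two analysis windows are extracted: a **preictal** window
covering `[onset − 1000 ms, onset)` and an **ictal** window covering
`[onset, onset + 500 ms)` (half-open in samples; the onset sample is
ictal). The defaults are the window sizes at which spared predictive value
peaks for spatial-pattern features; both are configurable and
`window_grid_search()` reproduces the search over preictal 100–5000 ms and
ictal 100–1000 ms.

Three feature families are computed per window:

* **Basic** — mean spike-band power (15–50 Hz), mean wave-band power
  (2.5–6 Hz), and the SWD duration in ms (ictal vector only). The band
  edges are package design choices: the wave band brackets the 3–4 Hz
  fundamental, the spike band the sharp transient's energy.
* **Extended** — per channel, averaged across channels: Hjorth activity
  (variance), mobility (`sqrt(var(diff(x))/var(x))`, per-sample first
  difference), complexity; RMS amplitude; Welch band powers over delta
  1–4, theta 4–8, alpha 8–13, beta 13–30, low gamma 30–50 and high gamma
  50–min(100, Nyquist−1) Hz; the first four moments of the voltage and of
  the instantaneous power `x(t)^2` (kurtosis non-excess, so a Gaussian
  scores 3); and multiscale permutation entropy — order 4, delay 1,
  natural log, averaged over non-overlapping coarse-graining scales 1–3.
  Order 4 was chosen because its entropy ceiling `ln 24 ≈ 3.18` nats is
  consistent with the 2.1–2.7 nat range typical of these windows, while
  order 3 (ceiling `ln 6 ≈ 1.79`) is not. The basic features are a subset
  of the extended computations.
* **CSP** — common spatial patterns. Per-epoch spatial covariances are
  trace-normalized, averaged per class, and the filters solve the
  generalized eigenproblem `C_i w = λ (C_s + C_i) w`; λ is the impaired
  share of composite variance along the filter, and the `k = 5` filters
  with largest `max(λ, 1−λ)` are kept per window (an odd `k` is
  deliberate: selection is by discriminability, not symmetric
  pair-taking). Features are normalized log variance shares
  `log(var_j / Σ var_j')`, giving 10 CSP features over both windows.

Non-CSP features are screened univariately with a two-sided Wilcoxon
rank-sum test at `p < 0.001` (exact enumeration up to combined n = 12
without ties, tie- and continuity-corrected normal approximation
otherwise). CSP features bypass the screen — they are already capped by
the filter count. By default selection is re-run inside every training
fold (`scope = "per_fold"`); a `"global"` scope reproducing whole-dataset
selection is available for comparison, with the leakage caveat documented.

Selected features feed a scalar scorer — a Fisher linear discriminant
(pseudo-inverse pooled covariance, so collinear columns degrade
gracefully) or a linear SVM with cost 1 — oriented so larger scores mean
more impaired. Window strategies: *preictal* only, *ictal* only,
*concatenation* of both feature vectors into one scorer, or *fusion*:

$$ s_{\mathrm{fused}} = \alpha\,\mathrm{LLR}_{\mathrm{pre}}(s_{\mathrm{pre}})
   + (1-\alpha)\,\mathrm{LLR}_{\mathrm{ict}}(s_{\mathrm{ict}})
   + \log\frac{\pi_{\mathrm{imp}}}{\pi_{\mathrm{sp}}} $$

with class-conditional Gaussian score models per window (per-class means
and standard deviations, σ floored at 10⁻⁶ of the score range; priors
empirical) and a preictal weight α searched on a 0.01-step grid. Four
feature sets × four window strategies × two classifiers give the 32-model
grid that `build_model_grid()` enumerates and `run_pipeline(model =
"grid")` evaluates.

## Conservative calibration

The decision rule is `spared ⟺ fused score < τ` with
`τ = min(impaired calibration scores) − margin`
(`calibrate_threshold()`), which by construction admits zero false-spared
on its calibration data. Two practical refinements in `fit_swd_model()`
make that construction meaningful beyond the training set:

* **Out-of-fold calibration scores.** Scores from a scorer evaluated on
  its own training data are optimistically separated; a threshold placed
  at their impaired minimum is too permissive for unseen events. The
  whole scoring chain (CSP fit, selection, scorer) is therefore refit in
  an internal stratified 5-fold split — repeated three times with
  different fold assignments and pooled — and the threshold, the fusion
  weight and the Gaussian score models are all estimated from these
  held-out scores.
* **Data-driven margin.** The minimum of *n* impaired scores
  overestimates the population lower tail, so with `margin = 0` the
  threshold sits exactly at the impaired edge of the class gap and the
  single most extreme unseen impaired event tends to fall just below it.
  The default `margin = "auto"` is the larger of (a) half the separating
  gap between the highest spared and lowest impaired calibration scores —
  a max-margin placement that never sacrifices a calibration spared call —
  and (b) the spacing between the lowest and third-lowest impaired
  calibration scores, an order-statistic extrapolation one gap further
  down the impaired tail. Any fixed numeric margin (including 0) can be
  supplied instead.

The α search evaluates each candidate by inner 5-fold cross-validation on
the calibration scores, with the inner threshold taken over all impaired
scores — mirroring the final calibration, under which the spared PPV
criterion ties at 1 by construction. Candidates are ranked by spared PPV,
then spared sensitivity, then a *robust* sensitivity (spared calls
surviving a threshold extrapolated one lower-tail spacing below the
lowest impaired score — order statistics only, hence invariant to the
score scale, which varies across α), and finally by smaller α. Without
the all-impaired threshold construction, the inner PPV estimate is
dominated by the order-statistic artifact above and the search drifts
toward noise-dominated weightings that make few, lucky spared calls.

Evaluation (`cross_validate()`) is stratified 10-fold at the SWD level
with everything training-dependent refit per fold, predictions pooled
across folds, and spared-positive metrics (`eval_report()`) in which 0/0
ratios are reported as `NA`, never silently 0 or 1. A
`group_by_patient = TRUE` mode keeps each patient's SWDs in one fold for
users worried about patient-identity leakage; the default per-SWD
stratification mirrors the common per-event protocol. Patient-level
labels use a logical-OR rule (`aggregate_patient()`): a patient is spared
only if every one of their SWDs is called spared.

## The synthetic cohort generator

Clinical EEG with per-SWD behavioral labels is not publicly available, so
`generate_dataset()` builds a labeled stand-in cohort with the contrasts
the method exploits. Defaults describe a 34-patient cohort with 81 spared
and 49 impaired SWDs:

* **Durations** lognormal, truncated to [300 ms, 20 s]: spared mean
  947 ms (SD 414), impaired mean 4336 ms (SD 3269) — the SDs are the
  reported standard errors scaled to the class sizes.
* **Waveform**: each SWD is a spike-plus-wave composite — a 2.5–5 Hz
  sinusoid (default fundamental 3.5 Hz, ±5% per-event jitter) with a
  ~20 ms Gaussian transient riding each wave peak and 100 ms cosine
  on/off ramps. Wave amplitude 45 µV (spared) vs 90 µV (impaired).
* **Topography**: spared SWDs use an anterior-dominant channel profile,
  impaired a posterior-shifted one. This is the feature that makes the
  classes separable for CSP: normalized log-variance features are
  invariant to overall amplitude, so a purely amplitude-based contrast
  would be invisible to them, and real spared/impaired discharges do
  differ in scalp distribution.
* **Preictal state**: a 2 s delta-band (1.5–3.5 Hz) component before each
  onset, 8 µV baseline, doubled for impaired events.
* **Background**: per-channel 1/f noise (10 µV RMS) plus a posterior
  10 Hz alpha rhythm with a slow amplitude envelope.

Identical configuration and seed give bit-identical output. The generator
emulates the statistical contrasts only — it contains no thalamocortical
physiology, no artifacts (blinks, EMG), no non-SWD epileptiform activity,
and its class separation is cleaner than clinical data. Passing tests on
synthetic cohorts therefore demonstrates that the pipeline recovers known
structure under the stated contrasts, not that the classifier's clinical
operating point transfers to real patients.

## Numerical choices and degenerate inputs

* Windows are half-open in samples; events with insufficient preictal
  context are excluded with a typed warning, never zero-padded (padding
  would corrupt preictal features).
* Recordings are harmonized to 256 Hz (the lowest rate across typical
  cohorts) with polyphase anti-aliased resampling, band-passed 0.5 to
  min(100, Nyquist−1) Hz, and common-average referenced.
* Constant channels: Hjorth mobility/complexity and permutation entropy
  are defined as 0; all-zero windows yield zero powers, not errors.
* A rank-deficient composite covariance in CSP is ridge-regularized by
  `1e-8 · trace/channels` with a warning; `k` greater than the channel
  count is an error.
* If no feature survives the `p < 0.001` screen, the single best-ranked
  feature is kept (with a warning) so a scorer can always be trained.
* Exact Wilcoxon enumeration uses a dynamic program over doubled midranks
  (integers even under ties); the two-sided p is the probability of a
  rank sum at least as far from its mean as observed.
* EDF I/O quantizes to 16 bits over a symmetric physical range; round
  trips are exact to half a quantization step.
* Fold counts adapt downward when a class is smaller than the requested
  folds; with fewer than 3 events in a class, calibration falls back to
  resubstitution scores.

## Problem sizes

The test suite and the acceptance script run the full experiment at the
cohort's natural size (130 SWDs over 34 patients, 16 channels at 256 Hz;
10-fold outer CV with 3×5 internal calibration refits per fold), which
completes in well under a minute on one core. Unit tests use smaller
cohorts (20–60 SWDs over 4–10 patients) chosen to keep each property
check sharp rather than to exercise scale.

## Known limitations

* The fusion Gaussians are heteroscedastic (per-class σ), so the
  log-likelihood ratio is quadratic and non-monotone in the raw score;
  extreme spared scores can map to impaired-looking fused scores. This is
  conservative (never unsafe) but can cost sensitivity; the α search's
  robust criterion mitigates it.
* The zero-false-spared guarantee is a property of the calibration data
  and the margin construction, not a distribution-free bound; on real
  data the appropriate margin depends on the within-class score spread
  across recording conditions.
* Patient-level validation assumes SWD-level predictions are exchangeable
  within patient; systematic per-patient montage or amplitude effects are
  only partially emulated by the generator.
* The pipeline classifies *marked* SWDs; detection/marking of discharges
  and artifact rejection are out of scope.
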