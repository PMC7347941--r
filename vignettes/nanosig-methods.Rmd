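---
title: "Methods: single-molecule nanogap signal classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule nanogap signal classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosig)
library(dplyr)
```

## The measurement and the analysis problem

A mechanically controllable break junction (MCBJ) bends a substrate until a
gold nanowire breaks, leaving a sub-nanometre electrode gap. Under a fixed
bias (100 mV here) a tunnelling current flows across the gap; when a single
molecule transiently resides between the electrodes the current jumps above
the baseline, producing a pulse whose amplitude, duration (dwell time) and
intra-pulse variability carry information about the molecule. The analytes
are the three monoamine neurotransmitters dopamine (DA), norepinephrine
(NE) and serotonin (5-HT). Their single-molecule current distributions
overlap almost completely (means near 15, 14 and 15 pA with spreads of
about 7 pA), so no threshold on amplitude can identify a molecule; the
pipeline instead classifies every pulse with a supervised model and lets
the evidence accumulate across many pulses.

The workflow is:

1. **Detection** — estimate the baseline, extract pulse signals.
2. **Featurization** — each pulse becomes ten region-average currents
   `I1..I10` plus derived statistics.
3. **Noise removal** — two rounds of positive–unlabeled (PU) learning
   remove electrode-migration spikes and matrix contaminants.
4. **Classification** — a gradient-boosted tree ensemble labels each pulse.
5. **Identification** — a plurality vote and count ratios aggregate the
   per-pulse labels into a molecule identity and a mixture composition.

## Trace model and simulator

No public single-molecule traces exist for this system, so the package
ships a seeded simulator (`simulate_trace()`) that produces annotated
traces with the statistical structure the analysis assumes:

* **Baseline**: a constant tunnelling level
  `I = G_contact * V * exp(-beta * d)` (defaults `G_contact` = G0 =
  77.48 µS, `beta` = 10.9 /nm, gap `d` = 0.56 nm) plus Gaussian instrument
  noise (default sd 1 pA). The inverse of the same law is
  `gap_distance_from_baseline()`. The decay constant is a conventional
  vacuum-gap scale, configurable, not a calibrated device property.
* **Pulses**: Poisson arrivals per class; per-pulse mean amplitudes are
  Gaussian truncated at zero (15 ± 7, 14 ± 7, 15 ± 7 pA for DA, NE, 5-HT);
  dwell times are log-normal with median 10 ms (the conventional
  single-molecule dwell model; the instrument resolves pulses at 10 ms);
  within a pulse the current is piecewise constant over ~10 segments with
  mean-one log-normal jitter of log-sd equal to the class fluctuation
  scale. Log-normal (multiplicative) jitter was chosen over additive
  Gaussian jitter because it keeps every segment strictly positive — with
  additive jitter at serotonin's fluctuation scale, segments reach zero and
  one molecular residence fragments into several apparent detections — and
  because junction conductance fluctuations act multiplicatively.
* **Artifacts**: sporadic rectangular spikes with amplitudes far above the
  molecular scale (default 150 ± 30 pA, sub-millisecond), standing in for
  electrode-migration noise, which appears even in blank measurements.

`simulate_feature_set()` draws the same per-class feature distributions
directly in feature space, so classifier and denoiser tests do not depend
on detector behaviour. Its `overlap_control` argument interpolates between
fully separable classes (0: amplitude means pushed apart, spreads shrunk)
and the realistic, heavily overlapped regime (1).

### Calibration of the fluctuation scales

The fluctuation ordering 5-HT > DA > NE is established for this system,
but the class-resolved distributions are not published. The default scales
(0.05 NE, 0.25 DA, 0.55 5-HT) were fixed once so that the generator
reproduces the qualitative classification behaviour reported for the
instrument data: a cross-validated confusion matrix in which every class is
most often predicted as itself, and mixture designs of 1:2:4 (and its
rotations) whose dominant analyte wins the predicted-count plurality. With
narrower spacing, tree ensembles cannot distinguish dopamine's
within-pulse variance from norepinephrine's and the DA row of the
confusion matrix leaks into NE, contradicting both reported behaviours.
Under the calibrated models the per-signal macro F on synthetic data
(roughly 0.7–0.8 in feature space) is higher than the ~0.5 reported for
instrument data — the generator lacks the slow drifts, correlated noise
and chemical diversity of real measurements, and passing tests on it shows
algorithmic correctness, not instrument-level performance.

## Detection

`detect_pulses()` uses a rolling-median baseline (window 1000 samples,
i.e. 0.1 s at 10 kHz — long against the 10 ms dwell so pulses do not drag
the median) and a robust noise scale `sigma = 1.4826 * MAD` of the
residuals. Samples with residual above `threshold_sigma * sigma` (default
3) seed candidate pulses, which are extended outward to the baseline
return (residual ≤ 0), merged when separated by fewer than `merge_gap = 5`
samples, and kept only if they last at least `min_duration = 10` samples
(ten feature regions need ten samples) and contain at least
`min_core_samples = 3` above-threshold samples — isolated noise
exceedances otherwise inflate past `min_duration` via the extension step.
Edge-truncated pulses are discarded because their region features would be
biased. The extraction procedure for the original instrument is not
published in detail; this realization is the package's own, with every
constant exposed in `detection_params()`.

## Features

Each pulse is divided into 10 contiguous, equal-duration regions along the
time axis; when the length is not divisible by 10 the leading regions take
one extra sample each (deterministic, conservation-tested). `I_j` is the
arithmetic mean of the baseline-subtracted current in region `j`;
subtraction makes features robust to the gap-width-dependent baseline and
is switchable. The fluctuation factor is
`(max_j I_j − mean_j I_j) / mean_j I_j`, computed from the ten region
averages (the published definition is ambiguous between the region-average
mean and the raw pulse mean; these differ only through the remainder
rule). It is scale-invariant and zero iff all regions are equal. Kernel
density estimates of the fluctuation factor use a Gaussian kernel with
Scott's rule-of-thumb bandwidth; zero-variance input raises an error
rather than returning a delta spike. Current histograms bin per-signal
mean currents in fixed 1 pA bins anchored at zero.

## PU noise removal

Tissue-like samples contain signals from the analytes mixed with electrode
noise and matrix contaminants, and only *positive* examples (pure-solution
signals) plus *unlabeled* mixtures are available — the positive–unlabeled
setting. `fit_pu()` implements the classic non-traditional classifier: a
probabilistic model trained to separate positives from unlabeled rows
estimates `p(s = 1 | x)`; the label frequency `c = P(s = 1 | y = 1)` is
estimated as the mean prediction on a held-out 20% of the positives; the
corrected signal score is `s(x) = p(x) / c`, clipped to `[0, 1]`, with
decision threshold 0.5.

The base learner is a deliberately *low-capacity* gradient-boosted tree
(depth 2, 50 rounds, `min_child_weight` 20, 70% row subsampling). This is
a statistical requirement, not a performance compromise: the corrected
score is only valid if `p(x)` reflects class-conditional structure, and a
high-capacity booster memorizes its own unlabeled training rows, pushing
their probabilities toward zero precisely where the pipeline applies the
filter (the sample being cleaned is part of the unlabeled training set).
The mean corrected score over an unlabeled set estimates its positive
fraction (`estimate_positive_fraction()`), which the tests check against
known synthetic mixing fractions.

`two_round_denoise()` applies the filter twice, as done for tissue data:
round 1 uses pure-solution signals as positives and blank + sample as
unlabeled, removing electrode-migration-like noise; round 2 retrains with
the round-1 sample survivors as positives (the first round's purpose is to
furnish in-sample training data) and the round-1 removals as unlabeled,
then re-filters the survivors. Every sample row carries both round scores
and a removal-round tag, and rows are conserved across the rounds. A
structural consequence of this wiring is worth stating: because round 2's
positives are exactly the round-1 survivors, a contaminant that fully
escapes round 1 also contaminates round 2's training positives, so round 2
mainly removes the *remnant* of populations that round 1 already
identified in the unlabeled pool; in synthetic three-population
experiments the artifact and contaminant clusters are removed
predominantly in round 1. If round 1 removes fewer than 20 rows, round 2
has no viable unlabeled set and is skipped with a flag.

## Classification

`train_classifier()` fits a gradient-boosted tree ensemble
(multi-class softprob; defaults 500 trees, depth 4, learning rate 0.1 —
the original work reports no hyperparameters, so these conventional
defaults are config-exposed) on the ten region currents. `NOISE` and
`UNLABELED` rows are never classes: noise handling belongs to the PU
stage, matching the pipeline order. `cross_validate()` performs stratified
k-fold (default tenfold) validation and reports per-fold row-normalized
confusion matrices (mean ± sd) and the macro F-measure — the unweighted
mean of per-class F1. With balanced training sets macro and micro F
coincide, so the choice is benign. The chance baseline for a uniform
random predictor on balanced classes is `1/n_classes` (0.33 for three).

The end-to-end pipeline (`run_training()`) adds the fluctuation factor to
the classifier's feature columns by default. On trace-derived features the
per-region observation noise blurs the within-pulse variance signal that
separates the classes, and the raw ten currents alone yield a dopamine
row without diagonal dominance; the explicit fluctuation statistic, which
the feature stage computes anyway, restores it. `train_classifier()`
itself defaults to the bare `I1..I10` so the classifier matches the
published feature set when used directly.

## Identification and vote mathematics

`majority_vote()` assigns the sample identity by count plurality, with an
explicit tie rule (`error`, `lexicographic`, or seeded `random`).

For planning, `plurality_accuracy_exact()` computes the probability that
the true class wins the plurality when each of `n` signals is
independently predicted as (true, other, other) with probabilities
`(p1, p2, p3)`: it enumerates all `(n1, n2, n3)` compositions of `n`
(at most `(n+1)(n+2)/2` terms, evaluated in log space) and sums the
multinomial probabilities of outcomes where `n1` is maximal. Ties at the
maximum either contribute fractional credit `1/k` (default, a random
tie-break) or nothing (`tie_credit = FALSE`, strict plurality). The seeded
Monte-Carlo twin `plurality_accuracy_mc()` serves as an independent oracle,
and `signals_needed()` inverts the calculation by linear scan — the
accuracy is not strictly monotone in `n` because of parity effects, so no
bisection is used.

`estimate_mixture()` normalizes predicted label counts into composition
ratios. The raw count ratios are the canonical output: per-signal
misclassification biases them (the method identifies the dominant analyte
but is not quantitative), so no confusion-matrix unmixing is applied.
Goodman's simultaneous multinomial confidence intervals are attached as a
clearly additive extension, and `ternary_coordinates()` maps a ratio
triple affinely onto the unit equilateral triangle for ternary plots
(`autoplot()` on a mixture estimate).

## Numerical and design choices

* Current is pA end-to-end; readers convert from nA/µA only under an
  explicit metadata unit key. Time is 0-based; pulse spans are half-open
  `[start, end)` in samples.
* The canonical trace format is plain text (`# key: value` header, then
  `time_s<TAB>current_pA`) with fixed formatting, so repeated writes are
  byte-identical and fixtures stay diffable. Time is written at 0.1 ns
  resolution so the uniform-grid invariant (relative tolerance 1e-6 of the
  step) survives a round trip at 10 kHz.
* All stochastic stages take explicit integer seeds; the pipeline
  propagates one global seed and every run writes a manifest (config hash,
  seed, per-stage counts) sufficient to reproduce it. Manifests contain no
  timestamps, so identical runs are byte-identical.
* Degenerate inputs fail loudly with classed errors: non-uniform time
  grids name the first offending row, unknown labels name the closed
  vocabulary, a PU fit on identical positive/unlabeled tables raises a
  calibration error, and an empty post-filter sample yields an explicit
  empty-result status rather than a crash.

## Problem sizes in the test suite

The shipped tests run the full stack at reduced scale: 10–40 s simulated
traces at 10 kHz (one 300 s, 3-million-sample trace exercises the I/O
round trip), feature sets of 300–3000 rows, tenfold cross-validation, 20
seeded end-to-end mixture runs of 1000 signals each, and exact vote
calculations up to n = 110 (and 400 for the asymptotic check). These sizes
were chosen so the whole suite completes in a few minutes while every
statistical assertion retains adequate power.

## Known limitations

* The simulator emulates amplitude, dwell, fluctuation and artifact
  structure but not slow baseline drift, correlated (1/f) noise, junction
  rearrangement within a residence, or chemical diversity of real
  contaminants; synthetic separability is therefore optimistic, and
  passing tests demonstrate correctness of the algorithms, not expected
  performance on instrument data.
* The PU denoiser assumes noise is represented in the unlabeled pool
  (blank + sample); a contaminant class absent from both cannot be
  learned.
* Mixture ratios are qualitative. The dominant analyte is recovered
  reliably; absolute composition requires confusion-matrix unmixing and
  calibration that the measurement does not currently support.
* The tunnelling-barrier constants are conventional defaults; gap
  distances derived from them are relative, not metrological.
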