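---
title: "Verifying identity from single-lead ECG: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying identity from single-lead ECG: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgverify)
```

## The verification problem

An ECG verification system answers one question: *does this heartbeat
recording belong to the person it is claimed to belong to?* Unlike
classification, verification must handle users the model has never seen
during training. `ecgverify` does this with an ensemble Siamese design: a
single shared encoder maps any beat window to an embedding, and a learned
similarity head compares a probe embedding against the `n_ref` stored
templates of the claimed identity. Because the encoder is generic — it
learns what makes two beats *the same person*, not what makes a beat
*person 17* — new users enroll by storing embeddings, with no retraining.

The ensemble aspect is the comparison against several stored references
rather than one. A single reference beat is a noisy summary of a person;
averaging the similarity over `n_ref` references (default 3) tolerates
beat-to-beat variation in a way one-to-one matching does not.

## Pipeline

1. **R-peak detection** (`detect_r_peaks`). An energy detector in the
   Pan–Tompkins tradition: 5–15 Hz zero-phase Butterworth band-pass,
   derivative, squaring, 150 ms moving-window integration, a threshold at
   30% of the maximum integrated energy, refinement to the raw-signal
   maximum within 100 ms, and a 200 ms refractory period. The fixed
   fractional threshold is adequate for resting recordings of the quality
   the simulator emulates; it is exposed (`threshold_frac`) because
   ambulatory data with large transient artifacts would need an adaptive
   rule. The detector assumes an upright R wave.
2. **Segmentation** (`segment_record`). One window of `L` samples per
   beat, with `floor(0.4 L)` samples before the R peak — 40%/60% placement
   captures the P wave before R and the full T wave after it at typical RR
   intervals. Windows crossing a record boundary are discarded, and each
   window is z-scored (constant windows are dropped with a warning).
   Presets: `L = 256` at 500 Hz ("ecgid-like"), `L = 200` at 1000 Hz
   ("ptb-like").
3. **Spectral augmentation** (`featurize`). Channel 1 is the normalized
   window; channel 2 is the z-scored magnitude of its full-length discrete
   Fourier transform, `|X[k]|, k = 0 … L−1`. Among the candidate second
   channels (half-spectrum, real/imaginary pair, phase), the full-length
   magnitude is the only one that turns `L × 1` into exactly `L × 2` with
   a single added channel, and magnitude is the stable, shift-tolerant
   choice. The conjugate symmetry of the magnitude sequence is redundant
   information, but preserving the shape contract matters more than
   removing the redundancy: both channels enter the same convolutional
   stack.
4. **Encoder**. Eight 1D convolutional layers (kernel 3, "same" zero
   padding, ReLU) with filter counts 32, 32, 64, 64, 128, 128, 256, 256,
   each followed by width-2 stride-2 max pooling in *ceil* mode, then a
   flatten and a dense projection to a 512-dimensional embedding. Ceil
   mode is essential: it is the only pooling length rule under which an
   odd intermediate length survives halving, so `L = 200` passes the
   stack as 200 → 100 → 50 → 25 → 13 → 7 → 4 → 2 → 1 and both presets
   flatten to 256 values. The dense layer is linear; leaving the embedding
   unsaturated keeps absolute differences informative at every scale, and
   the sigmoid non-linearity lives where it is needed, in the head.
5. **Similarity head**. `score = sigmoid(w · |a − b| + b0)`: a learned
   weighting of the elementwise absolute difference (a Manhattan-style
   comparison) squashed to (0, 1). It is symmetric by construction, and
   `similarity(a, a)` is the constant `sigmoid(b0)` for every `a`.
6. **Ensemble score**. The mean of the probe's pairwise similarities to
   the `n_ref` references. The mean is invariant under reference
   permutation and keeps each reference's evidence independent; the
   alternative — similarity to the mean embedding — is available via
   `esn_config(aggregate = "similarity_to_mean")` but blurs
   multi-modal reference sets (e.g. resting and post-exercise beats of
   one person).

## Training

Training minimizes binary cross-entropy of the *bundle* score against the
match label, plus L2 weight decay, with Adam. A bundle is `n_ref`
references from one subject and one probe, labelled positive iff the probe
is the same subject; the builder (`build_bundles`) produces exactly
balanced positives and negatives regardless of how unbalanced the
per-subject segment counts are, which is the structural reason Siamese
training tolerates imbalanced source data. Attaching the loss to the
aggregated score (not to each pair separately) trains the network for the
decision it will actually make; per-pair scoring remains available through
`similarity` itself.

Hyperparameters not pinned by the architecture are surfaced in
`esn_config` with these defaults: learning rate 1e−3, L2 coefficient
1e−4, batch size 32 bundles, 50 epochs, kernel 3, embedding 512. All
randomness (initialization, shuffling) derives from the config seed; the
entire forward/backward pass is dense linear algebra, so a fixed seed
reproduces the loss trace exactly on a given platform.

Numerical choices: scores are clamped to [1e−7, 1 − 1e−7] inside the
cross-entropy; pooling ties route the gradient to the earlier sample;
the absolute-difference gradient uses `sign(a − b)`, which is zero on
exact ties — correct as a subgradient and vanishingly rare off
initialization.

## Enrollment and authentication

`enroll` encodes the first `n_ref` usable segments of a new user and
stores the embeddings in a versioned JSON repository — deterministically,
so re-enrollment from the same record reproduces the same repository, and
without ever writing raw samples (a property the test suite asserts by
scanning the serialized file). `authenticate` scores a probe against the
claimed user's templates and accepts iff the score is **greater than or
equal to** the policy threshold (default 0.7); the boundary convention is
documented rather than left to chance. An unknown claimed identity is an
error, not a reject: a reject asserts a mismatch against known templates,
which cannot be asserted for an identity that has none.

## Evaluation

`rates_at` computes FAR (impostor attempts accepted), FRR (genuine
attempts rejected) and accuracy at a threshold, with the same `≥`
convention as authentication. `eer` sweeps every distinct score, the
midpoints between adjacent scores and two sentinels; FAR is non-increasing
and FRR non-decreasing along this sweep, and the equal error rate is read
at their crossing, linearly interpolated between adjacent sweep points.
Interpolation removes the step-function ambiguity of finite score sets;
the returned threshold is the sweep point nearest the crossing by rate
gap, so rates recomputed at it agree to within one empirical step.
`crossval` runs the full train/score cycle per fold over a stratified
assignment (`kfold`: shuffled round-robin within each label class, fold
sizes within one bundle, per-fold balance within one bundle per class).
Accuracy is reported at the 0.5 classification cutoff, with the 0.7
policy variant alongside, because which operating point a published
accuracy figure uses is generally underdetermined; reporting both removes
the guesswork.

Cross-validation is at bundle level: the same underlying segment may
appear (in different bundles) on both sides of a split. That matches the
protocol the model is trained under, but it measures *bundle*
generalization, not cohort generalization; a stricter subject-disjoint
mode would require splitting subjects, which the default deliberately
does not do.

## The synthetic cohort

The simulator (`sample_subjects`, `synth_record`) gives every downstream
stage a ground truth. Each subject is five Gaussian bumps (P, Q, R, S, T)
with subject-specific amplitudes, offsets and widths; beats are placed at
RR intervals `mean_rr + N(0, rr_jitter_sd)` floored at `0.2 mean_rr` so
beats can never overlap; a baseline-wander sinusoid and white noise are
added. The time-domain sum-of-Gaussians form (in the spirit of the ECGSYN
family of generators, without the ODE) is deterministic, fast, and yields
closed-form R-peak ground truth. Defaults model a mildly noisy resting
recording: 20 ms RR jitter, 0.05 mV baseline wander at 0.25 Hz, 0.02 mV
additive noise against R amplitudes of 0.9–1.6 mV. R amplitudes are
stratified across their range with a guaranteed pairwise gap
(`0.4 × 0.7 / n_subjects` mV), which keeps any sampled cohort separable —
at zero noise a nearest-centroid classifier on raw windows exceeds 99%
accuracy, the precondition the end-to-end training checks rely on.

What the simulator does **not** emulate: U waves, pathological
morphologies (arrhythmia, ST deviation), electrode motion artifacts,
respiration-coupled amplitude modulation, or inter-session variability of
a single subject. Passing tests on synthetic cohorts therefore
demonstrate that the machinery is correct and that the model learns
person-discriminative morphology under controlled conditions; they do not
by themselves establish field performance on clinical recordings, where
noise is structured and within-subject drift is real.

## Problem sizes

The bundled end-to-end experiment (`run_synthetic_benchmark`) uses 20
subjects × 30 beats, 400 balanced bundles with `n_ref = 3`, 2-fold
stratified cross-validation and 15 training epochs per fold — sizes chosen
so a complete run finishes in minutes on a single CPU while leaving the
task non-trivial (20 morphologies, noise, jitter and baseline wander all
on). The separable sanity task (2 subjects, zero noise, 200 bundles, 8
epochs) exists to catch optimization regressions: a Siamese model that
cannot reach ~100% training accuracy there is broken, independent of any
statistical question.

## Known limitations

- The R-peak detector's fixed fractional threshold assumes the largest
  energy events are QRS complexes; a single huge artifact would suppress
  detection elsewhere in the record.
- Verification quality on real data depends on acquisition consistency
  between enrollment and probe (lead placement, posture, heart rate);
  none of that variation is modelled here.
- The WFDB reader supports storage format 16 (the format of the two
  target databases) and nothing else; it exists for interoperability, not
  as a general WFDB implementation.
- Training is CPU-bound dense linear algebra; it is sized for
  desk-scale cohorts, not for production-scale training runs.
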