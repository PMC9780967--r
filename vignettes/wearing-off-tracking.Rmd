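---
title: "Tracking the levodopa wearing-off phase from wearable gait recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking the levodopa wearing-off phase from wearable gait recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wotrack)
```

## The problem

Long-term levodopa treatment of Parkinson's disease leads to *wearing-off*:
the therapeutic benefit fades between doses, and the patient fluctuates
between an ON phase (medication effective) and an OFF phase (symptoms
re-emerging). Objective, continuous detection of these phases from wearable
sensors would let clinicians adapt dosing schedules to the individual.

`wotrack` implements a complete desk-scale version of such a tracker. The
sensing model is bilateral lower-limb surface EMG — four muscles per leg:
lateral Gastrocnemius (LG), Tibialis Anterior (TA), Biceps Femoris (BF),
Rectus Femoris (RF) — plus an optional 7-channel EEG montage (T3, C3, Cz,
C4, T4, P3, P4), all sampled at 500 Hz. Each sEMG channel is reduced to a
1-bit *trigger* (1 = contracted), gait cycles are segmented at LG onsets
(foot strike), and per-stride muscular indexes feed a binary classifier of
the medication phase, with Pre-levodopa (OFF) as the positive class.

Because no patient recordings are distributed, the package ships a
first-class synthetic session generator whose stride-level populations are
calibrated to published Pre/Post group statistics. Everything downstream of
the generator treats its output as raw data.

## The synthetic generator

`simulate_session()` draws, per leg and stride: a stride period (normal,
quantized to the 2 ms grid), per-muscle duty cycles, and the two
co-contraction times (LG-TA and RF-BF). Muscle activation windows are placed
by a fixed phase template — LG fires at foot strike; TA spans late stance
into swing, overlapping the LG tail; RF runs up to the next foot strike; BF
sits at the stance transition overlapping the RF head. The template is
parameterized so the realized overlaps and duty cycles match the configured
means in expectation.

Three numerical choices deserve explanation:

* **Co-contraction calibration.** A co-contraction cannot exceed either
  muscle's contraction time, but the configured RF-BF population (mean
  232.5 ms, SD 50 ms) is broader than the slack the BF contraction time
  (about 252 +/- 26 ms) leaves above it — with normal marginals, roughly a
  fifth of the draws would have to be capped, biasing the realized mean a few
  milliseconds low. The generator therefore draws the RF-BF co-contraction
  comonotonically with the BF duty cycle and shifts the pre-cap mean (by a
  Monte-Carlo root-solve with a fixed internal seed) so the capped draw hits
  the configured mean exactly in expectation. Realized SDs compress slightly
  (about 43 ms instead of 50 ms for RF-BF); means are treated as the binding
  contract.

* **Ground-truth mask definition.** Rendered bursts are a 20-200 Hz Gaussian
  carrier, amplitude-modulated by a trapezoid with 20 ms linear ramps, on top
  of baseline noise (`snr_db`, default 20 dB, is the carrier-to-baseline
  amplitude ratio). The ground-truth activation mask is the *half-maximum
  support* of that trapezoid: each ramp extends 10 ms beyond the mask edge.
  This makes the truth edge a well-defined instant (the half-activation
  time) that an unbiased detector can estimate.

* **Condition-independent EEG.** The published cortical (movement-related
  potential) features do not separate the ON and OFF phases. The generator
  enforces this *by construction*: the 256-sample pre-onset EEG window of
  stride *k* is generated from a random stream seeded without the condition
  label, so for matched seeds the Pre and Post cortical ground truth is
  identical. Windows are Hann-shaped bursts in the three bands (2-5 Hz,
  9-11 Hz, 12-30 Hz), centred 250 ms before the onset, over 1/f-like
  background at tens of microvolts. The two legs' onset sequences are
  generated independently and can drift together; when two pre-onset windows
  would overlap, the later one is flagged unusable (`window_usable`) and its
  cortical truth is `NA`.

Between-subject variation is a multiplicative random effect (default SD 3%)
with three factors: a temporal scale on stride time, and one
activation-width factor per antagonist pair applied to that pair's duty
cycles *and* co-contraction. Tying the pair's factors together keeps every
subject's co-contraction target compatible with the contraction times that
bound it; giving each feature an independent factor occasionally produced
subjects whose co-contraction mean was unreachable.

Default population values (means for both conditions, SDs) are the published
group statistics; where the two published sources disagree on the TA/RF
duty-cycle ordering, the table ordering is the default and
`default_params(dc_source = "text")` selects the alternative. Post-condition
duty-cycle SDs are not published and reuse the Pre values.

## Trigger generation

`binarize()` converts a raw channel to a trigger in two stages.

**Coarse detection** (C++): full-wave rectification, a trailing 50 ms
moving-RMS envelope, and a double threshold with hysteresis — ON above
`mu_b + 3 sigma_b`, OFF below `mu_b + 1.5 sigma_b` — where `mu_b, sigma_b`
are baseline statistics tracked over a sliding 2 s buffer restricted to
clearly-relaxed samples, seeded by an initial 500 ms assumed relaxed (a
documented limitation of the causal design). The statistics are those of the
*rectified samples*, not of the smoothed envelope: the envelope's own SD is
several times smaller, and thresholding at three envelope-SDs lets ordinary
baseline excursions ride through the 30 ms debounce, producing spurious
bursts. State changes must persist for the 30 ms debounce and are backdated
to the start of the run.

**Edge refinement** (default on): the trailing envelope and the asymmetric
hysteresis delay the coarse edges — the relaxation edge by most of the RMS
window — which would bias every duration-based index. Around each coarse
edge the refinement estimates the half-activation time by an *area
(centroid) estimator*: the sum of the normalized rectified amplitude between
the local baseline and the per-burst plateau over a bracketing window, which
locates the midpoint of any symmetric monotone transition without threshold
crossings. Being linear in the samples, it is unbiased against additive
noise and immune to momentary envelope dips. A small analytic shape
correction, computed from the measured burst-to-baseline ratio and an
assumed 20 ms linear activation ramp (`ramp_ms`), accounts for the
rectified-Gaussian amplitude profile being slightly convex near the baseline.
On default-SNR synthetic sessions the residual mean edge bias is below one
sample (2 ms), against per-burst random errors of roughly +/- 9 ms that
average out over a session.

All trigger invariants (binary values, debounced run lengths, exact
round-trip between trains and edge lists, invariance to uniform amplitude
scaling) are enforced by tests.

## Stride features

Strides are the half-open intervals between consecutive LG onsets of the
same leg; incomplete boundary cycles are dropped, so a session of *n*
strides per leg yields *n - 1* complete cycles. Within each stride,
contraction time is the number of contracted samples times 2 ms (totalled
over all bursts intersecting the stride, so contraction + relaxation equals
the stride time exactly); the duty cycle is the contraction share in
percent; co-contraction is the number of samples where both triggers of a
pair are 1. Left and right legs are pooled into one observation table with
the leg kept as metadata. Strides flagged as curve steps by the generator
(turn-around steps of a shuttle walk) are excluded before analysis.

## Cortical features

The EEG branch idles as a FIFO of the last 256 samples (about 512 ms). At
each LG onset the snapshot is analysed by a short-time Fourier transform
(default frame 128, hop 64, Hann window; magnitudes coherent-gain corrected
so an in-bin sinusoid of amplitude A yields peak magnitude A). The feature
per channel and band is `20 log10(max |X| / 1 uV)` with the maximum over
frames and in-band bins (inclusive edges; if a frame length leaves no bin
centre inside a band, the bin nearest the band midpoint is used), floored at
-120 dBu. A single-frame 256-point rectangular mode exists for oracle
testing. Whether "maximum spectral content" means magnitude or power is not
settled; magnitude is the default and both frame and window are exposed.

One behaviour worth knowing: because the Pre/Post cortical windows share
random numbers, *pipeline-level* paired t-tests on cortical features are
anti-conservative — the paired differences have near-zero variance, so the
tiny systematic alignment differences left by trigger-timing jitter can
reach small p-values even though the populations are identical. The
selection-pattern guarantees in the test suite are therefore stated at the
ground-truth level, where the cortical differences are exactly zero. The
default pipeline keeps the EEG branch off, which is also the deployed
configuration (the cortical features carry no wearing-off signal, and
dropping the branch saves sensor power).

## Feature selection and classifiers

Pre and Post populations are compared feature-wise by a two-sided paired
t-test at alpha 0.05, pairing the i-th usable stride of a subject's Pre
session with the i-th of its Post session (truncating to the shorter;
`pairing = "subject_mean"` collapses subjects first). No multiple-testing
correction by default, matching the per-feature reading of the published
table; a Bonferroni switch exists. All-zero differences report t = 0, p = 1;
zero-variance nonzero differences report p = 0 with a degeneracy flag.
Despite the TA duty cycle testing non-significant, the classifier feature
set defaults to all seven muscular features (the published distributions and
figures use all of them); `selected_only` restricts to significant ones.

Eight classifier configurations are supported: CART (Gini, pruned to at most
129 splits), quadratic discriminant (with a hand-written ridge fallback for
singular class covariances), linear-kernel SVM, KNN with k = 21 and
city-block distance (hand-implemented; distance ties break by lowest row
index), and four dense networks sharing a batch-norm input layer and a
1-unit sigmoid output: three/two/two/one hidden layers of 32 units (ReLU
except the third network's Tanh-then-ReLU). The scale-sensitive shallow
models are z-scored with training-set statistics; the networks rely on
batch-norm. The network engine (forward pass, backprop, Nadam and RMSProp,
batch-norm running statistics with momentum 0.99, epsilon 1e-3) is
implemented in plain R matrix algebra — at these sizes (hundreds of
parameters) this is entirely adequate and keeps the forward pass auditable
against an independent matrix-product oracle at 1e-6 relative tolerance.

Training protocol (not published; all config-exposed): binary cross-entropy,
batch size 32, up to 200 epochs, early stopping with patience 20 on the
held-out fold of a 4-fold split (train on three folds, validate on the
fourth), best-epoch weights restored. Everything is deterministic under a
fixed seed.

`complexity()` reports convention-level counts: a dense layer `in -> out`
costs `in*out` multiply-accumulates plus `out` bias accumulates, batch-norm
2 per input, activations counted separately; ROM is 4 bytes per float32
parameter. These conventions reproduce the published *ordering* of the four
networks (2429 / 1373 / 1373 / 317 parameters); matching a vendor tool's
absolute RAM/ROM/MACC numbers is out of scope.

## Evaluation

`evaluate_model()` reports the confusion matrix (positive class
Pre-levodopa/OFF), accuracy, recall, precision, F1 and specificity in
percent (displayed rounded half-up to 2 decimals), the threshold-sweep ROC
(ties swept together), trapezoidal AUC, and the operating point closest to
the ideal corner (FPR, TPR) = (0, 1). AUC is checked in tests against both
the Mann-Whitney rank normalization and an independent ROC implementation.

## The end-to-end pipeline

`run_pipeline()` reproduces the study design: five subjects (three training,
two test; mild/severe mix), one Pre and one Post session each of 8 x 150 =
1200 steps (600 strides per leg), subject-disjoint partitions throughout —
test subjects contribute nothing to training, standardization or selection.
With defaults it simulates about 108 minutes of 8-channel sEMG, binarizes
every channel, extracts roughly 7200 training and 4800 test strides, runs
the selection, trains the single-hidden-layer network (RMSProp) and
evaluates it. On one CPU core this takes about a minute; the problem sizes
in the test suite (60-1000 strides per leg) were chosen to exercise every
code path at a few percent of that cost.

On generator-default data the selection reproduces the published pattern —
stride time, both co-contractions, and the LG/BF/RF duty cycles significant,
the TA duty cycle not — and the network reaches roughly 71-80% test accuracy
across seeds. That figure is a sanity floor, not a reproduction of the
published 83.7%: the synthetic populations are Gaussian with pooled
group-level moments, so between-class separation comes only from the
published mean shifts and variance ratios, whereas real per-patient
distributions carry additional structure (asymmetry, autocorrelation,
subject-specific shapes) that the published accuracies exploit.

## What the generator does not emulate

No kinematics or IMU channels; no 24-bit ADC or fixed-point effects; no
electrode artifacts, motion artifacts or line noise; leg phases are
independent rather than antiphase-coupled; EMG bursts are single
trapezoids per muscle per stride (no doublets); EEG windows are stitched
into, not convolved with, the background. Passing tests on this data
demonstrates the correctness of the *processing*, not clinical performance.

## Known limitations

* The first 500 ms of every channel are assumed relaxed for baseline
  seeding; a recording that starts mid-contraction will mis-seed the
  baseline until the buffer turns over.
* The edge refinement assumes an approximately linear activation ramp
  (`ramp_ms`); gross mismatch degrades edge timing back toward the coarse
  detector's bias envelope.
* The TA duty-cycle null is razor-thin by construction (published means
  63.48 vs 63.49 with SD 5.44 at 3600 pairs gives |t| about 0.08), so
  roughly one seeded replicate in twenty crosses alpha purely by chance —
  exactly the type-I behaviour the test suite's calibration check verifies.
* JSON model serialization covers the dense networks only; shallow models
  live in-session.
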