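---
title: "Window size, electrode arrangement, and CNN-based emotion decoding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window size, electrode arrangement, and CNN-based emotion decoding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Decoding a listener's emotional state from the raw EEG is hard, and decoding
it for a subject the classifier has never seen is much harder: EEG is
non-stationary and differs markedly between people.  Compact convolutional
networks operating on raw multichannel windows are one of the few approaches
that generalize across subjects at all, and two of their input-design
hyperparameters are routinely chosen by convention rather than evidence: the
*window size* (how many seconds of signal form one training instance) and
the *channel arrangement* (in which order the electrode rows are stacked
into the input matrix, or how they are placed on a scalp-shaped grid).

`eegemo` is a reusable, tested pipeline for studying exactly these two
factors.  Because the kind of dataset such a study needs — many subjects,
music-length recordings, *continuous* arousal–valence annotation — has no
public equivalent, the package's first module is a synthetic-EEG generator
that plants the physiological effects the analysis is supposed to find.
Every downstream stage (filtering, windowing, channel ordering, CNN
training, cross-validated evaluation, nonparametric comparison) can then be
verified against ground truth.

## The synthetic data model

One *cohort* is `n_subjects × n_songs_per_subject` recordings, each a
12-channel matrix at 250 Hz (10–20 montage Fp1, Fp2, F3, F4, F7, F8, Fz,
C3, C4, T3, T4, Pz; Cz is the reference and therefore absent).

**Latent emotion.**  Each song carries a piecewise-constant arousal–valence
trajectory: block lengths uniform in `block_duration` (default 15–30 s),
levels uniform in $[-1,1]$ per block, joined by 1 s linear ramps.
Piecewise-constant blocks were chosen over a smooth stochastic process
because they give an unambiguous per-window majority ground truth against
which the window labeller can be tested exactly.

**Annotation.**  A simulated rater clicks every 2–3 s (uniform gaps); each
click records the latent coordinates plus Gaussian noise (`annotation_noise_sd`,
default 0.1), clipped to $[-1,1]$.  Neither the click cadence nor the noise
level of real raters is known; these defaults are stated assumptions chosen
to be plausible for a deliberate, continuous self-report task, not
estimates.

**Signal.**  Channel $c$ of a recording is

$$x_c(t) \;=\; n_c(t) \;+\; A_{\alpha,c}(t)\,\sin\phi_{10,c}(t)
\;+\; A_{\beta,c}(t)\,\sin\phi_{20,c}(t) \;+\; w_c\, s(t),$$

where $n_c$ is pink ($1/f$) noise (spectral shaping of white noise, unit
SD, scaled by `noise_sd` = 1 and the subject's noise multiplier), $s$ is a
single shared pink-noise source, and $w_c$ are spatially smooth mixing
weights (a Gaussian bump over the scalp grid).  The shared source induces
the non-trivial cross-channel correlation that makes correlation-based
orderings meaningful.  The mixing weights are a *fixed* function of the
montage geometry — volume conduction is a property of the head, not of the
song — so they carry no recording identity.

The oscillation phases $\phi_{f,c}(t) = 2\pi f t + \varphi_{0}
+ \sum_{u\le t}\varepsilon_u$ follow a slow random walk
($\varepsilon \sim N(0, 0.1^2)$ per sample, about 0.5 Hz linewidth around
the 10 Hz alpha and 20 Hz beta carriers).  This matters: with a constant
phase, every 4 s analysis window of a recording contains a *bit-identical*
tone template (window lengths are whole multiples of the tone periods), and
a CNN will happily use that template to recognize the recording — and hence
its majority label — instead of the emotion effect.  We observed exactly
this failure mode (high window-level validation accuracy, below-chance
accuracy on held-out subjects) before introducing the phase drift.  Real
cortical rhythms are narrowband with drifting phase, so the drift also
moves the simulation closer to physiology.

**Planted effects.**  Valence couples to frontal alpha asymmetry:
$A_{\alpha}$ on F3 is $a_0(1 - k_v\,v(t))$ and on F4 $a_0(1 + k_v\,v(t))$
(F7/F8 the same at half strength, all other channels $a_0$).  The sign
convention — positive valence suppresses *left* alpha — is configurable,
since the literature only motivates an asymmetry, not its direction.
Arousal couples to a broadband beta gain on all channels,
$A_{\beta,c} = b_0(1 + k_a\,a(t))$.  Defaults: $a_0 = 1$, $b_0 = 0.5$,
$k_v = 0.8$, $k_a = 0.5$.  Amplitudes that a large gain would drive
negative are floored at zero with a warning.  Per-subject lognormal
multipliers (SD 0.15 on the log scale) on gain, noise floor and effect
strength model the inter-subject variability that motivates
subject-independent evaluation.

All randomness flows from `master_seed` through deterministic child seeds
(one per subject profile, trajectory, annotation trace and recording), so a
cohort is reproducible bit for bit.

**What the generator does *not* model.**  Eye-blink and muscle artifacts,
line noise, electrode drift, genuine broadband rhythms, volume-conducted
effect leakage between the frontal channels, or any relationship between
music audio features and emotion.  Passing tests on this data show that the
pipeline recovers a known effect through the full chain — they do not show
that the same CNNs would reach any particular accuracy on real recordings.

## Preprocessing

A 4th-order Butterworth bandpass at 0.5–60 Hz, applied forward–backward
(zero phase) so left/right amplitude relations are not phase-distorted,
followed by per-channel z-scoring.  Three choices deserve a note:

* **Filter family and order** are conventional EEG practice; nothing in the
  analysis depends on the exact roll-off.
* **z-scoring scope** is per channel *within each recording*.  Scope is
  genuinely open (per channel / per recording / per subject); the
  per-recording choice is the only one that cannot leak statistics across
  cross-validation folds.
* **Population (n) rather than sample (n−1) SD**: definitionally simpler,
  numerically indistinguishable at 30 000 samples, pinned by tests.
* A 60 Hz **notch** stage exists but is off by default: mains interference
  is an acquisition-time artifact that the synthetic data does not contain.

## Windowing and labelling

Windows of length $L$ start at 0 with stride $L - O$; trailing partial
samples are discarded, so a duration-$D$ recording yields
$\lfloor (D-L)/(L-O)\rfloor + 1$ windows.  Window spans are half-open
$[t, t+L)$ so a click on a boundary is counted exactly once in the
overlapped regime.

Labels are binary per dimension: value $> 0$ maps to high arousal /
positive valence, value $\le 0$ to low / negative (the boundary value 0 is
a measure-zero case assigned deterministically to the low class).  A
window's label is the majority of the binarized clicks inside it; a tie is
resolved by the sign of the mean raw value; a window with no clicks
inherits the last click before its start, and is dropped only if no click
precedes it.  Carry-forward matters because clicks arrive every 2–3 s
while windows can be 1 s long — dropping all clickless windows would bias
the window-size comparison against short windows.

## Channel arrangements

Four arrangements of the 12 channel rows are provided:

* **identity/random** — the montage order, or a seeded uniform permutation;
  the benchmark protocol averages 20 seeded permutations.
* **MaxCBO / MinCBO** — greedy chains on $|\rho|$, the absolute Pearson
  correlation between channels: start with the extreme pair, then
  repeatedly append at either chain end the unused channel with the
  extreme $|\rho|$ to that end (max for MaxCBO, min for MinCBO).  Ties
  break lexicographically, then toward the left end, making the output
  deterministic.  The greedy construction is pinned by an exhaustive-search
  oracle (all permutations, feasible to 8 channels) in the tests rather
  than claimed optimal.
* **physical 3D** — channels placed on a 5×3 scalp-top-view grid (anterior
  row: pads, Fp1, pad, Fp2, pad; middle row F7 F3 Fz F4 F8; posterior row
  T3 C3 Pz C4 T4), stacked along time; the three unfilled cells are
  zero-padded.  Pz sits centred because the Cz reference is absent.

Correlation matrices are computed **per cross-validation fold from the
training subjects only**.  Whether the original protocol did this is
unknowable from the text; computing them on all data would leak
test-subject statistics into the input construction.

## The CNN family

Four architectures (3Conv–6Conv) in two input modes.  2D mode consumes
channels × time matrices (12 × 250·L); 3D mode consumes grid stacks
(5 × 3 × 250·L).  The layer sequences are fixed tables (convolutions of
32 then 64 filters, one max-pooling stage, dropout 0.5, a 128-unit dense
layer, a 2-unit softmax); `arch_tokens()` serializes any instantiated
model back to the table row for auditing.  Interpretation decisions:

* **Padding.**  Convolutions use zero same-padding, pooling is valid.
  Same-padding is forced by feasibility: the deepest stacks apply 2×2
  kernels after two halvings of a 12-row axis, which valid padding would
  exhaust.
* **3D kernel axis order.**  A kernel printed as 9 × 2 × 3 is read as
  (time 9, width 2, height 3), because 9 exceeds both spatial extents of
  the 5×3 grid; the 4 × 1 × 1 pooling therefore pools time only.
* **Activations.**  ReLU after every convolution and the 128-unit layer,
  softmax at the output — the standard choice where the tables are silent.
* **Initialization.**  He-scaled Gaussian for convolutions and the hidden
  dense layer, Glorot-scaled for the output layer, all driven by one seed.

Training is minibatch Adam (defaults: learning rate 1e-3, batch 64, at
most 30 epochs) on class-weighted softmax cross-entropy — weights inverse
to the training-class frequencies, so a mildly imbalanced cohort does not
push the classifier toward its majority class (under LOSO with few
subjects a majority-class learner is systematically *anti*-correlated
with the held-out subject, because that subject's class share is
anti-correlated with the remaining cohort's) — with a window-level random
validation split (fraction 0.1) drawn inside the training subjects, early
stopping on validation loss (patience 5), and restoration of the
best-validation parameters.  The validation split is window-level because
the protocol sentence it implements selects *instances* within the
training set; a subject-level split would change the LOSO semantics.
`restore_best = FALSE` switches restoration off; see the scaled profile
below for why.

### The compute backend

No deep-learning framework is assumed.  The package carries its own
single-precision backend (RcppArmadillo + BLAS): activations are stored
channels-last on a zero-haloed canvas so that every kernel offset of a
same-padding convolution is one `sgemm` call on a pointer-shifted view —
no im2col gather or col2im scatter.  Parameters and Adam moments live in
an external-pointer state, so a training step performs no double↔float
conversions.  The backward pass is verified against numeric
differentiation of an independent, naive double-precision R implementation
of the 3Conv network (agreement to ~1e-8 on gradient entries), and the
forward pass against the same oracle.

## Evaluation and statistics

* **Accuracy** is $100\,(TP+TN)/(TP+FP+TN+FN)$; **MCC** is the usual
  Matthews correlation with the convention that a zero factor in the
  denominator (e.g. a one-class predictor) yields 0, i.e. chance level.
* **LOSO CV**: one fold per subject, training on all others; arrangements
  recomputed per fold; fold window-index sets are retained on the result
  object so leakage is auditable.  **Subject-dependent** evaluation uses
  stratified 10-fold CV within one subject.
* Per-condition headline numbers are reported **two ways** — the mean of
  per-subject metrics and the metrics of pooled counts — because the
  aggregation used for the original tables is not stated.  Statistical
  comparisons always use the per-subject vectors.
* **Wilcoxon signed-rank** (paired, two-sided) drops zero differences and
  uses the exact null distribution (counting polynomial) for up to 25
  untied pairs, a tie-corrected normal approximation otherwise.
  **Kruskal–Wallis** uses the tie-corrected H with the chi-square
  approximation.  **FDR** is Benjamini–Hochberg step-up; the family size
  follows the experiment (9 window-length comparisons per model × 4 models
  = 36 per dimension; 3 arrangement comparisons per model × 4 models = 12
  per dimension) and the comparison tables carry it explicitly.

## Problem sizes and the scaled profile

The experiment drivers default to a reduced cohort (6 subjects × 4 songs ×
60 s) so that a full driver run stays desk-sized; the study-scale profile
(12 × 16 × 120 s) is one `generator_config()` away.  The package's own
end-to-end recovery check uses the reduced cohort with 4 s windows and the
3Conv 2D model, trained with batch 8 for a fixed 6 epochs without
best-epoch restoration.  Two findings motivated that training profile:

* With ~300 training windows, more optimizer steps per epoch (batch 8
  rather than 64) reach a usable representation within a handful of
  epochs; at batch 64 an epoch is only five Adam steps and the network
  never leaves its initialization regime inside the budget.
* At this scale the window-level validation loss is minimized after 2–3
  epochs and then *rises* while held-out-subject accuracy is still
  improving — validation windows share recordings with training windows,
  so the loss tracks memorization-driven overconfidence, not
  generalization.  Restoring the best-validation epoch therefore throws
  the useful training away; a fixed budget is the honest alternative at
  this scale.  At the full study scale, with an order of magnitude more
  windows, early stopping behaves conventionally and remains the default.

The recovery check compares a cohort with the planted effects
($k_v = 0.8$, $k_a = 0.5$) against an effect-free cohort under identical
protocols: valence LOSO accuracy must exceed the null run by at least ten
percentage points, and the null run's pooled MCC must sit within ±0.1 of
zero.  A spectral (Welch periodogram) oracle checks the generator
independently of the CNN: the per-block right-minus-left log alpha-power
difference must correlate with planted valence at $|r| > 0.5$.

## Numerical choices and degenerate inputs

* Constant channels z-score to all zeros; zero-variance channels are
  rejected by the correlation stage with an explicit message.
* Greedy-ordering ties and the label tie-break are fully deterministic
  (documented above), so reruns are bit-identical.
* The exact signed-rank null is computed by the standard counting
  recurrence, not enumeration, so n = 25 costs microseconds.
* Recordings shorter than one window segment to an empty list; a recording
  without an annotation trace is skipped and reported, never silently
  dropped.
* Single-precision training is deterministic for a fixed seed on a given
  platform (one BLAS thread); bit-level identity across different BLAS
  builds is not guaranteed.

## Known limitations

* The synthetic effects are stylized: two tones plus pink noise is a
  caricature of cortical dynamics, and the planted asymmetry is larger
  than what real affective EEG shows.  The pipeline's recovery margins on
  this data say nothing quantitative about real-data accuracy.
* The CNNs are trained for small fixed budgets in the scaled profile;
  conclusions about architecture rankings at that scale would be noise.
* The exhaustive-ordering oracle is limited to 8 channels; for the full
  12-channel montage the greedy orderings are only known to be valid
  chains, not optima — which mirrors how they are used.
* EDF export is not provided; recordings serialize as RDS matrices plus
  CSV annotation/manifest tables.
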