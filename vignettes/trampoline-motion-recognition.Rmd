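---
title: "Recognizing trampoline motions from wrist acceleration: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing trampoline motions from wrist acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trampohar)
```

## The problem and the data model

A smartwatch worn on the wrist reports 3-axis acceleration in G
(1 G = 9.8 m/s²) at a nominal 100 Hz. During trampoline exercise the
wearer performs one of six motions: standing (ST), walking (WL),
marching (MR), two-leg jumping (TJ), and one-leg jumping on the left
(LJ) or right (RJ) leg. The package's unit of data is a *recording* —
one continuous bout of a single motion for one (subject, set) — and
its unit of classification is a *window*: 64 consecutive samples
(0.64 s), cut with stride 64 so windows never overlap and never span a
label change. A trailing partial window is dropped rather than padded;
with stride equal to the window size, padding would fabricate almost a
full window of data. Windowing is index-based: timestamps are used
only to validate monotonicity, because a fixed-rate protocol windows
by sample count, not wall time.

All internal computation stays in G. The constant `G_TO_MS2` (9.8) is
exported for users who need SI units but is never applied internally.

## The classifier

`build_ours()` constructs the main model: a VGG-derived 1D CNN with
thirteen kernel-3, same-padding, ReLU convolutions in five blocks
(16,16 | 32,32 | 64,64,64 | 128,128,128 | 128,128,128), a size-2 max
pool after each block, global average pooling (GAP) over the final
128-channel sequence, and a softmax over the six classes.

Two representational choices deserve explanation:

* **Input layout.** The window is flattened axis-major
  (all x, then all y, then all z) into a single-channel sequence of
  length 192. This is the layout under which the convolution/pooling
  chain produces the published output lengths 192 → 96 → 48 → 24 →
  12 → 6 for this architecture family; a three-channel 64×3 layout is
  available behind `layout = "multichannel"` for comparison, since
  either is defensible for wrist HAR.
* **GAP head.** Replacing the fully-connected head with GAP means the
  classifier above the feature extractor is a single 128×6 projection
  (774 parameters). `build_vgg16_fc()` keeps the identical extractor
  and restores a flatten + two 128-unit dense layers head; it has
  strictly more parameters (423,254 vs 308,310) and serves as the
  overfitting-prone comparison point. The dense width 128 is a scale
  choice of this package (matched to the 128-channel extractor rather
  than the 4096 of image-scale VGG); nothing canonical prescribes it.

`build_simple_cnn()` is a deliberately small baseline: three
convolutions (32/64/128), one pool, and a 100-unit dense head. The
literature this baseline gestures at does not fix its internals, so
these hyperparameters are a documented reconstruction — comparisons
against it measure "a small CNN of this shape", not a specific prior
model. `build_depth_variant(k)` builds the depth-sweep family: k
convolutions in groups of three, channels starting at 16 and doubling
per group, a pool after each completed group (none after a trailing
partial group).

Kernel size 3 and ReLU activations are not printed anywhere in the
protocol this package follows; they are the VGG convention and the
natural reading of "small filters", and they are fixed here once.

## Training

`har_train_config()` defaults to the printed protocol: Adam with
learning rate 1e-3, categorical cross-entropy, minibatch 20, 100
epochs, no early stopping, no input normalization or augmentation (raw
G values enter the network). The engine (`src/cnn.cpp`) is
single-precision C++: im2col + GEMM convolutions, cached pooling
argmaxes, and an in-engine Adam loop, so one training call crosses the
R/C++ boundary once. Determinism: the seed fixes He-normal
initialization (drawn in R) and epoch shuffling (a dedicated
Mersenne-Twister in C++); the engine is single-threaded with a fixed
accumulation order, so identical seeds give bitwise-identical weights.
Ties between equal softmax outputs resolve to the lowest class index
in the fixed label order ST, WL, MR, TJ, LJ, RJ.

Training refuses label sets with fewer than two classes, or with a
declared class absent from the data — a model that can never predict a
class should fail loudly, not silently.

## Hand-crafted features

`extract_features()` computes 175 descriptors per window, 55 time
domain + 120 frequency domain, for the random-forest baseline.
Conventions, frozen by tests against straight-from-definition oracles:

* Per-axis time statistics (16 × 3): mean, mean of |·|, sample SD
  (n−1), SD of |·|, min, max, RMS, type-7 quartiles, IQR, first and
  last value, skewness and *excess* kurtosis from population moments,
  and zero-crossing rate. ZCR counts sign changes of the
  *mean-removed* signal over n−1 adjacent pairs: gravity offsets would
  otherwise pin the rate at zero for every wrist signal.
* Axis-pair correlations and |·|-correlations (6), and frame intensity
  — the mean Euclidean norm of the acceleration vector (1).
* Spectral statistics on the one-sided FFT magnitude with DC excluded,
  in four bands — all (up to Nyquist), low [0, 4.2), mid [4.2, 8.4),
  high [8.4, 12.6) Hz, closed-left/open-right so bands are disjoint.
  Per axis per band (9 × 3 × 4): maximum and its frequency, second
  maximum and its frequency, SD, quartiles, IQR; plus in-band
  magnitude correlations per axis pair (3 × 4).
* The "second maximum" is the largest bin *not adjacent* to the argmax
  bin, so spectral leakage of the main peak is not reported twice. In
  a band with no eligible bin (the low band holds only 2 bins at this
  window geometry) it is 0 by convention.
* Degenerate statistics are imputed 0: skewness/kurtosis when variance
  < 1e-12, correlations with a zero-variance argument, features of an
  empty band (with a warning). Every window therefore yields a fully
  finite vector — imputation beats NA-propagation into the forest.

Whether "intensity" should be per-axis or per-frame, and whether ZCR
should be gravity-removed, are genuinely unspecified in the HAR
feature lists this inventory follows; the choices above (per-frame
intensity, mean-removed ZCR) are this package's conventions, stated
here and asserted in tests so the 175-length contract cannot drift.

The RF baseline wraps the classic `randomForest` implementation with
300 trees and default mtry (no forest hyperparameters are part of the
published protocol).

## Evaluation

`run_loso()` implements leave-one-subject-out cross-validation: one
fold per subject, that subject entirely held out. Confusion matrices
are *predicted rows × correct columns*; precision is therefore a row
ratio and recall a column ratio, F their harmonic mean, and the
headline number is the **unweighted subject-mean accuracy** (reported
separately from pooled accuracy — they differ whenever subjects
contribute unequal window counts or difficulty). Zero-denominator
classes yield 0 with a warning rather than NaN. `merge_labels()`
collapses a partition of the labels, conserving totals; merging
mutually confused classes moves their cross-terms onto the diagonal,
so pooled accuracy cannot decrease.

`personalize()` emulates on-device adaptation with the target user's
first three sets (by set index) available for training and the
remaining sets held out:

* **None** — the fold model unchanged;
* **FT** — all weights fine-tuned on the user's sets;
* **FT-Classifier** — only the softmax projection updated, extractor
  weights bitwise frozen;
* **Mixin** — full retraining on everyone else plus the user's sets.

The first-three/rest split is deterministic; `rotate_sets = TRUE`
averages over every 3-of-5 choice when variance matters more than
speed. Fine-tuning uses 20 epochs by default — the adaptation set is
an order of magnitude smaller than the training set, and no
fine-tuning schedule is part of the published protocol.

## The synthetic cohort

No recordings for this task are publicly deposited, so
`generate_cohort()` produces a cohort with the statistical structure
the classifiers exploit — it is a documented stand-in, not a
biomechanical simulation. Per subject it draws a bounce frequency
(1.2–2.6 Hz), amplitude scale, arm-swing gain, left/right asymmetry,
sensor noise SD (0.03–0.08 G), and a wrist-tilt rotation in the x–z
plane (±15°, emulating watch orientation differences). Per class:

* ST is Gaussian noise about the (tilted) gravity vector;
* WL is a low-amplitude quasi-periodic pattern at ~0.6× the bounce
  frequency with phase drift;
* TJ is the largest-amplitude bounce carrier with two harmonics and an
  arm-swing sinusoid at half the carrier;
* MR alternates sides every bounce cycle, putting lateral energy at
  the f/2 sub-harmonic;
* LJ/RJ are fixed-sided with opposite lateral sign — generated from
  one shared random stream, so with identical seeds the right jump is
  the *exact* lateral mirror of the left jump, deliberately the most
  confusable pair. The tilt is restricted to the x–z plane precisely
  so it commutes with this mirror.

The whole cohort is a pure function of one seed; every derived stream
(profiles, recordings, initializations, shuffles, forests) uses a
31-bit mixed sub-seed, and the session RNG state is saved and restored
around every draw.

What the generator does **not** emulate: trampoline membrane dynamics,
within-bout fatigue, posture changes, sensor drift or clipping, or the
full inter-subject heterogeneity of real wrists. Consequently the
synthetic task is *easier* than the real one: leave-one-subject-out
accuracies here typically reach the mid-90s, whereas the published
human-cohort experiment this pipeline mirrors reports 78.8% for the
CNN. Passing pipeline tests on this cohort demonstrates correctness of
the machinery and above-chance cross-subject learning — not field
accuracy. The variance knobs are exposed on `subject_profile()` rather
than asserted, because real inter-subject variance is unknown.

## Problem sizes and numerical choices in the shipped tests

The test suite and `scripts/acceptance.R` run the full-size cohort
(8 subjects × 5 sets × 6 motions × 10 s = 3600 windows) but a reduced
CNN schedule of 15 epochs per fold — on this cohort the training loss
has essentially plateaued by then, and the full 100-epoch protocol
adds cost without changing any tested conclusion. The Mixin-vs-None
personalization comparison retrains the full model per subject and is
therefore evaluated on the first three subjects (A–C, a fixed choice
made up front). Small-scale unit tests use a 3-subject × 2-set × 3 s
cohort and a single-convolution depth variant.

Other numerical facts worth knowing: the engine computes in float32
(gradient checks therefore use finite-difference tolerances of ~1e-2);
He-normal initialization for ReLU layers and 1/√n for the softmax
projection; Adam β₁ = 0.9, β₂ = 0.999, ε = 1e-8; serialized sensor
logs carry 10 significant digits, so a write/read round trip is exact
to well below 1e-9 G.

## Known limitations

* The CNN engine supports exactly the layer vocabulary these
  architectures need (conv-ReLU, size-2 max pool, GAP, flatten, dense,
  softmax); it is not a general autodiff framework.
* Only same-padding odd kernels and stride-1 convolutions are
  implemented.
* Synthetic recordings are stationary within a bout; methods that
  exploit bout-level nonstationarity would be flattered unrealistically.
* The reference confusion matrices shipped in `inst/extdata/` contain
  one unreported cell (random-forest, predicted WL / correct RJ) and a
  few printed metric values that disagree with their own counts at the
  last decimal; recomputation tests cover exactly the arithmetically
  consistent entries.
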