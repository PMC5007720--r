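---
title: "Classifying individual and simultaneous movements from surface EMG"
author: "emgpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying individual and simultaneous movements from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A myoelectric prosthesis is driven by surface electromyography (EMG):
electrical activity of the residual forearm muscles, picked up by an
array of bipolar electrodes. With two electrodes and threshold logic a
user controls one joint at a time; with an electrode array and pattern
recognition, the *pattern* of activation across channels can be mapped to
one of many movement classes, including simultaneous movements of several
joints. `emgpr` implements an offline version of this pipeline: from raw
multi-channel recordings to a compared set of classifiers with paired
significance tests.

Three degrees of freedom (DoF) are modelled — hand open/close, hand
flex/extend, wrist pronation/supination — each in one of three states
(+1 agonist, −1 antagonist, 0 inactive). That yields 3³ = 27 movement
labels: 6 individual movements, 20 simultaneous combinations, and a rest
(no-movement) class. The canonical order is mixed-radix with DoF 1 least
significant and digit order (0, +1, −1), so rest is always class 0 and
the index is a bijection with the state vector.

## Windowing and features

Each movement is recorded as repetitions of a sustained contraction
(3 repetitions of 3 s by default). Analysis parameters, with defaults and
units:

| parameter | default | meaning |
|---|---|---|
| `window_length` | 0.2 s | sliding analysis window |
| `increment` | 0.05 s | window hop |
| `trim_fraction` | 0.15 | fraction removed at each end of every repetition |
| `zc_threshold`, `ssc_threshold` | 0 | amplitude deadbands for ZC/SSC |

Trimming removes the movement onset and release so only the isotonic
part of the contraction remains; boundaries are rounded down and windows
are half-open sample intervals that never span a repetition boundary.
The window count per contiguous segment of `L` samples is
`floor((L − w)/i) + 1`. Note an arithmetic consequence: at 2 kHz, 3 s
repetitions trimmed 15 % at each end give 4200 samples, hence 39 windows
per repetition and **117 per movement** — not the 121 sometimes quoted
for this protocol (121 would require trimming the concatenated recording,
which yields 123, or a slightly different rounding). The window count is
therefore always derived from the formula, never hard-coded, and the
default evaluation setting `test_per_movement = NULL` ("all windows not
used for training") accommodates either arithmetic. With the classic
72-window training draw this leaves 45 test windows per movement here.

Per channel and window, four time-domain features: mean absolute value,
waveform length, zero crossings, and slope sign changes. ZC counts sign
changes between consecutive samples whose amplitude step exceeds the
deadband; SSC counts interior samples whose slope changes sign with both
adjacent steps above the deadband. The deadbands default to 0 because
the reference protocol does not state them, but they are exposed since
acquisition software commonly uses small positive values. Eight channels
give the standard 32-dimensional feature vector.

Two linear normalizations are provided: z-score (column mean 0, sample
SD 1) and "midrange 0, range 2" (training minimum → −1, maximum → +1).
Normalization parameters are **fitted on the training partition only**
and applied unchanged to the test partition. Fitting them on all data
before splitting would leak test information into training; this choice
may differ from some historical toolboxes, which normalize the full
feature matrix up front. Zero-spread columns get scale 1 with a warning
rather than dividing by zero.

## Output codings

* **single** — one output unit per label (27 units), decoded by argmax
  with a deterministic lowest-index tie-break. Simultaneous combinations
  are first-class labels.
* **multiple** — one unit per individual movement (6 units);
  simultaneous movements activate several units. Decoding thresholds at
  0.5; if both units of one DoF are active the larger output wins; no
  active unit decodes to rest. Accuracy counts a prediction correct only
  when the entire decoded state vector matches — no partial credit,
  since the protocol does not define any.
* **per-DoF** — for linear models, which cannot emit multiple active
  outputs from one model: one 4-class model per DoF with classes agonist
  / antagonist / other movement / rest. During training, a window counts
  as "other" for a DoF when that DoF is inactive but some other DoF is
  active; windows where the DoF itself is active go to
  agonist/antagonist regardless of co-active DoFs (the protocol leaves
  this labelling unstated; this is the one consistent reading we found,
  and it is applied uniformly). Decoding maps block argmax to the DoF
  state, "other" and "rest" both to inactive, so an all-"other" decode
  is rest-equivalent.

When the evaluation machinery is asked for the *multiple* output type it
uses the per-DoF ensemble for LDA and GLM and the 6-unit logistic coding
for MLPs, mirroring how the two model families handle simultaneous
movements in practice.

## Classifiers and trainers

**LDA.** Classic pooled-covariance linear discriminants. The pooled
covariance is regularized by adding `1e-8 · trace(Σ)/p` to the diagonal —
numerically invisible on healthy data, but it keeps degenerate fixtures
(constant features, tiny classes) from producing singular systems.
Priors default to empirical class frequencies.

**GLM.** A single-layer network with bias, softmax output (multinomial
cross-entropy) for one-hot targets or logistic output (sum of Bernoulli
cross-entropies) for binary targets. Two trainers:

* *IRLS* — Fisher scoring. For logistic outputs the per-output weighted
  least squares with working weights y(1−y) is the exact Newton step.
  For softmax the full multinomial Fisher information is assembled
  (blocks Zᵀ diag(y_j(δ_jj' − y_j')) Z) and solved, which restores the
  quadratic convergence a per-output diagonal approximation lacks. Every
  step is safeguarded by halving until the total cross-entropy does not
  increase, so the training error sequence is non-increasing.
* *scg* — scaled conjugate gradient (below) on the same objective.

The objective is convex, so both trainers reach the same optimum; the
test suite asserts agreement of the final training cross-entropy to
1e-4 on a fixed weight-decayed toy problem (observed agreement is at
machine precision).

**MLP.** Feed-forward networks with logistic hidden units (one or two
hidden layers) and softmax or logistic outputs, trained full batch:

* *gradient descent* — backpropagation with learning rate 0.1 applied to
  the mean (per-sample) gradient, momentum 0. The reference protocol
  does not state the historical toolbox's hyperparameters, so these are
  declared defaults, exposed in `train_config()`, not inferred values.
* *scg* — Møller's scaled conjugate gradient: conjugate directions with
  a Levenberg–Marquardt-style scale λ adapted by the comparison
  parameter, no line search. Constants follow the canonical published
  algorithm (σ₀ = 1e-4, initial λ = 1e-6) and are configurable. The
  trace of accepted error values is non-increasing by construction and
  is stored on the fitted model.

Both trainers stop at `max_iterations` (default 200) or at the
convergence tolerances. Weight initialization is N(0, 1/fan-in), fully
reproducible from `rng_seed`. Error functions are cross-entropies matched
to the output function; weight decay (default 0) adds ½·α‖w‖².

The package's central empirical property is *optimizer quality*: at an
equal 200-iteration budget, the scg-trained MLP reaches a far lower
training cross-entropy and higher test accuracy than the same network
under gradient descent. The acceptance suite measures this over 20
seeded synthetic sessions; a typical run gives median training
cross-entropy ≈ 1e-8 (scg) vs ≈ 4.4e3 (gradient descent) and mean test
accuracy 0.99 vs 0.72.

## Evaluation protocol

`repeated_split_evaluate()` draws, per repetition, a fresh stratified
split (72 training windows per movement by default; test windows either
a fixed count or all remaining), fits the normalization on the training
rows, trains, and scores exact-match accuracy. Mean accuracy (Acc) and
its standard deviation (SD) are computed over repetitions. With a single
synthetic "subject" the SD over repetitions coincides with the pooled SD
a multi-subject study would report.

`compare_methods()` evaluates several methods under one configuration;
because the split sequence is derived only from the labels and the seed,
all methods see identical splits (common random numbers) and the
per-repetition accuracies are paired — differences reflect the method,
not the split. Paired comparisons use a two-sided Wilcoxon signed-rank
test: zero differences are dropped (all-zero gives p = 1 with a
no-evidence flag), the exact signed-rank null distribution is used for
up to 25 tie-free differences, and a normal approximation with tie and
continuity corrections otherwise. The exact path is verified against
exhaustive enumeration of all sign assignments for n ≤ 12.

`hidden_unit_sweep()` trains `nets_per_hu` (default 10) networks per
candidate hidden-layer size on shared splits. The stopping rule as
usually phrased — "the smallest number of hidden units for which no
significantly higher accuracy could be observed" — is ambiguous about
the comparison set; we read it as: find the best-scoring size, then
select the smallest size whose paired accuracies are not significantly
worse than the best's at α = 0.05. On a saturating task this selects the
smallest size in range; on a task needing capacity (e.g. XOR-like
structure) it refuses sizes below the step.

Training time is recorded per method and written to a separate timing
file; it is hardware-dependent and deliberately excluded from the
determinism contract and from all assertions.

## The synthetic generator

`generate_session()` emulates the statistical structure of a
multi-electrode recording protocol: for each of the 27 labels, each
channel carries band-limited Gaussian noise (white noise through a
zero-phase 4th-order Butterworth band-pass, 20–450 Hz by default — EMG's
usual energy band) scaled by a stationary gain

    gain = 1 + a · √snr

where `a ∈ [0, 1]` is the channel's activation for that label. The
activation matrix (6 individual movements × 8 channels) gives each
movement 2–3 dominant channels with partially overlapping supports, and
the agonist/antagonist of each DoF disjoint dominant channels, the way
antagonist muscle groups sit on different sides of the forearm.
Simultaneous movements combine their constituents' activation rows by
row-wise `max` by default — co-contraction saturates the electrode
rather than summing (a declared modelling choice; `sum` with clipping is
available). Rest is baseline noise. `snr` is the power a fully active
channel adds relative to baseline: `snr = 0` makes all 27 classes
statistically identical, `snr ≥ 10` makes them separable by
construction, and `snr = 3` is what we call moderate — class-dependent
gains clearly above noise but with confusable combinations.

What the generator does **not** emulate: motor-unit firing statistics,
signal nonstationarity within a contraction, electrode shift, sweat,
fatigue, or crosstalk changes over time. Passing tests on synthetic
sessions therefore demonstrates the *pipeline's* correctness and the
*relative* behaviour of trainers and codings, not absolute accuracies on
real recordings.

### A caveat that also applies to real data

Within one session, sliding windows overlap (200 ms window, 50 ms hop →
75 % overlap) and all windows of a movement share that movement's few
noise realizations. Random train/test splits *within* a session are
therefore not independent draws: even at `snr = 0`, where no class
information exists at all, within-session accuracy sits well above 1/27
(≈ 0.13 in our measurements), because the classifier memorizes
realization-specific amplitude quirks that the overlapping test windows
share. The chance-level check in the acceptance suite consequently
measures what the binomial derivation is actually about — generalization
— by training on one `snr = 0` session and scoring an independently
generated one, on non-overlapping windows (every 4th), whose count sets
the standard error. Observed: 0.0346 vs 1/27 ≈ 0.0370, within one
standard error. The same leakage mechanism inflates within-session
accuracies on real windowed EMG, which is worth remembering when reading
any single-session comparison, including ours.

## Numerical choices and degenerate inputs

* Decoder tie-breaks: argmax takes the lowest index; equal agonist and
  antagonist outputs above threshold resolve to the agonist.
* Zero-spread feature columns: normalization scale forced to 1 with a
  warning.
* Singular pooled covariance after regularization, non-finite training
  error, or diverging weights raise typed errors
  (`emgpr_numeric_error`) rather than propagating NaNs.
* IRLS steps are halved (down to 1e-4 of the Newton step) before
  declaring no progress; scg rejects steps whose comparison parameter is
  negative and re-scales λ, so neither trainer can increase its
  objective.
* The MAT-file v5 container is written uncompressed; the reader handles
  either byte order and both tag formats but deliberately rejects
  compressed elements with a clear message. Field names of session
  structs vary across toolbox releases, so the reader takes a
  configurable field map instead of hard-coding one layout.
* The fixture dialect stores samples as `%.17g` text, which round-trips
  IEEE doubles bit-for-bit.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own desk-scale defaults: unit tests use short
sessions (500 Hz, 2 × 1 s repetitions — 22 windows per movement) that
preserve the full 27-label structure; the evaluation regimes use
full-protocol sessions (3 × 3 s, 8 channels, 117 windows per movement)
at 1 kHz, with 20 sessions for the optimizer comparison and 10 seeds ×
4 SNR levels for the monotonicity check; the acceptance script's method
comparison runs the 2 kHz default protocol with 10 repeated splits.

## Known limitations

* Proportional (intensity) decoding and online/real-time metrics are out
  of scope; the toolkit classifies window labels offline.
* The per-DoF "other" labelling above is one consistent reading of an
  under-specified convention; alternatives (e.g. excluding simultaneous
  windows from linear training) would change per-DoF ensemble results.
* Accuracies on the bundled generator are optimistic relative to real
  EMG for the reasons given above; the toolkit's value is in paired,
  seeded comparisons, not absolute numbers.
* A replication harness for the historical 17-subject public dataset is
  supported in principle through the MAT container and field maps, but
  that dataset is external and not fetched or bundled.
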