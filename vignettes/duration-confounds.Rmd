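---
title: "Negative-class duration confounds in respiratory sound classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative-class duration confounds in respiratory sound classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automatic classifiers for adventitious respiratory sounds (ARS) —
wheezes and crackles heard over the chest — are usually evaluated
against a negative "other" class that has to be synthesized, because
databases annotate only the positive events. A common recipe generates
the negatives as randomly placed segments with *fixed* durations
(50 ms and 150 ms). Annotated wheezes and crackles, however, have
heavy-tailed, *variable* durations. When the negative class is the only
class with (two) fixed durations, event duration — visible to every
model through the excerpting convention — becomes a shortcut feature,
and reported accuracies say little about whether the model recognizes
the sounds at all.

`arsound` implements the full pipeline needed to demonstrate and
quantify this effect: corpus input/output and participant-based
splitting, negative-event generation in fixed-duration (FD) and
Burr-distributed variable-duration (VD) modes, time-frequency imaging,
a 2430-dimensional multiscale feature extractor, MRMR feature ranking,
classical classifiers and a compact CNN, and an experiment runner that
crosses the negative-class mode over training and test splits.

## Duration model

Annotated ARS durations are modelled with the Burr Type XII
distribution, density

$$f(x) = \frac{kc}{\alpha}\Big(\frac{x}{\alpha}\Big)^{c-1}
 \Big(1+\Big(\frac{x}{\alpha}\Big)^{c}\Big)^{-(k+1)}, \quad x > 0,$$

with scale $\alpha$ and shapes $c, k$. Two fitted parameter sets are
shipped: a crackle-like model ($\alpha = 0.199$ s, $c = 7.6698$,
$k = 0.3146$), truncated at 100 ms, and a wheeze-like model
($\alpha = 0.2266$ s, $c = 4.1906$, $k = 0.3029$) supported on
100 ms–2 s. Sampling uses the closed-form inverse CDF with rejection of
out-of-range draws — mirroring the "discard out-of-range durations"
recipe — in bounded-memory chunks (the crackle model's acceptance
probability under its 100 ms ceiling is about 0.0016).

## The three-experiment protocol

`runExperiment()` crosses the negative mode over splits:

* **FD/FD** — train and test negatives with fixed 50/150 ms durations;
* **FD/VD** — train on fixed, test on Burr-distributed durations;
* **VD/VD** — both splits Burr-distributed.

Each experiment runs three tasks (crackle vs wheeze vs other; crackle
vs other; wheeze vs other), repeated over training seeds, and reports
mean ± sd of accuracy, per-class F1 and Matthews correlation (one-vs-all
collapse), plus AUC for the binary tasks. Train/test splits are always
participant-disjoint; feature selection runs on the training split only.

The qualitative expectation — the package's headline check, asserted in
`tests/testthat/test-acceptance.R` — is that for the best classifier the
mean 3-class accuracy orders as FD/FD > VD/VD > FD/VD, and that a
classifier given *only* the event duration is near ceiling on FD/FD but
near the majority-class rate on VD/VD.

## Synthetic corpus: what it emulates, and what it does not

No public data ships with the package; `synthCorpus()` generates
annotated recordings with the statistical structure the analysis needs:

* **Background**: pink-ish noise, low-passed by construction of the
  4 kHz rate, amplitude-modulated by a raised-cosine breathing cycle
  (default period 4 s, a resting respiratory rate of 15 breaths/min),
  carrying a dense train of weak millisecond transients — the
  nonmusical crackling texture of normal breath sounds. Without that
  texture, "does the excerpt contain any transient?" would separate
  crackles from negatives perfectly, which no real recording permits.
* **Crackles**: explosive broadband transients (energy 60 Hz–2 kHz,
  peak in the first third of the event). Annotated crackle intervals
  longer than ~20 ms are modelled as bursts of millisecond-scale
  transients, the loudest at onset, matching how annotation windows
  span crackle clusters. Event durations follow the crackle-like Burr
  model, i.e. the same distribution as the VD crackle-like negatives —
  duration is deliberately uninformative in the VD design.
* **Wheezes**: harmonic tones with 1/m harmonic roll-off, bounded
  vibrato (~0.4% frequency deviation) and raised-cosine fades;
  fundamentals uniform in 100–1000 Hz; durations from the wheeze-like
  Burr model.
* **Disturbances**: unannotated clicks and brief tonal hums placed
  outside annotated events, at 0.7–2.5 times the event level (ambient
  noises in auscultation recordings are often louder than the ARS).
  They give the negative class confusable structure; without them the
  variable-duration task is unrealistically easy.
* **Event level**: each event is scaled to a 5 dB energy ratio over the
  local noise bed. This default was calibrated so that the
  variable-duration 3-class task lands in the published difficulty
  range for real lung-sound data (best accuracies near 0.8–0.95 rather
  than at ceiling); clearly audible events (10 dB and above) make every
  task saturate and the design comparison vacuous.

Determinism: one master seed; each recording derives its own stream by
hashing (seed, participant, recording), so corpora are reproducible as
a whole while files remain independently perturbed — the same scheme
used for per-file negative-event generation.

What the generator does **not** model: airway physiology, fine vs
coarse crackle subtypes, diagnosis labels, recording-chain coloration,
or the heterogeneous annotation styles of real databases. Passing tests
on this corpus therefore shows that the pipeline's machinery behaves as
specified and that the duration confound operates as claimed; it does
not certify clinical performance on real recordings.

## Time-frequency conventions

The canonical image of a 2.0 s excerpt at 4000 Hz uses a 32 ms
Blackman–Harris window, 75% overlap and a 512-point transform with no
edge padding, giving frames $\lfloor (L - W)/H \rfloor + 1 = 247$ and
$512/2+1 = 257$ one-sided bins; the printed 247 × 257 / 247 × 64 image
sizes pin down this framing convention, which is why the package uses
hop = window/4 and no centering. Windows shorter than the transform
length are zero-padded. Magnitude (not power) spectrograms are used;
logarithmic compression enters only inside the MFCC computation. The
mel filterbank is triangular with peak 1 (area-unnormalized), centers
uniform on the mel scale $m = 2595\log_{10}(1+f/700)$ from 0 Hz to
Nyquist. Images are min–max normalized per image to [0, 1]; a constant
image maps to zeros.

Excerpting centers shorter events in the 2 s window with symmetric
zero-padding (extra sample to the right); longer events keep their
first 2 s. Event-to-sample conversion floors the start and ceils the
end so no annotated sample is dropped. Zero-padding adds no energy,
but it *does* make event duration visible to every downstream model —
that visibility is precisely the confound under study, so the
convention is kept rather than masked.

## Features

Per analysis frame, 81 channels: 25 spectral (magnitude-weighted
moments, zero-crossing rate, normalized Shannon entropy, flatness,
Sethares roughness over spectral peaks, irregularity, four spectral
flux variants, brightness above 100/200/400/800 Hz with the 400/100
and 800/100 ratios, rolloff at 95/75/25/5% with the 5/95 and 25/75
ratios), 26 cepstral (13 MFCCs and their first differences) and 30
melodic (pitch, harmonic-comb voicing and inharmonicity, raw and
smoothed by centered moving averages of 100/250/500/1000 ms, on the
raw and 400 Hz high-passed signal). Summarizing each channel by mean,
standard deviation (sample convention), median, min and max over six
window lengths (16–512 ms, Hamming, 75% overlap) yields
$81 \times 5 \times 6 = 2430$ named features
(`{stat}_{feature}_{windowMs}`, e.g. `std_melinharm250ms_32`).

Numerical choices worth recording: every ratio with a vanishing
denominator is defined as 0 so silent frames cannot poison event
statistics; unvoiced frames carry pitch 0 and are included in the
statistics (statistics must be total functions); the pitch tracker
estimates a candidate from the frame autocorrelation (smallest
strongly-peaked lag, to avoid period multiples) and refines it on the
spectrum by quadratic peak interpolation, because at a 4 kHz rate the
autocorrelation lag grid is too coarse above ~800 Hz for percent-level
accuracy; the pitch floor is 60 Hz (the crackle band's lower edge) and
the ceiling 1600 Hz, with the floor raised per window so at least two
periods fit.

## Selection and models

MRMR ranking uses the mutual-information quotient: pick
$\arg\max I(f; y)$ first, then greedily maximize
$I(f; y) / \overline{I(f; s)}$ over the already-selected set $s$, with
equal-frequency 10-bin discretization for MI estimation (the estimator
is a free choice; equal-frequency bins are robust to the heavy-tailed
feature scales here). Subsets of 10, 100 or all features feed the
classical classifiers.

Three classical classifiers are provided behind one surface: a
regularized Gaussian LDA whose `delta` shrinks the pooled covariance
toward its average diagonal (giving the LDA regularization
hyperparameter a concrete, invertible meaning at feature counts near or
above the sample count), an RBF SVM (via e1071, features standardized
with training-split statistics), and RUSBoost — SAMME boosting of
shallow rpart trees where each round's training subset undersamples
every class to the minority count, weighted by the boosting weights.
Hyperparameters are tuned by sequential model-based optimization
(Gaussian-process surrogate on the log-scaled unit cube, expected
improvement, Latin-hypercube initial design) against accuracy on a
stratified 25% validation split, then the winner is refit on the full
training split. Everything is reproducible from (data, seed).

The CNN takes one or two image branches (spectrogram, mel spectrogram),
each a stack of 3×3 convolution + ReLU + 2×2 max-pool blocks, then a
concatenated ReLU dense layer and softmax head, trained with Adam
(default: 30 epochs, batch 16, learning rate 0.001) and early stopping
after 10 epochs without validation-loss improvement, restoring the
best checkpoint. The default stack (16/32/64 filters, dense 64) is a
reasonable compact choice, configurable because the package's claims
are behavioral, not architectural.

## Problem sizes used by the test suite

The shipped checks run on deliberately compact instances, chosen as the
smallest sizes at which each property is stable: the directional suite
uses 52 recordings of 15 s (13 participants × 4, 40% of participants
held out), about four crackles and two wheezes per recording, ten
training seeds, features at the 32 and 128 ms scales with the top-100
MRMR subset, and a scaled-down mel-branch CNN (16 mel bands over 64 ms
windows, 4/8 filters, 10 epochs). Duration-model checks use
$10^5$ sampler draws and corpus-level Kolmogorov–Smirnov tests at
$\alpha = 0.01$. The full 2430-feature extractor and the canonical
247 × 257 / 247 × 64 image geometry are exercised directly.

## Known limitations

* The synthetic corpus is a statistical emulation; absolute accuracies
  on it do not transfer to real auscultation data — only the
  *contrasts* between experimental designs are meaningful.
* The Gaussian-process search is a compact SMBO implementation, not a
  full Bayesian-optimization framework; budgets beyond a few hundred
  evaluations would warrant a dedicated optimizer.
* The CNN runs on the CPU in plain R; it is sized for compact images
  and method-level experiments, not for training at database scale.
* Only PCM-16 WAV input is supported; other containers must be
  converted upstream.
* The scalogram/wavelet image family is out of scope.
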