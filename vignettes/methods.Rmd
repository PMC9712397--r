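---
title: "Decoding attentional states from naturalistic EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attentional states from naturalistic EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegattend` implements an end-to-end pipeline for deciding, from scalp EEG,
whether a person engaged in a free-flowing social task (the motivating case
is Tibetan monastic debate) is attentive or distracted at a given moment.
The ground truth does not come from the participant: external raters watch
video of the session and mark intervals of visible attention or distraction,
the way an observer judges a conversation partner. Everything downstream —
synchronization, annotation fusion, preprocessing, spectral features,
statistics, classification — exists to connect those behavioral intervals to
the 32-channel voltage record. This vignette explains each stage's model,
its assumptions, the parameters that matter, and what the test suite does
and does not establish.

## The synthetic study

Real recordings of this kind are large and cannot ship inside a package, so
the generator (`synth_config()`, `generate_recording()`, `synth_debate()`,
`generate_dataset()`) is itself a first-class, tested component. It
simulates debates with a known hidden state so that every later stage can be
scored against truth.

Each simulated debate consists of:

* **A hidden state timeline.** Alternating labeled intervals (lognormal
  durations, median 12 s, separated by 0.5–2 s unlabeled gaps) with
  distraction the more frequent state. Less experienced debaters drift more
  (distraction probability 0.68 vs 0.55), so a dataset reproduces both the
  roughly 300:180 distraction:attention instance imbalance of a ~480-epoch
  study and an experience effect testable with a 2×2 chi-square.
* **Background activity.** Per channel, 1/f-shaped noise plus a white
  component (total sd 10 µV): the canonical shape of broadband EEG without
  committing to any biophysical source model.
* **Band-limited oscillators.** Narrowband Gaussian processes in the delta
  (0.5–4 Hz), theta (4–8), alpha (8–13) and beta (13–28) bands on every
  channel, with baseline envelopes of 6/4/4/3 µV. The attentional state
  modulates the *envelope* on designated channel groups — alpha +2 µV over
  the left frontal sites (Fp1/AF3/F3/F7), theta +3 µV over the left
  parietal sites (P3/P7/CP5), delta −4 µV over the central sites
  (Cz/C3/C4) during attention. Modulating an existing oscillator, rather
  than adding an extra source, keeps each band's identity clean for
  recovery tests.
* **Blink artifacts.** Raised-cosine transients (~0.4 s), frontal-dominant
  weights, peaked at the nominal blink time, every 2–6 s, plus the five
  deliberate, well-separated calibration blinks at the start of the session
  that the synchronization stage relies on.
* **A clock offset.** Annotations are logged on the video clock, which lags
  the EEG clock by `clock_offset_s` (default 0.25 s); the pipeline must
  estimate and undo it.
* **Noisy raters.** Each of 3 raters reproduces the true intervals with
  Gaussian boundary jitter (sd 0.3 s), misses intervals with probability
  0.1, and may split long intervals (raters differ in labelling detail).
  Raters never invert a label: their errors are omission and timing.

No published effect sizes in microvolts exist for this setting, so the
magnitudes above are free parameters of the generator. They were fixed once,
during design, such that a study of the reference size (12 debates × 600 s,
~480 fused instances) recovers the planted topography with sensitivity
≥ 0.9 after FDR correction and decodes above chance; the theta and delta effects are larger than alpha's
because a 0.125-s window of a low-frequency band carries the least
amplitude evidence, and window-level recovery needs an envelope-power
ratio near 2.5 between states (see *Limits of window-level decoding*
below). What the passing tests show is therefore that the *pipeline* is
correct and sensitive at realistic signal-to-noise; they do not show that
real debate EEG carries effects of these magnitudes. The generator also
does not emulate heartbeat or muscle artifacts, volume-conduction
correlations between channels, or non-stationary drift.

## Synchronization

The five calibration blinks appear both in the video (times supplied by the
annotation workflow) and in frontal EEG. `detect_blinks()` low-passes the
mean of Fp1/Fp2/AF3/AF4 at 5 Hz, thresholds at median + 6·MAD, enforces
0.5 s peak separation, and refines each peak with the centroid of the bump
above half height (sub-sample accuracy on broad, smoothed transients).
`estimate_offset()` takes the median of the pairwise EEG-minus-video
differences — robust to a single badly localized pair — and
`apply_offset()` shifts annotation tracks onto the EEG clock. Across 20
seeds the planted 250 ms offset is recovered within 4 ms (one sample at
256 Hz), which is tighter than the rater boundary jitter by two orders of
magnitude, so synchronization error is negligible for epoching.

## Annotation fusion

Raters mark intervals; analysis needs labeled instants backed by agreement.
`fuse_majority()` discretizes time at 100 Hz and lets each rater vote on
each 10-ms tick; a label wins a tick when at least `ceiling(n/2)` raters
mark it (2 of 3 with the default panel). Ticks where both labels reach a
majority, or neither does, produce nothing — no majority, no instance.
Maximal winning runs of at least 0.2 s (suppressing jitter slivers) become
fused events whose anchor is the run onset. Tick voting was chosen over
cross-rater event matching because it is the unambiguous reading of
"at least half of the raters" for interval data; it is permutation-invariant
and monotone in agreeing raters, and the suite re-checks every fused event
against a brute-force tick count. Whether an "instance" is an event onset
or midpoint is not determined by the rating procedure itself; the onset is
used here (configurable), with the epoch window's pre-anchor second
absorbing rater reaction time.

## Preprocessing and epoching

The chain is fixed: downsample 512 → 256 Hz (zero-phase 8th-order
anti-alias low-pass at 80 % of the new Nyquist, then decimation), band-pass
0.5–45 Hz (zero-phase 4th-order Butterworth; ≥ 40 dB at twice the upper
edge), ocular-artifact removal, then average re-referencing (idempotent;
channel mean exactly zero at every sample). Zero-phase (forward–backward)
filtering matters because epochs are anchored to behavioral times: phase
distortion would shift features relative to the anchor.

Component-based ocular cleaning by visual inspection is not reproducible in
software, so the package uses frontal-proxy regression: the 5 Hz-low-passed
mean of the frontal channels is regressed out of every channel by least
squares. A proxy channel is regressed against the *other* proxy channels
only, so its own noise never inflates its coefficient. On synthetic data
this removes ≥ 80 % of blink energy on frontal channels while leaving
out-of-band oscillations within 5 %; residual low-frequency blink energy on
non-frontal channels is a known limitation relative to a well-curated
component analysis.

Epochs are 2 s (512 samples at 256 Hz), taken as `[anchor − 1 s,
anchor + 1 s)` with `floor(t · fs)` 0-based sample mapping — fixed exactly
so the suite can assert bit-reproducible windows. The window extends 1 s
before the marked instant because the mark trails the neural event by
roughly the rater's reaction time.

## Wavelet band decomposition

Band features come from an orthonormal Daubechies discrete wavelet
transform, written in the package (no DWT package ships with the
environment, and the transform is the analytical core, so it is authored
and oracle-tested rather than wrapped). "Daubechies-8" is read as the
8-vanishing-moment family (16-tap filters), the more common reading of the
name; the 8-tap `db4` is available as an option. Filters are built by
spectral factorization of the binomial polynomial and satisfy
`sum(h) = sqrt(2)`, `sum(h²) = 1` to 1e-12; the values agree with the
PyWavelets filter bank at 1e-15.

With periodized filtering the transform is exactly orthonormal: perfect
reconstruction and Parseval energy conservation hold to 1e-10 on every
tested signal, and the fast polyphase path equals a brute-force
direct-convolution oracle on short signals. A symmetric-extension mode
(transform of the mirror-doubled signal, truncated on reconstruction — also
exactly invertible) is exposed for users who prefer to soften the circular
wrap; the periodic mode is the default and is what the tests pin down.

Five levels at 256 Hz map the dyadic components onto the canonical bands:
A5 → delta (0–4 Hz), D5 → theta (4–8), D4 → alpha (8–16), D3 → beta
(16–32), D2 → gamma (32–64, computed but excluded from analysis because
gamma is movement-contaminated in unconstrained recordings), D1 discarded.
The dyadic edges only approximate the nominal 13/28/45 Hz boundaries; that
approximation is inherent to mapping five bands onto five dyadic levels and
is accepted rather than hidden. The per-channel feature is the mean
rectified amplitude of the band-reconstructed signal over the 2-s window
(for a sine of amplitude A this is 2A/π, which the suite checks), plus a
"raw" variant on the unfiltered epoch.

## Channel statistics

`channel_ttest()` runs an independent two-sample t-test per channel on the
per-epoch band features. Pooled variance is the default (Welch is an
option): with only "independent t-test" specified, the textbook default is
the faithful choice. Two masks are reported side by side rather than
composed: a conservative `|t| ≥ 4` screen (an intentionally strict
false-positive guard) and the Benjamini–Hochberg FDR mask at q = 0.05,
whose realized p threshold is returned because masked topographies are
conventionally reported together with the applied threshold.
`fdr_bh()` is implemented from the step-up definition — the largest k with
`p_(k) ≤ (k/m)q` — because the realized threshold `p_(k)` is part of the
contract; `p.adjust(p, "BH")` serves as an independent cross-check in the
tests, and an exhaustive comparison against the brute-force definition runs
over every subset of a 12-value p-grid. Note one property that does *not*
hold, though it is tempting to assume: appending an uninformative p = 1
can demote previously significant entries, because m grows and every
per-rank threshold tightens.

Epochs are treated as independent observations. They are not — epochs from
one debate share a debater and a session — and a mixed model with
debate-level random effects would be the stricter analysis; the flat t-test
matches the granularity this kind of study actually reports and is
documented as a limitation.

`power_twosample()` computes two-sided two-sample power from the noncentral
t directly, including both rejection tails, so power → α as d → 0 (the
single-tail shortcut in common use is α/2-limited and visibly wrong at
small effects; the implementation is checked against a 10⁵-rep Monte-Carlo
oracle). For reference, at d = 0.99 the standard design gives power ≈ 0.60
at n = 11 per group and ≈ 0.92 at n = 24 — published power claims in this
area are not always mutually consistent under a single design, which is
why the operation exposes both forward and inverse modes instead of
hard-coding a quoted n.

## Decoding

Band-reconstructed epochs are cut into non-overlapping 32-sample windows
(16 per 2-s epoch), each a 32-timestep × 32-channel sequence inheriting the
epoch's label. Classical models (SVM-RBF via `e1071`; a 16-8-4 ReLU MLP;
a 50-tree, depth-16 Gini random forest via `ranger`) consume the flattened
1024-value window under stratified 10-fold cross-validation. Sequence
models (single-layer LSTM; 1-D CNN with kernel 5, batch normalization and
dropout 0.4) consume the sequences under a stratified 60:20:20
train/validation/test split with early stopping on validation accuracy.
The class imbalance is handled by random majority-class subsampling
(`balance_subsample()`; the production-scale cap is 200,000 windows, and a
cap equal to the minority count gives exactly balanced sets).

Two design decisions matter more than any architecture detail:

* **Epoch-grouped splits.** All windows of an epoch stay in one fold or
  partition. Window-level splitting puts near-identical 32-sample slices of
  the same 2-s signal on both sides of the train/test boundary and inflates
  accuracy badly; every reported number here is leakage-guarded, and the
  suite asserts the guard directly.
* **Energy-bearing input encoding.** When the class signal is carried by
  amplitude (variance) rather than mean, the loss surface of a
  small-weight-initialized recurrent network is flat: classes that differ
  only in even moments produce no first-order gradient, and training
  stalls at chance for many initializations. `train_eval_split()`
  therefore standardizes each (time, channel) feature on the training
  partition and appends the squared signal as additional input channels
  (disable with `opts$augment = FALSE`): band energy becomes a
  first-moment feature and training is reliable instead of
  initialization-dependent. Validation-selected weight restarts
  (`opts$restarts`) remain available; the study-scale evaluations use 48
  hidden units, dropout 0.2, learning rate 5e-3, up to 60 epochs, patience
  10, 2 restarts. The networks themselves are small hand-written
  implementations (no deep-learning framework exists in the supported
  environment) whose gradients are verified numerically in the suite.

Because no deep-learning framework is available, the LSTM/CNN are modest;
their role is to demonstrate the protocol (split hygiene, early stopping,
confusion reporting), not to chase benchmark accuracy.

### Limits of window-level decoding

A 32-sample window at 256 Hz spans 0.125 s. Within one band that window
carries very few independent amplitude samples — roughly `2 × bandwidth ×
0.125` degrees of freedom per channel, i.e. ~1 for theta and below 1 for
delta. An oracle that knows the planted channels and thresholds their
summed band energy tops out near 0.63–0.65 accuracy per *window* on the
default dataset; per *epoch* (averaging 16 windows) it reaches ~0.78–0.86.
Consequently the honest, leakage-guarded window-level accuracies here sit
in the 0.55–0.62 range — far above chance (one-sided binomial p ≪ 0.01 on
>4000 evaluations) but nowhere near the headline figures achievable when
windows from one epoch leak across the split. Any pipeline of this shape
reporting >0.9 window-level accuracy with 0.125-s windows should be
suspected of exactly that leakage.

The transfer experiment completes the picture: a random forest trained on
one synthetic dataset keeps its accuracy on a second dataset generated with
the same parameters (different seed), but collapses toward chance on a
dataset whose effects are planted on disjoint (right-hemisphere/occipital)
channels — the decoder learns the topography, and the topography is the
transferable content.

## Evaluation conventions and sizes

Chance-level confidence intervals use the *epoch* as the independent unit:
the 16 windows of an epoch share their signal, so window-level binomial
intervals are anti-conservative by up to a factor of 4 in width.

Problem sizes used by the test suite and the acceptance script, chosen as a
desk-scale study that preserves the reference instance counts: the default
dataset is 12 debates × 600 s at 512 Hz (~480 fused instances, ~300:180
distraction:attention); the null-effect dataset 6 debates × 300 s; transfer
variants 4 debates × 300 s each; decoding uses balanced window sets capped
at 2000 per class; synchronization accuracy is measured over 20 seeds of a
30-s calibration segment. Every random draw in the package flows through a
single integer seed (per-debate and per-stage streams are derived
deterministically from it), so identical configurations are byte-identical
across runs and machines.

## Known limitations

* The generator's channels are statistically independent given the planted
  structure; real EEG has strong volume-conduction correlations, so
  topographic specificity is easier here than in practice.
* Frontal-proxy regression under-cleans posterior blink residue compared
  with curated component analysis.
* The flat (non-hierarchical) t-test ignores debate-level nesting.
* Dyadic band edges approximate the nominal alpha/beta/gamma boundaries.
* EDF/BDF ingestion is out of scope; recordings enter through the
  documented CSV/binary dialects or the in-memory generator.
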