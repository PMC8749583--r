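---
title: "Classifying hand and finger gestures from three-channel surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hand and finger gestures from three-channel surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgkit)
```

## The problem

Surface electromyography (EMG) measures the electrical activity of
contracting muscle from skin electrodes. A myoelectric gesture-recognition
system maps short snippets of multi-channel forearm EMG to the hand or
finger gesture that produced them, which is the control primitive behind
prosthetic hands and gesture interfaces. `emgkit` implements a complete
personalized-classifier pipeline for ten classes — nine hand/finger
gestures (rock, scissors, paper, one, three, four, good, okay, finger gun)
plus the resting state — from three channels sampled at 2000 Hz, together
with a protocol-faithful synthetic-signal generator so that every stage is
testable without access to laboratory recordings.

The pipeline is deliberately time-domain only: six classical features per
channel (18 in total) feed one of four classifier families — a multilayer
perceptron (MLP), a support vector machine, a random forest, and
multinomial logistic regression — each tuned by a grid search under
stratified 10-fold cross-validation, and the families are compared with
heteroscedasticity-robust statistics.

## The recording protocol and its simulation

A recording follows a block schedule: for each gesture, four *rounds*, each
consisting of five *sets* of 5 s rest followed by 5 s of the gesture, with
10 s of rest between rounds. `build_schedule()` encodes this; at the
defaults one recording spans 9 × (4 × 50 s) of rounds plus separators.

`synthesize_recording()` emulates such a recording as follows. Each channel
carries a zero-mean stochastic process obtained by bandpass-filtering
Gaussian white noise to 20–450 Hz — the band where surface-EMG energy is
concentrated — and standardising it to unit RMS. The carrier is then
amplitude-modulated: at rest the envelope sits at the channel's resting
amplitude, and during a contraction it rises to a gesture- and
channel-specific amplitude. Muscle activation does not begin exactly at the
command: an onset latency is drawn uniformly (default 0–0.3 s) per gesture
block, and the envelope ramps linearly over 0.2 s. These two defaults are
what create transient, partially-activated windows — the windows a
threshold-based annotator can mislabel, which is the behaviour worth
testing. Finally a 60 Hz sinusoid models mains pickup.

The default gesture-amplitude table (`default_gesture_gains()`) gives each
gesture a distinct three-channel pattern with a dominant-channel gain of 5×
the resting amplitude — a strongly supra-threshold contraction. Cohorts
(`make_cohort()`) perturb all amplitudes with multiplicative log-normal
noise (`sdlog = 0.2` by default), keeping amplitudes positive while
emulating inter-subject differences in muscle bulk and electrode coupling.

What the generator does **not** model: motor-unit action potentials,
electrode geometry and crosstalk, impedance drift, movement artefacts, or
mV calibration (all gains are ratios in arbitrary units). Passing the
pipeline-recovery tests therefore shows the software recovers a known
ground truth under realistic signal structure; it does not certify
performance on laboratory data.

## Preprocessing

Two causal digital filters are applied per channel: a 4th-order Butterworth
bandpass (20–500 Hz) and a 7th-order Butterworth bandstop (59.5–60.5 Hz)
for mains rejection. A 1 Hz-wide, 7th-order notch at a 2000 Hz rate is
numerically intractable in transfer-function form (the 14th-degree
polynomial coefficients lose the poles' positions), so filters are designed
as zeros/poles/gain — analog Butterworth prototype, band transform,
bilinear transform — and evaluated as cascaded second-order sections. The
single-pass causal default matches a real-time system; `zero_phase = TRUE`
runs each filter forward and backward for offline analysis. Note that the
notch's own impulse response rings for seconds (its bandwidth is 1 Hz);
steady-state attenuation at 60 Hz exceeds 100 dB, but transients decay
slowly, which tests must account for when measuring gain.

## Segmentation and activation labelling

Recordings are cut into 250 ms windows advanced by 25 ms (90 % overlap; 500
and 50 samples). Windows are enumerated *within* each round span, so no
window straddles two rounds or the inter-round rests; on the full protocol
this yields a rest:per-gesture window ratio of ≈ 9:1, matching the class
imbalance the protocol produces.

Because activation lags the command, window labels come from a
threshold detector rather than from the command schedule:

* **Calibration.** For every round, the peak magnitude of the filtered
  signal over the first 4 s of the round's leading rest block is the
  round's baseline (the first 0.25 s are skipped so the filter startup
  transient cannot inflate it). The per-channel threshold is
  `λ × Baseline_max`, with `Baseline_max` the largest per-round baseline on
  that channel and `λ ∈ [1, λ_max]`, where `λ_max` is the ratio of the
  largest to the smallest per-round baseline.
* **Choice of λ.** The sweep's optimality rule is: the smallest grid value
  of λ for which no threshold crossing occurs anywhere in the commanded
  rest spans (excluding a 1 s guard after each gesture block, where the
  envelope is still decaying). This maximises onset sensitivity subject to
  zero rest-state false activations; if no grid value qualifies, `λ_max` is
  returned with a warning.
* **Detection.** From each gesture-command boundary, each channel is
  scanned for its first sample above threshold; the earliest crossing
  across the three channels is the *activation point*, and the signal is
  taken to be activated for 5 s from it.
* **Annotation.** A window is labelled with the round's gesture if more
  than 50 % of its samples are activated, and as rest otherwise (exactly
  half is rest).

## Features and standardisation

Six time-domain features per channel and window: RMS, variance (under the
zero-mean convention, so `VAR = RMS²` identically), mean absolute value,
slope-sign changes, zero crossings, and waveform length. ZC and SSC take an
amplitude threshold to suppress noise-induced counts; the default is 0 (the
most common convention, and the study value is not published). The SSC
comparison is strict (`>`) by default so that flat segments score zero; a
`"literal"` mode (`≥`) is available. Feature columns are ordered
channel-major. The batch extractor computes window sums via cumulative
sums, so its cost is linear in recording length; it is tested to agree
exactly with the per-window formulas.

Features are standardised to zero mean and unit variance with the
standardiser *fitted on training data only* (inside every CV fold as well),
so no test or validation information leaks into the transform. Constant
columns map to zero.

## Class balancing, splits, and classifiers

The rest class is randomly under-sampled to the median per-gesture count
before splitting (both orders are defensible; balancing first keeps the
90/10 split proportions meaningful for every class). Two evaluations are
supported: a stratified 90/10 holdout, and a round-based split (train on
rounds 1–3, test on round 4) that approximates real-time deployment on
later data.

Hyperparameters are tuned by grid search under stratified 10-fold CV; the
full grids are: MLP hidden layers {2,3,4} × width {300,600,1000} × dropout
{0.2,0.3} × batch-normalisation {on,off}; SVM kernel {linear, RBF} × C
{1,10,100,1000} × γ {1…1e-4}; random forest trees {100,500,1000} × class
weight {balanced-subsample, none}; logistic regression penalty
{L1,L2,elastic-net,none} × C {1…1e-4} × class weight × solver, with
incompatible penalty/solver cells dropped. Ties in mean CV accuracy break
by grid order. A `"fast"` profile with a handful of points exists for
testing and examples.

The MLP is implemented in the package (no installed R package offers a
multi-layer perceptron with dropout and batch normalisation): equal-width
hidden layers of linear → batch-norm → ReLU → dropout, a softmax head,
categorical cross-entropy, Adam (defaults: batch 1024, learning rate 0.001,
2000 epochs; examples use 40–100 epochs), He-normal initialisation,
inverted dropout, and exponential running statistics for inference-time
batch-norm. ReLU and the layer ordering are documented conventions. The
SVM uses libsvm's one-vs-one decision (e1071), the forest is `ranger` (the
"balanced-subsample" weight is mapped to inverse-frequency class weights),
and logistic regression uses `glmnet` (λ = 1/(C·n), fitted down a short
warm-start path) with unpenalised fits delegated to `nnet::multinom`. All
randomness — fold assignment, under-sampling, initialisation — flows from
one run-level seed, and refitting with the same seed reproduces
predictions exactly.

## Method comparison and ablation

Per-(subject, method) accuracies are compared with Levene's test
(mean-centred; median-centring available), Welch's heteroscedastic ANOVA,
Games–Howell post-hoc pairs (implemented on the studentized-range
distribution, as no installed package provides it), and pairwise
variance-ratio F-tests with Benjamini–Hochberg FDR adjustment (the FDR
variant is a documented choice). Confusion matrices are row-normalised
per subject before averaging, so diagonal entries are sensitivities and
every subject weighs equally. The feature-ablation harness evaluates the
eight combinations of the base set ZC/SSC/WL plus subsets of
{MAV, RMS, VAR}; note that at threshold 0, ZC and SSC are scale-invariant
and WL is only linearly scale-equivariant, so on synthetic data whose
class information is purely amplitude the base set is expected to do
worst.

## Numerical and design notes

* Window starts are 1-based inclusive ranges (R convention); the count
  formula `floor((L−W)/S) + 1` is unchanged.
* Filter designs are validated against an analytic frequency response;
  linearity holds to 1e-9 relative.
* The λ grid defaults to 25 evenly spaced values in `[1, λ_max]`.
* Degenerate inputs error early: all-zero baselines (threshold would not
  be positive), signals shorter than one window, classes with fewer
  members than folds, empty grids or feature combinations.
* Problem sizes in tests and the acceptance script: full-protocol
  arithmetic uses the complete 9 × 4 × 5 schedule (4.3 M samples);
  classifier-recovery runs use 9 gestures × 2–4 rounds × 1 set per round
  with fast grids and 60-epoch MLPs — full channel count, class count and
  windowing, with repetition counts chosen for desk-scale runtime.
* Known limitations: the generator's amplitude-coded classes are easier
  than real EMG (synthetic holdout accuracies approach 1.0, whereas real
  studies report ~0.94 for comparable setups); the round-split evaluation
  on synthetic data does not reproduce the train/test drift of real
  sessions (electrode shift, fatigue), so its accuracy stays close to the
  holdout value rather than dropping as reported on laboratory data.

## A worked example

```{r example, eval = FALSE}
library(emgkit)

# one synthetic subject on a reduced protocol (2 rounds, 1 set per round)
sch <- build_schedule(rounds = 2, sets_per_round = 1)
rec <- synthesize_recording(sch, subject_profile(seed = 7))

# filter -> calibrate -> detect -> window -> features
tab <- process_recording(rec)
attr(tab, "lambda")
table(tab$label)

# balance, split, tune and evaluate all four families
res <- evaluate_subject(tab, grid_profile = "fast",
                        recipe = ann_recipe(epochs = 60), seed = 5)
res$accuracies
```
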