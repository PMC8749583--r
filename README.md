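# emgkit

Personalized hand/finger gesture recognition from three-channel surface
electromyography (EMG), as a tested, reusable R pipeline. It is aimed at
researchers in myoelectric control and biomedical signal processing who
want a complete, reproducible reference implementation of the classical
time-domain approach — and a synthetic-signal generator that makes every
stage testable without laboratory recordings.

## What it implements

Ten classes — nine gestures (rock, scissors, paper, one, three, four,
good, okay, finger gun) plus rest — are decoded from 3 EMG channels
sampled at 2000 Hz:

1. **Synthetic recordings** (`build_schedule()`, `subject_profile()`,
   `synthesize_recording()`, `make_cohort()`): band-limited (20–450 Hz)
   stochastic carriers, amplitude-modulated by trapezoidal activation
   envelopes with random onset latency, plus 60 Hz mains pickup;
   log-normal inter-subject amplitude variability.
2. **Preprocessing** (`apply_filters()`): Butterworth bandpass
   (4th order, 20–500 Hz) and bandstop (7th order, 59.5–60.5 Hz), designed
   as zeros/poles/gain and evaluated as cascaded second-order sections;
   causal by default, zero-phase optional.
3. **Segmentation and labelling** (`segment_windows()`,
   `compute_baseline_max()`, `select_lambda()`, `detect_activation()`,
   `annotate_windows()`): 250 ms windows at 25 ms steps (90 % overlap);
   per-channel activation threshold `λ × Baseline_max` calibrated on the
   first 4 s of each round's rest; earliest-channel activation points;
   5 s activated runs; majority (>50 %) window labelling.
4. **Features** (`extract_features()`, `feature_table()`): RMS, VAR
   (= RMS² under the zero-mean convention), MAV, SSC, ZC, WL per channel —
   18 features per window — with train-only standardisation.
5. **Datasets and models** (`undersample_rest()`, `split_holdout()`,
   `split_by_round()`, `cv_grid_search()`, `train_final()`): rest
   under-sampling to the median gesture count; stratified 90/10 holdout
   and round-based (train rounds 1–3, test round 4) splits; grid search
   under stratified 10-fold CV for an MLP (implemented in-package: Adam,
   dropout, batch normalisation), SVM, random forest, and multinomial
   logistic regression.
6. **Statistics** (`run_method_comparison()`, `games_howell()`,
   `run_ablation()`): Levene, Welch ANOVA, Games–Howell post-hoc,
   pairwise variance F-tests with Benjamini–Hochberg correction,
   row-normalised averaged confusion matrices, and the 8-combination
   feature ablation (ZC/SSC/WL ± MAV/RMS/VAR).

## Worked example

```r
library(emgkit)

sch <- build_schedule(rounds = 2, sets_per_round = 1)  # reduced protocol
rec <- synthesize_recording(sch, subject_profile(seed = 7))
tab <- process_recording(rec)          # filter, calibrate, window, label
attr(tab, "lambda")
#> [1] 1.118793
table(tab$label)[c("rest", "rock", "paper")]
#>  rest  rock paper
#>  3657   368   372

res <- evaluate_subject(tab, grid_profile = "fast",
                        recipe = ann_recipe(epochs = 60), seed = 5)
res$accuracies
#>   method  accuracy
#> 1    ann 0.9946524
#> 2    svm 0.9973262
#> 3     rf 0.9919786
#> 4     lr 0.9973262
```

The selected threshold coefficient λ ≈ 1.12 says a rest-span excursion
slightly above the calibration baseline forced the activation threshold a
notch higher; the label table shows the ≈9:1 rest
imbalance the alternating protocol produces (here over 2 rounds × 1 set);
and the accuracies are holdout accuracies of the four tuned classifier
families on this high-signal-to-noise synthetic subject — near-perfect by
construction, since the generator encodes each gesture as a distinct,
well-separated amplitude pattern.

A thin command-line front end over the same functions is installed at
`inst/cli/emgkit.R` (`simulate`, `preprocess`, `segment`, `features`,
`evaluate` subcommands).

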