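---
title: "Decoding viewed, imagined, and regulated conditioned stimuli: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding viewed, imagined, and regulated conditioned stimuli: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`imagfear` implements the computational core of a two-visit differential fear
conditioning experiment in which two oriented Gabor patches serve as
conditioned stimuli: the CS+ co-terminates with a mild shock on half of its
viewed presentations, the CS- never does. On visit one participants view and
*imagine* the stimuli (fear transfer to imagery); on visit two they view one
stimulus while imagining the opposite one (regulation by mental imagery).
The package provides the trial design, a synthetic-data generator with known
ground truth, the skin conductance scoring pipeline, ROI-level multivariate
cross-classification (MVCC), group-level resampling inference, and the
behavioural statistics, plus drivers under `analysis/` that replicate both
experiments end to end on synthetic data.

## Trial design and exclusions

Conditioning and regulation runs have 12 trials: four view and two
imagine/regulate trials per CS. The frame of each run is fixed — trial 1 and
trial 12 are view CS-, trial 2 is a reinforced view CS+ — and trials 3..11
are a seeded uniform shuffle of the remaining multiset. Exactly two of the
four view CS+ trials per run are reinforced (trial 2, plus one seeded pick),
so the reinforcement rate is 50% by construction rather than in expectation.
Analysis exclusions remove the reinforced trials and the first and last view
CS- trial of each run, which leaves equal counts in every condition: 12 per
condition over six conditioning runs, 16 over eight regulation runs. The
regulation phase is built with eight runs; the alternative six-run reading of
the protocol is inconsistent with 16 trials per condition (two regulate
trials per CS per run times eight runs), so eight is used throughout.

On regulate trials the participant views one CS while imagining the other.
We key the condition label by the *viewed* stimulus: `regulate_CSplus` is
down-regulation (view CS+ / imagine CS-) and `regulate_CSminus` is
up-regulation. Decoding scores regulate trials against the viewed stimulus,
which also makes the amygdala "down-regulate CS+ vs up-regulate CS-"
discrimination a CS+/CS- discrimination.

## The synthetic generator

Trial patterns are generated directly at the trial-by-voxel level — the
package's decoding contract starts where a beta-series GLM would end, and no
hemodynamic model is involved. Each ROI has two prototype response vectors
with exactly equal norm (`sqrt(n_voxels)`) and a configurable correlation
(default 0, i.e. orthogonal), built by Gram-Schmidt from seeded Gaussian
draws. A trial's expected pattern is a linear mixture:

* view: `view_gain * prototype(viewed)`
* imagine: `imagery_gain * prototype(imagined)`
* regulate: `regulate_view_gain * prototype(viewed) +
  regulate_imagery_gain * prototype(imagined)`

plus i.i.d. Gaussian voxel noise. Imagery is modelled as a weaker copy of
perception (`imagery_gain <= view_gain` by default), and regulation as a
mixture in which the imagined stimulus interferes with the viewed one.
Participants differ by a Gaussian perturbation of the group prototypes
(`participant_variability_sd`); classifiers are always trained within
participant, so this heterogeneity affects group inference, not the
single-participant decoding problem.

Defaults (`view_gain = 1`, `imagery_gain = 0.5`, `regulate_view_gain = 0.7`,
`regulate_imagery_gain = 0.5`, `noise_sd = 8` at 500 voxels with K = 120
selected) were fixed a priori from a signal-detection calculation: with
orthogonal prototypes the effective decision-value gain on regulate trials
is roughly `regulate_view_gain - regulate_imagery_gain`, and the chosen
noise level puts group view accuracy in the high-60s/70s and imagine
accuracy in the low 60s. No published effect-size anchors exist at the voxel
level, so these defaults are calibrated only to reproduce the *qualitative*
orderings (view > imagine > chance; regulate < view; amygdala transfer
present but weaker), never printed accuracies. The generator also does not
emulate spatial autocorrelation, physiological noise, or scanner drift in
the patterns — passing tests therefore validate the pipeline's logic and
calibration, not its behaviour on real fMRI data.

The SCR generator emits 1 kHz traces: baseline + linear drift + one
event-locked kernel per trial + Gaussian noise. The kernel is a difference
of two exponentials, zero before a 1 s latency, with 0.75 s rise and 2 s
decay constants, peak-normalised so a condition's amplitude parameter (in
microsiemens) is the kernel's peak height; the analytic peak time is
`latency + rise*decay/(decay-rise) * log(decay/rise)`. Electrodermal
responsiveness varies strongly across people, so each simulated trace draws
a log-normal participant gain (`participant_amp_sd = 0.4`) and per-condition
log-normal jitter (`condition_jitter_sd = 0.25`); both are multiplicative so
zero amplitudes stay exactly zero. Ratings are integer 1-7 responses:
condition mean + participant shift + noise, rounded and clipped.

All randomness flows from one master seed through `derive_seed()`, a
31-bit tag-folding scheme, so any participant/phase/purpose stream can be
replayed in isolation and identical configurations give byte-identical
result bundles.

## SCR scoring

Preprocessing per run: least-squares linear detrend, a 50-sample median
filter, then 10:1 decimation to 100 Hz — in that order. Three conventions
are worth stating because the procedure alone does not fix them:

* The detrend removes only the fitted slope and retains the run mean, so
  values stay interpretable in microsiemens; the later baseline correction
  removes offsets anyway, so scored peaks are identical either way.
* The 50-sample window is even; it covers samples `[i-25, i+24]` with
  half-sample reflection at the edges (no phase shift, no truncation), and
  the median of an even window is the mean of its two central order
  statistics.
* Downsampling is by decimation (every 10th sample), not block averaging;
  the median filter has already suppressed the high-frequency MRI noise.

Epochs cover -1.0 to +8.0 s around CS onset at 100 Hz with half-open sample
windows: baseline samples are offsets -100..-1, the trough window 0..99
(0-0.99 s), the peak window 100..800 (1-8 s). Each epoch subtracts its
baseline mean; the trial score is the peak-window maximum minus the
trough-window minimum, and any score below 0.02 uS (including negative
ones) is zeroed, so scores are non-negative. A trial whose window does not
fit inside its run is flagged missing and reduces the denominator of its
condition mean; a condition with no scoreable trials flags the participant
for exclusion from that contrast. The whole pipeline is checked against a
naive-loop oracle to 1e-9 on random traces.

## Decoding

Feature selection keeps the K voxels with the largest *positive* univariate
CS+ minus CS- training difference (K = 120 for visual ROIs, 300 for the
amygdala), ties broken by ascending voxel index. If fewer than K voxels
score positive, the top K by signed score are kept (with a warning) so K is
constant. The classifier is a linear support vector machine
(C-classification); the cost hyperparameter is auto-scaled to the data as
`C = 1 / mean(||x||_2)` over the selected training vectors, a formalisation
of "automatic scaling according to the norm of the data". No trial
normalisation is applied by default; whether patterns should be z-scored is
genuinely open and is left as an explicit argument rather than a hidden
default. Training uses only designated training-phase trials; tests verify
that corrupting the test set cannot change the selection or the weights.

The SVM solver is libsvm via e1071. Because permutation inference retrains
the model thousands of times on small problems, the package calls e1071's
compiled training routine directly through a thin internal wrapper and
predicts from the explicit weight vector; tests assert prediction-level
equivalence with `e1071::svm` on random datasets.

Reinforced trials never enter any decoding set, and every scored subset
must be class-balanced (chance is exactly 50%); violations are integrity
errors, not warnings.

## Group inference

Within participant, iteration *j* permutes the training labels (a
permutation of the label vector, so class counts are preserved), re-runs
feature selection *and* training — selection is part of the pipeline under
test, and leaving it outside the loop would leak label information into the
null — and evaluates on the fixed test subsets. The permutation sequence is
a deterministic function of `(seed, n_perm, n training trials)` only, so
nulls for different conditions of the same participant are seed-paired by
construction. The protocol text is ambiguous about whether training or test
labels are permuted; permuting training labels is the procedure that
actually generates a null for a train/test transfer, and the seed is used,
as described, to synchronise sequences across conditions.

The group null is a bootstrap: each of `n_boot` iterations draws one value
per participant (with replacement) and records the mean. P-values are
empirical with the add-one rule, `p = (1 + #{null >= obs}) / (1 + n_boot)`
one-tailed, doubled-and-capped for two-tailed tests — never zero, and
consistent with p-values at 1/10,000 resolution at full study scale.
Between-condition tests build per-iteration differences from the
seed-paired nulls, bootstrap-aggregate them, and default to two tails.
Accuracy-vs-chance tests are one-tailed (greater). No multiple-ROI
correction is applied, matching the uncorrected per-ROI reporting
convention; a Holm correction can be applied downstream if wanted. The
amygdala regulate-trial analysis is interpreted only when its view-trial
positive control is significant (`p < alpha`, strict), in both the forward
(train day-one conditioning, test regulation) and reverse direction.

At full study scale both resampling layers use 10,000 iterations; the test suite
and the calibration analyses use 300-1,000 permutations and 600-2,000
bootstrap iterations through the same code paths. Type-I calibration is
checked with 200 signal-free replicates of a 13-participant group (30
training trials, 12 balanced test trials, 60 voxels with K = 20 per
replicate): the rejection rate at alpha = 0.05 must fall inside the exact
binomial 95% interval. These sizes are the package's choice of a
desk-scale design with enough replicates for a sharp binomial check.

## Behavioural statistics

The 2x2 within-participant ANOVA (CS-Type x Instruction) is fitted with
`stats::aov` using participant error strata; with two-level factors every
effect has 1 numerator and n-1 denominator degrees of freedom and
sphericity is moot. Effect size is *generalized* eta-squared: the effect
sum of squares divided by itself plus *all* subject-related error sums of
squares (subject, subject x A, subject x B, subject x A x B), following the
Olejnik-Algina/Bakeman convention — not partial eta-squared. An independent
spreadsheet-style sums-of-squares oracle in the tests reproduces F and
eta-G-squared to 1e-8.

Cohen's d for paired contrasts is the mean difference divided by the SD of
the differences; the reporting convention in this literature is ambiguous,
so the pooled-SD variant is available behind `d_method = "pooled_sd"`.
One-tailed t-tests implement the directional CS+ > CS- hypothesis used for
visit-one SCR contrasts; visit-two contrasts are two-tailed (the direction
of regulation effects is itself the question). Zero-variance difference
vectors with a nonzero mean are reported at the machine bound with a
`degenerate` flag rather than as an error.

## Degenerate inputs and numerical conventions

* Empty schedules produce empty accounting tables; unequal per-condition
  counts are integrity errors (a malformed schedule, not a statistic).
* `prototype_cor` must lie in [-1, 1); 1 would make the classes identical.
* An all-constant ANOVA table returns F = 0, p = 1, eta = 0 (guarded by a
  scale-relative tolerance rather than exact comparison with 0).
* Exactly-at-threshold SCR scores (0.02 uS) are kept; the zeroing rule is
  strict "less than".
* The positive-control gate is strict: `p` exactly at alpha does not open it.

## Known limitations

* Synthetic patterns are spatially white; real multivoxel data have
  correlated noise, and accuracies here should not be read as forecasts of
  real-data performance.
* The SCR generator uses a fixed canonical kernel; it does not model
  habituation within runs or overlapping responses beyond linear summation.
* Participant attrition and equipment failures (which shaped the real
  sample sizes per measure) are not emulated; the generator always yields
  complete data, and missing-data handling is exercised through targeted
  unit tests instead.
* The real-data path (NIfTI beta series + ROI masks) is out of scope here;
  the analysis starts at trial-by-voxel matrices.
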