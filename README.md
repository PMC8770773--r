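# imagfear

Analysis pipeline for two-visit differential fear conditioning experiments
in which conditioned stimuli are **viewed, imagined, or regulated by mental
imagery**, with decoding of the stimulus identity from region-of-interest
(ROI) multivoxel patterns.

The scientific question the pipeline serves: when a visual CS+ (paired with
shock on 50% of viewed presentations) is merely *imagined*, does early
visual cortex carry a decodable stimulus representation — and can imagining
the opposite stimulus while viewing a CS *disrupt* that representation and
with it the conditioned fear response (self-report, skin conductance,
amygdala pattern)? The package is aimed at cognitive/affective
neuroscientists who want the full computational chain — design, scoring,
decoding, inference — as tested, reusable code, exercised end to end on
synthetic data with known ground truth.

## What it implements

* **Trial design** (`build_phase_schedule`, `apply_exclusions`,
  `count_analyzable`): classifier-training, pre-conditioning, conditioning
  and regulation schedules with the fixed run frame (first/last trial view
  CS-, second trial reinforced view CS+, trials 3..11 seeded shuffle),
  exact 50% reinforcement of viewed CS+ trials, and the inclusion rules
  that leave 12 analysable trials per condition over six conditioning runs
  and 16 over eight regulation runs. Schedules serialize to BIDS-style
  events TSV.
* **Synthetic data** (`pattern_truth`, `simulate_roi_dataset`,
  `simulate_scr`, `simulate_ratings`): trial-by-voxel patterns under a
  linear mixing model (view/imagine/regulate gains on equal-norm stimulus
  prototypes), 1 kHz skin conductance traces with a difference-of-
  exponentials event kernel, and 1-7 Likert ratings — all deterministic
  under a single master seed via `derive_seed()`.
* **SCR scoring** (`scr_preprocess`, `scr_epochs`, `score_trial_peaks`,
  `scr_condition_means`): per-run linear detrend, 50-sample median filter,
  decimation to 100 Hz, -1..+8 s epochs baseline-corrected on the second
  before CS onset, and trough-to-peak scoring
  `max[1, 8 s] - min[0, 0.99 s]` with responses `< 0.02 uS` zeroed.
* **Decoding** (`select_features`, `train_classifier`, `cross_classify`):
  top-K voxels by positive univariate CS+ minus CS- training difference
  (K = 120 visual, 300 amygdala), linear SVM with cost auto-scaled as
  `C = 1/mean(||x||_2)`, cross-classification from the training phase onto
  view / imagine / regulate test trials (regulate trials scored against the
  viewed stimulus). Chance is exactly 50% on the enforced class-balanced
  subsets.
* **Group inference** (`participant_null`, `group_null`, `empirical_p`,
  `condition_difference_test`): within-participant permutation nulls
  (training labels permuted; feature selection re-run inside every
  iteration; 10,000 iterations at full study scale), group bootstrap of one
  draw per participant (10,000 iterations), add-one empirical p-values,
  and seed-paired between-condition difference tests. The amygdala
  regulate-trial decoding is gated on its view-trial positive control
  (`amygdala_gate`).
* **Behavioural statistics** (`rm_anova_2x2`, `paired_t`, `one_sample_t`):
  2x2 within-participant ANOVA with generalized eta-squared
  (eta_G^2 = SS_effect / (SS_effect + all subject-related SS)), and paired /
  one-sample t-tests with Cohen's d (mean difference over SD of
  differences).
* **Orchestration** (`experiment_config`, `run_experiment1`,
  `run_experiment2`, `write_report`): full synthetic replications of both
  visits (13 and 12 participants), writing tidy TSV tables and a JSON
  summary, byte-identical under a fixed configuration and seed.

## Worked example

Decode imagined stimuli for one synthetic participant and test the
accuracy against a permutation/bootstrap null:

```r
library(imagfear)

schedule <- apply_exclusions(build_phase_schedule("conditioning", 6, seed = 42))
count_analyzable(schedule)
#>         condition n_included
#> 1 imagine_CSminus         12
#> 2  imagine_CSplus         12
#> 3    view_CSminus         12
#> 4     view_CSplus         12

truth <- participant_pattern_truth(pattern_truth(500, seed = 42), "p01", 42)
ct    <- apply_exclusions(build_phase_schedule("classifier_training", 6, seed = 42))
train <- simulate_roi_dataset(ct, truth, seed = 1, roi_name = "V1")
test  <- simulate_roi_dataset(schedule, truth, seed = 2, roi_name = "V1")

clf <- train_classifier(train, select_features(train, K = 120))
cross_classify(clf, test)
#>   condition n_correct n_trials accuracy
#> 1      view        22       24 91.66667
#> 2   imagine        19       24 79.16667

pn  <- participant_null(train, test, K = 120, n_perm = 500, seed = 3)
group_accuracy_test(79.16667, list(pn), n_boot = 1000, seed = 4,
                    condition = "imagine")
#> <permutation_test> observed = 79.17, p = 0.001998 (greater, n = 1000)
```

Reading the numbers: of the 24 included conditioning-phase imagine trials,
19 were classified correctly by an SVM that never saw imagery data
(79.2%, against a 50% chance level); the empirical p-value says fewer than
1 in 500 permutation/bootstrap null draws reached that group accuracy, so
the imagined stimulus leaves a decodable trace in this (synthetic) ROI.
At this single-participant high-SNR setting accuracy is higher than a
realistic group mean; the default generator is calibrated to qualitative
orderings, not printed accuracies.

The numbered scripts under `analysis/` run the full studies:
`01_trial_schedules.R` (design accounting), `02_simulate_participant.R`
(one participant's raw artefacts), `03_experiment1.R` and
`04_experiment2.R` (complete group replications of both visits, written to
`results/`), `05_calibration.R` (chance and type-I calibration of the
inference chain).

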