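# Small dataset constructors used across test files.

# signal-free classifier-training + conditioning pair for one participant
make_noise_pair <- function(seed, n_voxels = 60, ct_runs = 3, cond_runs = 3,
                            noise_sd = 1) {
  ct <- apply_exclusions(build_phase_schedule("classifier_training", ct_runs,
                                              derive_seed(seed, "ct")))
  cond <- apply_exclusions(build_phase_schedule("conditioning", cond_runs,
                                                derive_seed(seed, "cond")))
  tr <- pattern_truth(n_voxels, view_gain = 0, imagery_gain = 0,
                      regulate_view_gain = 0, regulate_imagery_gain = 0,
                      noise_sd = noise_sd, participant_variability_sd = 0,
                      seed = derive_seed(seed, "truth"))
  list(train = simulate_roi_dataset(ct, tr, derive_seed(seed, "train")),
       test = simulate_roi_dataset(cond, tr, derive_seed(seed, "test")))
}

# signal-bearing pair with configurable gains
make_signal_pair <- function(seed, n_voxels = 120, view_gain = 1,
                             imagery_gain = 0.5, noise_sd = 8,
                             ct_runs = 6, cond_runs = 6) {
  ct <- apply_exclusions(build_phase_schedule("classifier_training", ct_runs,
                                              derive_seed(seed, "ct")))
  cond <- apply_exclusions(build_phase_schedule("conditioning", cond_runs,
                                                derive_seed(seed, "cond")))
  g <- pattern_truth(n_voxels, view_gain = view_gain,
                     imagery_gain = imagery_gain, noise_sd = noise_sd,
                     seed = derive_seed(seed, "truth"))
  tr <- participant_pattern_truth(g, "p01", derive_seed(seed, "pt"))
  list(train = simulate_roi_dataset(ct, tr, derive_seed(seed, "train")),
       test = simulate_roi_dataset(cond, tr, derive_seed(seed, "test")))
}

# hand-rolled separable two-voxel dataset wrapped as an roi_dataset
make_toy_dataset <- function(X, labels, instruction = "view") {
  n <- nrow(X)
  trials <- data.frame(
    phase = "classifier_training", run_index = 1L, position_in_run = seq_len(n),
    viewed_stimulus = if (instruction == "imagine") "none" else labels,
    imagined_stimulus = if (instruction == "imagine") labels else "none",
    instruction = instruction, reinforced = FALSE, included = TRUE,
    stringsAsFactors = FALSE
  )
  structure(list(X = X, trials = trials, roi_name = "toy",
                 participant_id = "p01", phase = "classifier_training"),
            class = "roi_dataset")
}

scaled_config <- function(seed = 11, n_participants = 4, n_perm = 40,
                          n_boot = 100) {
  experiment_config(
    n_participants_exp1 = n_participants,
    n_participants_exp2 = max(2, n_participants - 1),
    runs = list(classifier_training = 2, preconditioning = 2,
                conditioning = 2, regulation = 2),
    rois = list(V1 = list(n_voxels = 80, K = 40, signal_scale = 1)),
    n_perm = n_perm, n_boot = n_boot, seed = seed
  )
}

# build a minimal scr_trace by hand (one run)
raw_trace <- function(samples, onsets, trials = NULL, fs = 1000) {
  n <- length(onsets)
  if (is.null(trials)) {
    trials <- data.frame(
      phase = "conditioning", run_index = 1L, position_in_run = seq_len(n),
      viewed_stimulus = "CSminus", imagined_stimulus = "none",
      instruction = "view", reinforced = FALSE, included = TRUE,
      stringsAsFactors = FALSE
    )
  }
  structure(list(fs = fs, samples = list(samples), onset_idx = list(onsets),
                 trials = trials, run_index = 1L),
            class = "scr_trace")
}
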