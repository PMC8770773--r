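#' @title Synthetic participants with known ground truth
#' @description
#' The generator produces, per participant, trial-by-voxel response matrices
#' for each phase (standing in for trial-wise GLM beta estimates), 1 kHz skin
#' conductance traces with event-locked responses, and 7-point Likert
#' ratings. Condition-dependent multivariate signal follows a simple linear
#' mixing model: view trials carry `view_gain` times the prototype of the
#' viewed stimulus, imagine trials an attenuated `imagery_gain` copy of the
#' imagined prototype, and regulate trials a mixture of both the viewed and
#' the imagined prototype. All parameters are recoverable ground truth.
#' @name synthgen
NULL

#' Ground truth for multivoxel pattern generation
#'
#' The two stimulus prototypes are constructed with exactly equal norm
#' (`sqrt(n_voxels)`, i.e. unit root-mean-square response per voxel) and an
#' exact inner-product correlation `prototype_cor` by Gram-Schmidt
#' construction from seeded Gaussian vectors.
#'
#' @param n_voxels Number of voxels (>= 2).
#' @param view_gain Multiplier on the viewed prototype for view trials.
#' @param imagery_gain Multiplier on the imagined prototype for imagine
#'   trials; imagery is modelled as a weaker copy of perception, so by default
#'   `imagery_gain <= view_gain`.
#' @param regulate_view_gain,regulate_imagery_gain Mixing weights for the
#'   viewed and imagined prototypes on regulate trials.
#' @param prototype_cor Correlation between the two prototypes, in `[-1, 1)`.
#' @param noise_sd Per-voxel Gaussian trial noise (signal units).
#' @param participant_variability_sd SD of per-voxel Gaussian perturbation
#'   added to the group prototypes for each participant.
#' @param seed Integer seed.
#' @return An object of class `pattern_truth`.
#' @examples
#' tr <- pattern_truth(50, seed = 1)
#' crossprod(tr$prototype_plus, tr$prototype_minus) # ~0: orthogonal default
#' @export
pattern_truth <- function(n_voxels, view_gain = 1, imagery_gain = 0.5,
                          regulate_view_gain = 0.7, regulate_imagery_gain = 0.5,
                          prototype_cor = 0, noise_sd = 8,
                          participant_variability_sd = 0.3, seed = 1) {
  stopifnot(n_voxels >= 2)
  if (prototype_cor < -1 || prototype_cor >= 1) {
    stop_config("prototype_cor must lie in [-1, 1), got ", prototype_cor)
  }
  stopifnot(view_gain >= 0, imagery_gain >= 0,
            regulate_view_gain >= 0, regulate_imagery_gain >= 0, noise_sd > 0,
            participant_variability_sd >= 0)
  protos <- with_seed(derive_seed(seed, "prototypes"), {
    z1 <- stats::rnorm(n_voxels)
    z2 <- stats::rnorm(n_voxels)
    u1 <- z1 / sqrt(sum(z1^2))
    z2 <- z2 - sum(z2 * u1) * u1
    u2 <- z2 / sqrt(sum(z2^2))
    scale <- sqrt(n_voxels)
    list(plus = scale * u1,
         minus = scale * (prototype_cor * u1 + sqrt(1 - prototype_cor^2) * u2))
  })
  structure(
    list(n_voxels = as.integer(n_voxels),
         prototype_plus = protos$plus, prototype_minus = protos$minus,
         view_gain = view_gain, imagery_gain = imagery_gain,
         regulate_view_gain = regulate_view_gain,
         regulate_imagery_gain = regulate_imagery_gain,
         prototype_cor = prototype_cor, noise_sd = noise_sd,
         participant_variability_sd = participant_variability_sd,
         seed = as.integer(seed)),
    class = "pattern_truth"
  )
}

#' Participant-specific pattern truth
#'
#' Classifiers are always trained within participant; per-participant
#' prototypes are the group prototypes plus seeded Gaussian perturbation of SD
#' `participant_variability_sd`.
#'
#' @param truth A group-level `pattern_truth`.
#' @param participant_id Character or integer identifier.
#' @param seed Integer seed (typically derived from the master seed).
#' @return A `pattern_truth` with perturbed prototypes.
#' @export
participant_pattern_truth <- function(truth, participant_id, seed) {
  stopifnot(inherits(truth, "pattern_truth"))
  s <- derive_seed(seed, "participant", as.character(participant_id), "prototypes")
  pert <- with_seed(s, list(
    plus = stats::rnorm(truth$n_voxels, 0, truth$participant_variability_sd),
    minus = stats::rnorm(truth$n_voxels, 0, truth$participant_variability_sd)
  ))
  truth$prototype_plus <- truth$prototype_plus + pert$plus
  truth$prototype_minus <- truth$prototype_minus + pert$minus
  truth
}

prototype_of <- function(truth, stimulus) {
  switch(stimulus,
         CSplus = truth$prototype_plus,
         CSminus = truth$prototype_minus,
         none = rep(0, truth$n_voxels))
}

#' Simulate a trial-by-voxel ROI dataset for a schedule
#'
#' Each row follows the mixing model: view trials are
#' `view_gain * prototype(viewed) + noise`, imagine trials
#' `imagery_gain * prototype(imagined) + noise`, and regulate trials
#' `regulate_view_gain * prototype(viewed) +
#'  regulate_imagery_gain * prototype(imagined) + noise`. Rows align
#' one-to-one with the schedule's trials.
#'
#' @param schedule A `phase_schedule` (exclusions applied).
#' @param truth A `pattern_truth` (typically participant-specific).
#' @param seed Integer seed for the trial noise.
#' @param roi_name,participant_id Metadata carried on the dataset.
#' @return An object of class `roi_dataset`: list with the numeric matrix `X`
#'   (trials x voxels), the schedule's trial table `trials`, and metadata.
#' @export
simulate_roi_dataset <- function(schedule, truth, seed, roi_name = "ROI",
                                 participant_id = "p01") {
  stopifnot(inherits(schedule, "phase_schedule"), inherits(truth, "pattern_truth"))
  tr <- schedule$trials
  n <- nrow(tr)
  mu <- matrix(0, n, truth$n_voxels)
  for (i in seq_len(n)) {
    mu[i, ] <-
      switch(tr$instruction[i],
        view = truth$view_gain * prototype_of(truth, tr$viewed_stimulus[i]),
        imagine = truth$imagery_gain * prototype_of(truth, tr$imagined_stimulus[i]),
        regulate = truth$regulate_view_gain * prototype_of(truth, tr$viewed_stimulus[i]) +
          truth$regulate_imagery_gain * prototype_of(truth, tr$imagined_stimulus[i]),
        stop_integrity("unknown instruction: ", tr$instruction[i])
      )
  }
  noise <- with_seed(derive_seed(seed, "roi_noise", roi_name),
                     matrix(stats::rnorm(n * truth$n_voxels, 0, truth$noise_sd),
                            n, truth$n_voxels))
  structure(
    list(X = mu + noise, trials = tr, roi_name = roi_name,
         participant_id = participant_id, phase = schedule$phase),
    class = "roi_dataset"
  )
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat("<roi_dataset>", x$roi_name, "/", x$participant_id, "/", x$phase, ":",
      nrow(x$X), "trials x", ncol(x$X), "voxels\n")
  invisible(x)
}

#' Ground truth for skin conductance simulation
#'
#' Event-locked responses use a difference-of-two-exponentials kernel,
#' normalised so that the condition amplitude equals the kernel peak height.
#' The kernel is zero before `latency`, then
#' `exp(-s/decay) - exp(-s/rise)` (s = time since latency), whose analytic
#' peak is at `s* = rise * decay / (decay - rise) * log(decay / rise)`.
#'
#' @param amplitudes Named numeric vector of peak amplitudes (microsiemens),
#'   one per condition label (see [condition_label()]).
#' @param us_amplitude Extra response amplitude added on reinforced (shock)
#'   trials; those trials are excluded from analysis but present in the trace.
#' @param participant_amp_sd,condition_jitter_sd Log-normal sigmas of the
#'   multiplicative participant-level gain (shared across conditions) and of
#'   per-condition amplitude jitter, applied once per simulated trace.
#'   Electrodermal responsiveness varies strongly between people, and these
#'   terms give condition means realistic between-participant variance; zero
#'   amplitudes stay exactly zero.
#' @param latency,rise,decay Kernel timing parameters in seconds.
#' @param baseline Tonic conductance level (microsiemens).
#' @param drift_slope Linear drift in microsiemens per second.
#' @param noise_sd Gaussian sample noise (microsiemens).
#' @param fs Sampling rate; fixed at 1000 Hz to match acquisition.
#' @return An object of class `scr_truth`.
#' @export
scr_truth <- function(amplitudes = c(view_CSplus = 0.35, view_CSminus = 0.15,
                                     imagine_CSplus = 0.25, imagine_CSminus = 0.12,
                                     regulate_CSplus = 0.18, regulate_CSminus = 0.20),
                      us_amplitude = 0.5, latency = 1, rise = 0.75, decay = 2,
                      baseline = 5, drift_slope = 5e-4, noise_sd = 0.02,
                      participant_amp_sd = 0.4, condition_jitter_sd = 0.25,
                      fs = 1000) {
  stopifnot(all(amplitudes >= 0), us_amplitude >= 0, rise > 0, decay > rise,
            latency >= 0, noise_sd >= 0, fs == 1000,
            participant_amp_sd >= 0, condition_jitter_sd >= 0)
  structure(
    list(amplitudes = amplitudes, us_amplitude = us_amplitude,
         latency = latency, rise = rise, decay = decay, baseline = baseline,
         drift_slope = drift_slope, noise_sd = noise_sd,
         participant_amp_sd = participant_amp_sd,
         condition_jitter_sd = condition_jitter_sd, fs = as.integer(fs)),
    class = "scr_truth"
  )
}

#' Difference-of-exponentials SCR kernel, peak-normalised to 1
#'
#' @param t Time since event onset, seconds (vectorised).
#' @param latency,rise,decay Kernel parameters, seconds.
#' @return Kernel values; maximum is exactly 1 at
#'   `latency + rise*decay/(decay-rise)*log(decay/rise)`.
#' @export
scr_kernel <- function(t, latency = 1, rise = 0.75, decay = 2) {
  s <- t - latency
  s_peak <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-s_peak / decay) - exp(-s_peak / rise)
  out <- ifelse(s > 0, (exp(-s / decay) - exp(-s / rise)) / peak, 0)
  out
}

#' Simulate a 1 kHz skin conductance trace for a schedule
#'
#' Each run is simulated independently: a tonic baseline plus linear drift,
#' plus one event-locked kernel per trial (amplitude chosen by condition,
#' reinforced trials additionally receive `us_amplitude`), plus Gaussian
#' noise. Onsets mark CS onset and follow the schedule's trial timing.
#'
#' @param schedule A `phase_schedule`.
#' @param truth An `scr_truth`; amplitudes must cover every condition in the
#'   schedule.
#' @param seed Integer seed for the noise.
#' @return An object of class `scr_trace`: list with `fs`, per-run numeric
#'   vectors `samples`, per-run integer vectors `onset_idx` (1-based sample
#'   index of CS onset), and the schedule's trial table.
#' @export
simulate_scr <- function(schedule, truth, seed) {
  stopifnot(inherits(schedule, "phase_schedule"), inherits(truth, "scr_truth"))
  tr <- schedule$trials
  cond <- condition_label(tr)
  missing_amp <- setdiff(unique(cond), names(truth$amplitudes))
  if (length(missing_amp) > 0) {
    stop_config("no SCR amplitude defined for condition(s): ",
                paste(missing_amp, collapse = ", "))
  }
  cue <- if (schedule$phase == "classifier_training") 0 else TRIAL_TIMING$cue
  trial_len <- cue + TRIAL_TIMING$stimulus + TRIAL_TIMING$iti
  fs <- truth$fs
  # one multiplicative responsiveness draw per trace (participant level),
  # plus per-condition jitter; zero amplitudes remain exactly zero
  conds_all <- names(truth$amplitudes)
  het <- with_seed(derive_seed(seed, "scr_amplitudes"), list(
    g = exp(stats::rnorm(1, 0, truth$participant_amp_sd)),
    j = exp(stats::rnorm(length(conds_all), 0, truth$condition_jitter_sd))
  ))
  amps <- stats::setNames(truth$amplitudes * het$g * het$j, conds_all)
  us_amp <- truth$us_amplitude * het$g
  runs <- sort(unique(tr$run_index))
  samples <- vector("list", length(runs))
  onsets <- vector("list", length(runs))
  for (k in seq_along(runs)) {
    rows <- which(tr$run_index == runs[k])
    n_tr <- length(rows)
    dur <- n_tr * trial_len + 2 # 2 s tail so the last epoch fits
    n_samp <- as.integer(dur * fs)
    tt <- (seq_len(n_samp) - 1) / fs
    onset_s <- (tr$position_in_run[rows] - 1) * trial_len + cue
    sig <- truth$baseline + truth$drift_slope * tt
    for (j in seq_along(rows)) {
      amp <- amps[[cond[rows[j]]]] +
        if (tr$reinforced[rows[j]]) us_amp else 0
      if (amp > 0) {
        rel <- tt - onset_s[j]
        act <- rel > truth$latency & rel < 15 # kernel support is effectively < 15 s
        sig[act] <- sig[act] +
          amp * scr_kernel(rel[act], truth$latency, truth$rise, truth$decay)
      }
    }
    noise <- with_seed(derive_seed(seed, "scr", runs[k]),
                       stats::rnorm(n_samp, 0, truth$noise_sd))
    samples[[k]] <- sig + noise
    onsets[[k]] <- as.integer(round(onset_s * fs)) + 1L
  }
  structure(
    list(fs = fs, samples = samples, onset_idx = onsets, trials = tr,
         run_index = runs),
    class = "scr_trace"
  )
}

#' Ground truth for Likert ratings
#'
#' @param means Named numeric vector of condition means on the 1-7 scale.
#' @param sd Within-participant response SD.
#' @param participant_sd SD of a participant-level random shift.
#' @return An object of class `ratings_truth`.
#' @export
ratings_truth <- function(means, sd = 1, participant_sd = 0.5) {
  stopifnot(all(means >= 1), all(means <= 7), sd >= 0, participant_sd >= 0)
  structure(list(means = means, sd = sd, participant_sd = participant_sd),
            class = "ratings_truth")
}

#' Simulate 7-point Likert ratings
#'
#' One integer rating per participant per condition: condition mean +
#' participant shift + Gaussian noise, rounded and clipped to `[1, 7]`.
#'
#' @param truth A `ratings_truth`.
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @return Long data frame: `participant`, `condition`, `rating`.
#' @export
simulate_ratings <- function(truth, n_participants, seed) {
  stopifnot(inherits(truth, "ratings_truth"), n_participants >= 1)
  conds <- names(truth$means)
  out <- with_seed(derive_seed(seed, "ratings"), {
    shift <- stats::rnorm(n_participants, 0, truth$participant_sd)
    df <- expand.grid(participant = seq_len(n_participants), condition = conds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    raw <- truth$means[df$condition] + shift[df$participant] +
      stats::rnorm(nrow(df), 0, truth$sd)
    df$rating <- as.integer(pmin(7, pmax(1, round(raw))))
    df
  })
  out[order(out$participant, out$condition), c("participant", "condition", "rating")]
}
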