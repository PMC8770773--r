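#' @title Synthetic replication of the two-visit experiment
#' @description
#' `run_experiment1()` replicates visit one (fear transfer to imagined
#' stimuli): classifier-training and conditioning schedules, synthetic ROI
#' patterns, SCR scoring, view/imagine cross-classification with group
#' permutation + bootstrap inference, and the behavioural statistics.
#' `run_experiment2()` replicates visit two (regulation of fear by mental
#' imagery): regulation schedules, view/regulate decoding in visual ROIs,
#' the gated amygdala analysis in both directions, and the corresponding
#' SCR and rating statistics. Everything is deterministic under the
#' configuration's master seed.
#' @name pipeline
NULL

default_rois <- function() {
  vis <- function(n) list(n_voxels = n, K = 120, signal_scale = 1)
  list(
    V1 = vis(500), V2 = vis(500), V3 = vis(500), V4_V3AB = vis(500),
    amygdala = list(n_voxels = 800, K = 300, signal_scale = 0.6)
  )
}

#' Experiment configuration
#'
#' Defaults reproduce the study's procedural constants: 13 participants in
#' experiment 1 and 12 in experiment 2; 6 classifier-training, 3
#' pre-conditioning, 6 conditioning and 8 regulation runs; 120 selected
#' voxels in visual ROIs and 300 in the amygdala; 10,000 permutations and
#' 10,000 bootstrap iterations. Any element can be overridden (tests use
#' fewer ROIs, voxels and resampling iterations through identical code
#' paths).
#'
#' @param ... Named overrides of the defaults (unknown names are an error).
#' @return An object of class `experiment_config`.
#' @examples
#' cfg <- experiment_config(n_perm = 500, n_boot = 1000,
#'                          rois = list(V1 = list(n_voxels = 150, K = 60,
#'                                                signal_scale = 1)))
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n_participants_exp1 = 13,
    n_participants_exp2 = 12,
    runs = list(classifier_training = 6, preconditioning = 3,
                conditioning = 6, regulation = 8),
    rois = default_rois(),
    pattern = list(view_gain = 1, imagery_gain = 0.5,
                   regulate_view_gain = 0.7, regulate_imagery_gain = 0.5,
                   prototype_cor = 0, noise_sd = 8,
                   participant_variability_sd = 0.3),
    scr = scr_truth(),
    ratings = list(
      fear_exp1 = ratings_truth(c(view_CSplus = 5.6, view_CSminus = 1.8,
                                  imagine_CSplus = 4.6, imagine_CSminus = 1.9),
                                sd = 0.9, participant_sd = 0.5),
      vividness_exp1 = ratings_truth(c(imagine_CSplus = 4.3, imagine_CSminus = 4.0),
                                     sd = 1.1, participant_sd = 0.6),
      fear_exp2 = ratings_truth(c(view_CSplus = 5.9, view_CSminus = 1.5,
                                  regulate_CSplus = 2.9, regulate_CSminus = 3.9),
                                sd = 0.9, participant_sd = 0.5),
      vividness_exp2 = ratings_truth(c(regulate_CSplus = 4.8, regulate_CSminus = 4.6),
                                     sd = 1.2, participant_sd = 0.6)
    ),
    n_perm = 10000, n_boot = 10000,
    seed = 1, alpha = 0.05,
    scr_tail_exp1 = "greater",   # directional CS+ > CS- hypothesis, visit 1
    scr_tail_exp2 = "two.sided", # regulation contrasts are two-tailed
    include_scr = TRUE, include_ratings = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop_config("unknown config field(s): ",
                                       paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "experiment_config")
}

roi_group_truth <- function(cfg, roi_name) {
  roi <- cfg$rois[[roi_name]]
  p <- cfg$pattern
  pattern_truth(
    n_voxels = roi$n_voxels,
    view_gain = p$view_gain * roi$signal_scale,
    imagery_gain = p$imagery_gain * roi$signal_scale,
    regulate_view_gain = p$regulate_view_gain * roi$signal_scale,
    regulate_imagery_gain = p$regulate_imagery_gain * roi$signal_scale,
    prototype_cor = p$prototype_cor, noise_sd = p$noise_sd,
    participant_variability_sd = p$participant_variability_sd,
    seed = derive_seed(cfg$seed, "roi_truth", roi_name)
  )
}

participant_ids <- function(n) sprintf("p%02d", seq_len(n))

# schedules are shared across ROIs within a participant; seeded per
# participant so trial orders differ between participants
participant_schedule <- function(cfg, pid, phase) {
  apply_exclusions(build_phase_schedule(
    phase, cfg$runs[[phase]], derive_seed(cfg$seed, "schedule", phase, pid)))
}

participant_roi_data <- function(cfg, pid, roi_name, schedule) {
  g <- roi_group_truth(cfg, roi_name)
  pt <- participant_pattern_truth(g, pid, cfg$seed)
  simulate_roi_dataset(schedule, pt,
                       seed = derive_seed(cfg$seed, pid, schedule$phase, roi_name),
                       roi_name = roi_name, participant_id = pid)
}

filter_trials <- function(dataset, keep) {
  stopifnot(inherits(dataset, "roi_dataset"), length(keep) == nrow(dataset$trials))
  dataset$X <- dataset$X[keep, , drop = FALSE]
  dataset$trials <- dataset$trials[keep, , drop = FALSE]
  dataset
}

split_condition <- function(cond) {
  parts <- strsplit(cond, "_", fixed = TRUE)
  data.frame(instruction = vapply(parts, `[[`, "", 1),
             cs_type = vapply(parts, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

# per-ROI decoding + inference over a list of participants
group_decode <- function(cfg, trains, tests, roi_name, conds, tail_diff = "two.sided") {
  K <- cfg$rois[[roi_name]]$K
  obs <- list(); nulls <- list()
  for (i in seq_along(trains)) {
    sel <- select_features(trains[[i]], K)
    clf <- train_classifier(trains[[i]], sel)
    acc <- cross_classify(clf, tests[[i]])
    obs[[i]] <- stats::setNames(acc$accuracy, acc$condition)
    nulls[[i]] <- participant_null(
      trains[[i]], tests[[i]], K, cfg$n_perm,
      seed = derive_seed(cfg$seed, "perm", roi_name, trains[[i]]$participant_id))
  }
  per_cond <- lapply(conds, function(cn) {
    o <- vapply(obs, `[[`, 0.0, cn)
    test <- group_accuracy_test(o, nulls, cfg$n_boot,
                                seed = derive_seed(cfg$seed, "boot", roi_name, cn),
                                condition = cn, tail = "greater")
    data.frame(roi = roi_name, condition = cn,
               observed_accuracy = test$observed, p_value = test$p,
               tail = test$tail, n_perm = cfg$n_perm, n_boot = cfg$n_boot,
               seed = cfg$seed, stringsAsFactors = FALSE)
  })
  diff <- NULL
  if (length(conds) == 2) {
    o1 <- vapply(obs, `[[`, 0.0, conds[1])
    o2 <- vapply(obs, `[[`, 0.0, conds[2])
    dt <- condition_difference_test(
      o1, o2, nulls, cond_a = conds[1], cond_b = conds[2],
      n_boot = cfg$n_boot,
      seed = derive_seed(cfg$seed, "boot_diff", roi_name), tail = tail_diff)
    diff <- data.frame(roi = roi_name, contrast = paste(conds, collapse = " - "),
                       observed_difference = dt$observed, p_value = dt$p,
                       tail = dt$tail, stringsAsFactors = FALSE)
  }
  list(accuracies = do.call(rbind, per_cond), difference = diff,
       observed = obs, nulls = nulls)
}

scr_participant_means <- function(cfg, pid, schedule) {
  trace <- simulate_scr(schedule, cfg$scr, seed = derive_seed(cfg$seed, pid, "scr"))
  peaks <- score_trial_peaks(scr_epochs(scr_preprocess(trace)))
  scr_condition_means(peaks)
}

scr_group_stats <- function(means_list, tail) {
  tab <- do.call(rbind, lapply(seq_along(means_list), function(i) {
    m <- means_list[[i]]
    cbind(participant = i, m, split_condition(m$condition))
  }))
  an <- rm_anova_2x2(tab, "participant", "cs_type", "instruction", "mean_peak")
  wide <- stats::reshape(tab[, c("participant", "condition", "mean_peak")],
                         idvar = "participant", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^mean_peak\\.", "", names(wide))
  instr <- unique(split_condition(setdiff(names(wide), "participant"))$instruction)
  tt <- lapply(instr, function(iv) {
    r <- paired_t(wide[[paste0(iv, "_CSplus")]], wide[[paste0(iv, "_CSminus")]],
                  tail = tail)
    data.frame(contrast = sprintf("%s: CSplus - CSminus", iv),
               t = r$t, df = r$df, p = r$p, tail = r$tail, cohen_d = r$cohen_d,
               stringsAsFactors = FALSE)
  })
  list(condition_means = tab, anova = an, t_tests = do.call(rbind, tt))
}

ratings_group_stats <- function(fear, vividness, vividness_floor = 1) {
  fc <- split_condition(fear$condition)
  fear2 <- cbind(fear, fc)
  an <- rm_anova_2x2(fear2, "participant", "cs_type", "instruction", "rating")
  wide <- stats::reshape(fear[, c("participant", "condition", "rating")],
                         idvar = "participant", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^rating\\.", "", names(wide))
  instr <- unique(fc$instruction)
  tt <- lapply(instr, function(iv) {
    r <- paired_t(wide[[paste0(iv, "_CSplus")]], wide[[paste0(iv, "_CSminus")]])
    data.frame(contrast = sprintf("fear %s: CSplus - CSminus", iv),
               t = r$t, df = r$df, p = r$p, tail = r$tail, cohen_d = r$cohen_d,
               stringsAsFactors = FALSE)
  })
  viv <- lapply(sort(unique(vividness$condition)), function(cn) {
    x <- vividness$rating[vividness$condition == cn]
    r <- one_sample_t(x, mu = vividness_floor, tail = "greater")
    data.frame(contrast = sprintf("vividness %s > floor", cn),
               t = r$t, df = r$df, p = r$p, tail = r$tail, cohen_d = r$cohen_d,
               stringsAsFactors = FALSE)
  })
  list(anova = an, t_tests = rbind(do.call(rbind, tt), do.call(rbind, viv)))
}

provenance_block <- function(cfg, experiment) {
  list(experiment = experiment, seed = cfg$seed, n_perm = cfg$n_perm,
       n_boot = cfg$n_boot, rois = names(cfg$rois),
       n_participants = if (experiment == 1) cfg$n_participants_exp1
                        else cfg$n_participants_exp2,
       runs = cfg$runs)
}

#' Run the visit-one replication (fear transfer to imagined stimuli)
#'
#' @param config An [experiment_config()].
#' @return An object of class `results_bundle` with elements `decoding`
#'   (per-ROI accuracies and p-values), `differences` (view vs imagine),
#'   `scr`, `ratings`, and `provenance`.
#' @export
run_experiment1 <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  pids <- participant_ids(cfg$n_participants_exp1)
  ct <- lapply(pids, participant_schedule, cfg = cfg, phase = "classifier_training")
  cond <- lapply(pids, participant_schedule, cfg = cfg, phase = "conditioning")

  decoding <- NULL; differences <- NULL
  for (roi in names(cfg$rois)) {
    trains <- lapply(seq_along(pids), function(i)
      participant_roi_data(cfg, pids[i], roi, ct[[i]]))
    tests <- lapply(seq_along(pids), function(i)
      participant_roi_data(cfg, pids[i], roi, cond[[i]]))
    g <- group_decode(cfg, trains, tests, roi, c("view", "imagine"))
    decoding <- rbind(decoding, g$accuracies)
    differences <- rbind(differences, g$difference)
  }

  scr <- NULL
  if (cfg$include_scr) {
    means <- lapply(seq_along(pids), function(i)
      scr_participant_means(cfg, pids[i], cond[[i]]))
    scr <- scr_group_stats(means, tail = cfg$scr_tail_exp1)
  }
  ratings <- NULL
  if (cfg$include_ratings) {
    fear <- simulate_ratings(cfg$ratings$fear_exp1, length(pids),
                             derive_seed(cfg$seed, "fear_exp1"))
    viv <- simulate_ratings(cfg$ratings$vividness_exp1, length(pids),
                            derive_seed(cfg$seed, "vividness_exp1"))
    ratings <- ratings_group_stats(fear, viv)
  }
  structure(list(decoding = decoding, differences = differences, scr = scr,
                 ratings = ratings, provenance = provenance_block(cfg, 1)),
            class = "results_bundle")
}

gated_amygdala <- function(cfg, trains, tests, label, dependent_cond) {
  g <- group_decode(cfg, trains, tests, "amygdala", c("view", dependent_cond))
  view_p <- g$accuracies$p_value[g$accuracies$condition == "view"]
  proceed <- amygdala_gate(view_p, cfg$alpha)
  acc <- g$accuracies
  if (!proceed) {
    # the dependent analysis is reported as not run, not as a number
    acc <- acc[acc$condition == "view", , drop = FALSE]
    g$difference <- NULL
  }
  list(direction = label, gate_p = view_p, gate_passed = proceed,
       accuracies = acc, difference = g$difference)
}

#' Run the visit-two replication (regulation of fear by mental imagery)
#'
#' Visual ROIs are trained on the (regenerated) day-one classifier-training
#' data of the returning participants and tested on regulation-phase trials
#' (regulate trials scored against the viewed stimulus). The amygdala
#' analysis trains on day-one conditioning view trials and is gated on its
#' view-trial positive control; the reverse direction (train on regulation
#' view trials, test day-one conditioning) is likewise gated.
#'
#' @param config An [experiment_config()].
#' @return A `results_bundle` with `decoding`, `differences`, `amygdala`
#'   (forward and reverse gated analyses), `scr`, `ratings`, `provenance`.
#' @export
run_experiment2 <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  if (cfg$n_participants_exp2 > cfg$n_participants_exp1) {
    stop_config("experiment 2 participants must be a subset of experiment 1")
  }
  pids <- participant_ids(cfg$n_participants_exp2) # returning participants
  ct <- lapply(pids, participant_schedule, cfg = cfg, phase = "classifier_training")
  cond <- lapply(pids, participant_schedule, cfg = cfg, phase = "conditioning")
  reg <- lapply(pids, participant_schedule, cfg = cfg, phase = "regulation")

  decoding <- NULL; differences <- NULL; amygdala <- list()
  for (roi in names(cfg$rois)) {
    reg_data <- lapply(seq_along(pids), function(i)
      participant_roi_data(cfg, pids[i], roi, reg[[i]]))
    if (roi == "amygdala") {
      cond_data <- lapply(seq_along(pids), function(i)
        participant_roi_data(cfg, pids[i], roi, cond[[i]]))
      cond_view <- lapply(cond_data, function(d)
        filter_trials(d, d$trials$instruction == "view"))
      amygdala$forward <- gated_amygdala(cfg, cond_view, reg_data,
                                         "conditioning_view -> regulation",
                                         dependent_cond = "regulate")
      # reverse direction: train on regulation view trials, test day one
      reg_view <- lapply(reg_data, function(d)
        filter_trials(d, d$trials$instruction == "view"))
      amygdala$reverse <- gated_amygdala(cfg, reg_view, cond_data,
                                         "regulation_view -> conditioning",
                                         dependent_cond = "imagine")
    } else {
      trains <- lapply(seq_along(pids), function(i)
        participant_roi_data(cfg, pids[i], roi, ct[[i]]))
      g <- group_decode(cfg, trains, reg_data, roi, c("view", "regulate"))
      decoding <- rbind(decoding, g$accuracies)
      differences <- rbind(differences, g$difference)
    }
  }

  scr <- NULL
  if (cfg$include_scr) {
    means <- lapply(seq_along(pids), function(i)
      scr_participant_means(cfg, pids[i], reg[[i]]))
    scr <- scr_group_stats(means, tail = cfg$scr_tail_exp2)
  }
  ratings <- NULL
  if (cfg$include_ratings) {
    fear <- simulate_ratings(cfg$ratings$fear_exp2, length(pids),
                             derive_seed(cfg$seed, "fear_exp2"))
    viv <- simulate_ratings(cfg$ratings$vividness_exp2, length(pids),
                            derive_seed(cfg$seed, "vividness_exp2"))
    ratings <- ratings_group_stats(fear, viv)
  }
  structure(list(decoding = decoding, differences = differences,
                 amygdala = amygdala, scr = scr, ratings = ratings,
                 provenance = provenance_block(cfg, 2)),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle> experiment", x$provenance$experiment,
      "- seed", x$provenance$seed, "\n")
  if (!is.null(x$decoding)) {
    cat("decoding:\n")
    print(x$decoding, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

empty_df <- function(cols) {
  as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a results bundle to disk
#'
#' Tidy TSV tables, a machine-readable JSON summary holding every result at
#' full precision, and a short run log. An empty bundle produces
#' headers-only tables.
#'
#' @param bundle A `results_bundle` (possibly with NULL components).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, default_cols, name) {
    p <- file.path(dir, name)
    write_tsv(df %||% empty_df(default_cols), p)
    paths <<- c(paths, p)
  }
  put(bundle$decoding,
      c("roi", "condition", "observed_accuracy", "p_value", "tail",
        "n_perm", "n_boot", "seed"), "decoding.tsv")
  put(bundle$differences,
      c("roi", "contrast", "observed_difference", "p_value", "tail"),
      "differences.tsv")
  put(bundle$scr$condition_means,
      c("participant", "condition", "n_trials", "mean_peak"), "scr_means.tsv")
  put(bundle$scr$anova, c("effect", "F", "df_num", "df_den", "p", "eta_G_sq"),
      "scr_anova.tsv")
  put(bundle$scr$t_tests, c("contrast", "t", "df", "p", "tail", "cohen_d"),
      "scr_ttests.tsv")
  put(bundle$ratings$anova, c("effect", "F", "df_num", "df_den", "p", "eta_G_sq"),
      "ratings_anova.tsv")
  put(bundle$ratings$t_tests, c("contrast", "t", "df", "p", "tail", "cohen_d"),
      "ratings_ttests.tsv")
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(unclass(bundle), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  paths <- c(paths, json_path)
  log_path <- file.path(dir, "run_log.txt")
  writeLines(c(
    sprintf("experiment: %s", bundle$provenance$experiment),
    sprintf("seed: %s", bundle$provenance$seed),
    sprintf("n_participants: %s", bundle$provenance$n_participants),
    sprintf("n_perm: %s  n_boot: %s", bundle$provenance$n_perm,
            bundle$provenance$n_boot),
    sprintf("rois: %s", paste(bundle$provenance$rois, collapse = ", "))
  ), log_path)
  invisible(c(paths, log_path))
}
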