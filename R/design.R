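#' @title Trial schedules for a two-visit fear conditioning experiment
#' @description
#' The experiment is organised into phases: a classifier-training phase in
#' which the two conditioned stimuli (CS+ and CS-) are only viewed, a
#' pre-conditioning practice phase, a conditioning phase (viewing and
#' imagining), and a regulation phase (viewing while imagining the opposite
#' stimulus). `build_phase_schedule()` constructs the ordered trial list for a
#' phase, `apply_exclusions()` flags the trials removed from analysis, and
#' `count_analyzable()` tabulates included trials per condition.
#' @name design
NULL

PHASES <- c("classifier_training", "preconditioning", "conditioning", "regulation")
STIMULI <- c("CSplus", "CSminus")

# Seconds; the audio cue precedes the stimulus in every phase after
# classifier training, the stimulus is shown for 6.5 s, and trials are
# separated by a 12 s inter-trial interval.
TRIAL_TIMING <- list(cue = 1.5, stimulus = 6.5, iti = 12)

new_trial_df <- function(n) {
  data.frame(
    phase = character(n), run_index = integer(n), position_in_run = integer(n),
    viewed_stimulus = character(n), imagined_stimulus = character(n),
    instruction = character(n), reinforced = logical(n), included = logical(n),
    stringsAsFactors = FALSE
  )
}

trial_row <- function(instruction, viewed, imagined, reinforced = FALSE) {
  list(instruction = instruction, viewed = viewed, imagined = imagined,
       reinforced = reinforced)
}

#' Condition label of each trial
#'
#' View trials are keyed by the viewed stimulus, imagine trials by the
#' imagined stimulus, and regulate trials by the viewed stimulus (so
#' `regulate_CSplus` is the down-regulation condition, viewing the CS+ while
#' imagining the CS-, and `regulate_CSminus` is up-regulation).
#'
#' @param trials A trial data frame (the `trials` element of a schedule).
#' @return Character vector of condition labels.
#' @export
condition_label <- function(trials) {
  key <- ifelse(trials$instruction == "imagine",
                trials$imagined_stimulus, trials$viewed_stimulus)
  paste(trials$instruction, key, sep = "_")
}

run_composition <- function(phase) {
  switch(phase,
    classifier_training = {
      # 5 view trials per stimulus per run, no cue, no reinforcement
      c(rep(list(trial_row("view", "CSplus", "none")), 5),
        rep(list(trial_row("view", "CSminus", "none")), 5))
    },
    preconditioning = {
      # 4 view + 4 imagine per stimulus per run, practice only
      c(rep(list(trial_row("view", "CSplus", "none")), 4),
        rep(list(trial_row("view", "CSminus", "none")), 4),
        rep(list(trial_row("imagine", "none", "CSplus")), 4),
        rep(list(trial_row("imagine", "none", "CSminus")), 4))
    },
    stop_config("unknown phase: ", phase)
  )
}

# Middle trials (positions 3..11) of a conditioning or regulation run. One of
# the three view CS+ trials is reinforced (chosen by the caller) so that,
# together with the mandatory reinforced trial at position 2, exactly 50% of
# the four view CS+ trials in the run carry shock.
middle_pool <- function(phase, reinforced_slot) {
  imag_instr <- if (phase == "conditioning") "imagine" else "regulate"
  pool <- c(
    lapply(seq_len(3), function(i)
      trial_row("view", "CSplus", "none", reinforced = (i == reinforced_slot))),
    rep(list(trial_row("view", "CSminus", "none")), 2),
    if (phase == "conditioning") {
      c(rep(list(trial_row("imagine", "none", "CSplus")), 2),
        rep(list(trial_row("imagine", "none", "CSminus")), 2))
    } else {
      # regulate trials view one CS while imagining the opposite one
      c(rep(list(trial_row("regulate", "CSplus", "CSminus")), 2),
        rep(list(trial_row("regulate", "CSminus", "CSplus")), 2))
    }
  )
  pool
}

#' Build the trial schedule for one experimental phase
#'
#' Conditioning and regulation runs have a fixed frame: the first and last
#' trial are view CS- trials, the second trial is a reinforced view CS+, and
#' the remaining trials (positions 3 to 11) are shuffled under the seed.
#' Exactly half of the view CS+ trials in each run are reinforced (the
#' mandatory one at position 2 plus one seeded pick among the remaining
#' three). Classifier-training runs hold 5 view trials per stimulus in random
#' order; pre-conditioning runs hold 4 view + 4 imagine per stimulus.
#'
#' @param phase One of `"classifier_training"`, `"preconditioning"`,
#'   `"conditioning"`, `"regulation"`.
#' @param n_runs Number of runs (>= 1). The study used 6 classifier-training
#'   runs, 3 pre-conditioning runs, 6 conditioning runs, and 8 regulation runs.
#' @param seed Integer seed; identical `(phase, n_runs, seed)` yield identical
#'   schedules.
#' @return An object of class `phase_schedule`: a list with elements `phase`,
#'   `n_runs`, `seed`, and `trials` (a data frame with one row per trial).
#' @examples
#' sch <- build_phase_schedule("conditioning", 6, seed = 7)
#' table(condition_label(sch$trials))
#' @export
build_phase_schedule <- function(phase, n_runs, seed) {
  phase <- as.character(phase)
  if (!phase %in% PHASES) stop_config("unknown phase: ", phase)
  stopifnot(n_runs >= 1)
  n_runs <- as.integer(n_runs)
  seed <- as.integer(seed)

  runs <- lapply(seq_len(n_runs), function(r) {
    run_seed <- derive_seed(seed, phase, "run", r)
    if (phase %in% c("classifier_training", "preconditioning")) {
      pool <- run_composition(phase)
      ord <- with_seed(run_seed, sample.int(length(pool)))
      trials <- pool[ord]
    } else {
      slot <- with_seed(derive_seed(seed, phase, "reinforce", r), sample.int(3, 1))
      mid <- middle_pool(phase, slot)
      ord <- with_seed(run_seed, sample.int(length(mid)))
      trials <- c(
        list(trial_row("view", "CSminus", "none")),
        list(trial_row("view", "CSplus", "none", reinforced = TRUE)),
        mid[ord],
        list(trial_row("view", "CSminus", "none"))
      )
    }
    df <- new_trial_df(length(trials))
    df$phase <- phase
    df$run_index <- r
    df$position_in_run <- seq_along(trials)
    df$viewed_stimulus <- vapply(trials, `[[`, "", "viewed")
    df$imagined_stimulus <- vapply(trials, `[[`, "", "imagined")
    df$instruction <- vapply(trials, `[[`, "", "instruction")
    df$reinforced <- vapply(trials, `[[`, FALSE, "reinforced")
    df$included <- TRUE
    df
  })

  structure(
    list(phase = phase, n_runs = n_runs, seed = seed,
         trials = do.call(rbind, runs)),
    class = "phase_schedule"
  )
}

#' Flag trials excluded from analysis
#'
#' Reinforced (shock) trials are excluded, as are the first and the last view
#' CS- trial of each conditioning or regulation run; this equates the number
#' of analysable trials across conditions and removes run-onset novelty
#' effects. Classifier-training and pre-conditioning trials are never
#' excluded. The operation is idempotent.
#'
#' @param schedule A `phase_schedule`.
#' @return The schedule with its `included` column updated.
#' @export
apply_exclusions <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  tr <- schedule$trials
  tr$included <- TRUE
  tr$included[tr$reinforced] <- FALSE
  if (schedule$phase %in% c("conditioning", "regulation")) {
    for (r in unique(tr$run_index)) {
      idx <- which(tr$run_index == r & tr$instruction == "view" &
                     tr$viewed_stimulus == "CSminus")
      if (length(idx) > 0) tr$included[c(min(idx), max(idx))] <- FALSE
    }
  }
  schedule$trials <- tr
  schedule
}

#' Count analysable trials per condition
#'
#' @param schedule A `phase_schedule` with exclusions applied.
#' @return A data frame with columns `condition` and `n_included`, one row per
#'   condition present in the schedule (empty for an empty schedule).
#'   Signals an integrity error if the included counts are unequal across
#'   conditions, which indicates a malformed schedule.
#' @export
count_analyzable <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  tr <- schedule$trials
  if (nrow(tr) == 0) {
    return(data.frame(condition = character(0), n_included = integer(0),
                      stringsAsFactors = FALSE))
  }
  inc <- tr[tr$included, , drop = FALSE]
  tab <- table(factor(condition_label(inc)))
  out <- data.frame(condition = names(tab), n_included = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (length(unique(out$n_included)) > 1) {
    stop_integrity("unequal included trial counts across conditions: ",
                   paste(out$condition, out$n_included, sep = "=", collapse = ", "))
  }
  out
}

#' Serialize a schedule to a BIDS-style events table
#'
#' Onsets mark stimulus (CS) onset. In phases with an audio cue
#' (pre-conditioning, conditioning, regulation) each trial occupies
#' cue (1.5 s) + stimulus (6.5 s) + ITI (12 s) = 20 s; classifier-training
#' trials have no cue (18.5 s). Onsets restart at zero in each run.
#'
#' @param schedule A `phase_schedule`.
#' @param path Optional path; when given the table is written as
#'   tab-separated values.
#' @return Invisibly (when writing) or visibly, a data frame with columns
#'   `onset`, `duration`, `trial_type`, `run`, `reinforced`, `included`.
#' @export
schedule_events <- function(schedule, path = NULL) {
  stopifnot(inherits(schedule, "phase_schedule"))
  tr <- schedule$trials
  cue <- if (schedule$phase == "classifier_training") 0 else TRIAL_TIMING$cue
  trial_len <- cue + TRIAL_TIMING$stimulus + TRIAL_TIMING$iti
  ev <- data.frame(
    onset = (tr$position_in_run - 1) * trial_len + cue,
    duration = TRIAL_TIMING$stimulus,
    trial_type = condition_label(tr),
    run = tr$run_index,
    reinforced = tr$reinforced,
    included = tr$included,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(ev))
  }
  ev
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("<phase_schedule>", x$phase, "-", x$n_runs, "runs,",
      nrow(x$trials), "trials (seed", paste0(x$seed, ")"), "\n")
  inc <- sum(x$trials$included)
  cat("  included:", inc, "of", nrow(x$trials), "\n")
  invisible(x)
}
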