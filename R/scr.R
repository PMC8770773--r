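#' @title Skin conductance preprocessing and trial scoring
#' @description
#' Trough-to-peak scoring of event-related skin conductance responses.
#' Traces are recorded at 1 kHz; preprocessing linearly detrends each run
#' (retaining the run mean, so values stay interpretable in microsiemens),
#' smooths with a 50-sample median filter to suppress MRI-induced spikes, and
#' downsamples by decimation to 100 Hz. Trials are epoched from -1 to +8 s
#' around CS onset, baseline-corrected by the mean of the second before
#' onset, and scored as the maximum in 1-8 s minus the minimum in 0-0.99 s;
#' responses below 0.02 uS are zeroed.
#' @name scr_pipeline
NULL

SCR_ZERO_THRESHOLD <- 0.02 # uS; smaller trough-to-peak responses are zeroed

# least-squares linear detrend, keeping the mean of the run
detrend_keep_mean <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  x - fit$fitted.values + mean(x)
}

#' Preprocess a 1 kHz trace to 100 Hz
#'
#' Per run: linear detrend (run mean retained), 50-sample median filter with
#' reflection-padded edges (window covering samples i-25 .. i+24), then 10:1
#' decimation. Onset indices are rescaled to the 100 Hz grid.
#'
#' @param trace An `scr_trace` at 1000 Hz.
#' @return An `scr_trace` at 100 Hz.
#' @export
scr_preprocess <- function(trace) {
  stopifnot(inherits(trace, "scr_trace"))
  if (trace$fs != 1000) stop_config("scr_preprocess expects a 1000 Hz trace")
  width <- 50L
  for (k in seq_along(trace$samples)) {
    x <- trace$samples[[k]]
    if (length(x) < width) {
      stop_config("run ", k, " is shorter than the ", width, "-sample filter window")
    }
    x <- detrend_keep_mean(x)
    x <- .rolling_median_even(x, width)
    keep <- seq(1L, length(x), by = 10L)
    trace$samples[[k]] <- x[keep]
    trace$onset_idx[[k]] <- (trace$onset_idx[[k]] - 1L) %/% 10L + 1L
  }
  trace$fs <- 100L
  trace
}

# Epoch window geometry at 100 Hz, in sample offsets relative to CS onset.
EPOCH_PRE <- 100L   # baseline samples: offsets -100 .. -1  (-1.00 .. -0.01 s)
EPOCH_POST <- 800L  # response samples: offsets 0 .. 800    (0 .. 8.00 s)
MIN_WIN <- c(0L, 99L)    # trough search window, 0 .. 0.99 s
MAX_WIN <- c(100L, 800L) # peak search window, 1.00 .. 8.00 s

#' Extract baseline-corrected epochs
#'
#' Epochs cover -1.0 to +8.0 s around CS onset at 100 Hz (offsets -100..800,
#' 901 samples). Each epoch has the mean of its pre-onset second subtracted.
#' A trial whose window does not fit inside its run is flagged missing (all
#' NA) rather than scored.
#'
#' @param trace An `scr_trace` at 100 Hz (output of [scr_preprocess()]).
#' @return An object of class `epoch_matrix`: list with the numeric matrix
#'   `epochs` (trials x 901), logical `missing`, and the trial table.
#' @export
scr_epochs <- function(trace) {
  stopifnot(inherits(trace, "scr_trace"))
  if (trace$fs != 100) stop_config("scr_epochs expects a 100 Hz trace")
  n_per_run <- vapply(trace$onset_idx, length, 0L)
  n <- sum(n_per_run)
  width <- EPOCH_PRE + EPOCH_POST + 1L
  ep <- matrix(NA_real_, n, width)
  miss <- logical(n)
  row <- 0L
  for (k in seq_along(trace$samples)) {
    x <- trace$samples[[k]]
    for (o in trace$onset_idx[[k]]) {
      row <- row + 1L
      lo <- o - EPOCH_PRE
      hi <- o + EPOCH_POST
      if (lo < 1L || hi > length(x)) {
        miss[row] <- TRUE
        next
      }
      seg <- x[lo:hi]
      ep[row, ] <- seg - mean(seg[seq_len(EPOCH_PRE)])
    }
  }
  structure(list(epochs = ep, missing = miss, trials = trace$trials),
            class = "epoch_matrix")
}

#' Trough-to-peak score of one epoch
#'
#' `max` over 1-8 s minus `min` over 0-0.99 s; values below 0.02 uS
#' (including negative ones) are zeroed, so scores are non-negative.
#'
#' @param epoch Numeric vector of 901 baseline-corrected samples
#'   (offsets -100..800 at 100 Hz), or a vector containing NA for a missing
#'   trial.
#' @return A single non-negative score in microsiemens (NA if missing).
#' @export
score_trial_peak <- function(epoch) {
  if (anyNA(epoch)) return(NA_real_)
  stopifnot(length(epoch) == EPOCH_PRE + EPOCH_POST + 1L)
  off <- function(o) o + EPOCH_PRE + 1L # offset -> column index
  peak <- max(epoch[off(MAX_WIN[1]):off(MAX_WIN[2])]) -
    min(epoch[off(MIN_WIN[1]):off(MIN_WIN[2])])
  if (peak < SCR_ZERO_THRESHOLD) 0 else peak
}

#' Score all trials of an epoch matrix
#'
#' @param epochs An `epoch_matrix`.
#' @return A data frame (class `trial_peak_table`) with one row per trial:
#'   the trial metadata plus `peak` (uS; NA for missing trials) and `zeroed`.
#' @export
score_trial_peaks <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  peak <- apply(epochs$epochs, 1, score_trial_peak)
  out <- epochs$trials
  out$peak <- peak
  out$zeroed <- !is.na(peak) & peak == 0
  class(out) <- c("trial_peak_table", class(out))
  out
}

#' Condition means of trial peaks
#'
#' Averages scored peaks over the included trials of each condition
#' (reinforced trials and run-edge CS- trials are excluded by the schedule's
#' inclusion flags; missing trials reduce the denominator). A condition with
#' zero scoreable trials yields NA and is reported in the `complete`
#' attribute so the participant can be dropped from that contrast.
#'
#' @param peaks A `trial_peak_table` (with exclusions already applied to the
#'   schedule it came from).
#' @return Data frame `condition`, `n_trials`, `mean_peak`; attribute
#'   `complete` is FALSE if any condition has no scoreable trial.
#' @export
scr_condition_means <- function(peaks) {
  stopifnot(inherits(peaks, "trial_peak_table"))
  use <- peaks$included & !is.na(peaks$peak)
  conds <- sort(unique(condition_label(peaks[peaks$included, , drop = FALSE])))
  lab <- condition_label(peaks)
  out <- data.frame(
    condition = conds,
    n_trials = vapply(conds, function(cn) sum(use & lab == cn), 0L),
    mean_peak = vapply(conds, function(cn) {
      v <- peaks$peak[use & lab == cn]
      if (length(v) == 0) NA_real_ else mean(v)
    }, 0.0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "complete") <- !anyNA(out$mean_peak)
  out
}

#' Write / read a trace as two-column TSV plus events
#'
#' @param trace An `scr_trace`.
#' @param dir Output directory; one `run-<k>_scr.tsv` (time_ms,
#'   conductance_uS) and one `run-<k>_events.tsv` per run.
#' @return Invisibly, the written file paths.
#' @export
write_scr_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "scr_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in seq_along(trace$samples)) {
    x <- trace$samples[[k]]
    step <- 1000 / trace$fs
    df <- data.frame(time_ms = (seq_along(x) - 1) * step, conductance_uS = x)
    p1 <- file.path(dir, sprintf("run-%02d_scr.tsv", k))
    utils::write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    ev <- data.frame(onset_ms = (trace$onset_idx[[k]] - 1) * step)
    p2 <- file.path(dir, sprintf("run-%02d_events.tsv", k))
    utils::write.table(ev, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
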