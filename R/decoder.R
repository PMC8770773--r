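#' @title ROI decoding by multivariate cross-classification
#' @description
#' A linear support vector machine is trained, within participant, on view
#' trials of a designated training phase (classifier training for visual
#' ROIs; day-one conditioning view trials for the amygdala) to discriminate
#' CS+ from CS- and is then applied unchanged to test-phase trials. Feature
#' selection keeps the K voxels with the largest positive univariate CS+
#' minus CS- difference on the training data (K = 120 for visual ROIs, 300
#' for the amygdala). Chance performance is 50%.
#' @name decoder
NULL

CLASS_LEVELS <- c("CSminus", "CSplus")

#' Stimulus identity a trial is scored against
#'
#' View trials are scored against the viewed stimulus, imagine trials
#' against the imagined stimulus, regulate trials against the viewed
#' stimulus (so down-regulation trials count as CS+ and up-regulation trials
#' as CS-).
#'
#' @param trials A trial data frame.
#' @return Character vector (`"CSplus"`/`"CSminus"`).
#' @export
target_label <- function(trials) {
  ifelse(trials$instruction == "imagine",
         trials$imagined_stimulus, trials$viewed_stimulus)
}

# rows of a dataset eligible for decoding: included, never reinforced
decoding_rows <- function(dataset) {
  which(dataset$trials$included & !dataset$trials$reinforced)
}

#' Univariate feature selection
#'
#' Scores each voxel by mean(CS+ trials) - mean(CS- trials) over the
#' eligible training trials and keeps the top K, ties broken by ascending
#' voxel index. If fewer than K voxels have positive scores, the top K by
#' signed score are still taken (with a warning) so K stays fixed.
#'
#' @param train An `roi_dataset` (the training phase).
#' @param K Number of voxels to keep (>= 1, <= number of voxels).
#' @return An object of class `feature_selection` with sorted `indices` and
#'   per-voxel `scores`.
#' @export
select_features <- function(train, K) {
  stopifnot(inherits(train, "roi_dataset"), K >= 1)
  if (K > ncol(train$X)) {
    stop_config("K = ", K, " exceeds the ", ncol(train$X), " available voxels")
  }
  rows <- decoding_rows(train)
  y <- target_label(train$trials[rows, , drop = FALSE])
  if (length(unique(y)) < 2) stop_config("training data must contain both classes")
  scores <- colMeans(train$X[rows[y == "CSplus"], , drop = FALSE]) -
    colMeans(train$X[rows[y == "CSminus"], , drop = FALSE])
  ord <- order(-scores, seq_along(scores))
  idx <- ord[seq_len(K)]
  if (sum(scores > 0) < K) {
    warning("fewer than K voxels have a positive CS+ - CS- difference; ",
            "selection keeps the top K by signed score", call. = FALSE)
  }
  structure(list(indices = idx, K = as.integer(K), scores = scores),
            class = "feature_selection")
}

#' Train the linear SVM
#'
#' C-classification with a linear kernel on the selected feature columns of
#' the eligible training trials. The cost hyperparameter is auto-scaled to
#' the norm of the data: `C = 1 / mean(||x||_2)` over training vectors
#' (after feature selection), unless given explicitly.
#'
#' @param train An `roi_dataset`.
#' @param sel A `feature_selection` from the same training data.
#' @param cost Optional positive cost; default is the auto-scaling rule.
#' @return An object of class `linear_classifier` holding the weight vector
#'   over selected features, the bias, the cost used, the selection, and a
#'   fingerprint of the training set.
#' @export
train_classifier <- function(train, sel, cost = NULL) {
  stopifnot(inherits(train, "roi_dataset"), inherits(sel, "feature_selection"))
  rows <- decoding_rows(train)
  X <- train$X[rows, sel$indices, drop = FALSE]
  y <- factor(target_label(train$trials[rows, , drop = FALSE]), levels = CLASS_LEVELS)
  if (nlevels(droplevels(y)) < 2 || min(table(y)) < 2) {
    stop_config("training requires at least 2 trials of each class")
  }
  if (is.null(cost)) {
    mean_norm <- mean(sqrt(rowSums(X^2)))
    if (mean_norm <= 0) stop_config("cannot auto-scale cost: zero-norm training data")
    cost <- 1 / mean_norm
  }
  fit <- svm_train_linear(X, as.double(as.integer(y) - 1L), cost)
  structure(
    list(w = fit$w, rho = fit$rho, labels = fit$labels, levels = CLASS_LEVELS,
         cost = cost, selection = sel,
         fingerprint = c(n = length(rows), p = ncol(X), sum = sum(X), ssq = sum(X^2))),
    class = "linear_classifier"
  )
}

predict_classifier <- function(clf, X_full) {
  codes <- svm_predict_codes(clf, X_full[, clf$selection$indices, drop = FALSE])
  clf$levels[codes + 1L]
}

default_subsets <- function(trials) {
  instr <- unique(trials$instruction)
  stats::setNames(lapply(instr, function(i) trials$instruction == i), instr)
}

#' Cross-classify test trials and score per-condition accuracy
#'
#' Applies a trained classifier to the eligible (included, unreinforced)
#' trials of a test dataset and reports percent-correct per condition
#' subset. By default one subset per instruction present in the test phase
#' (e.g. `view` and `imagine` for conditioning, `view` and `regulate` for
#' regulation). Each subset must be class-balanced in its target labels.
#'
#' @param clf A `linear_classifier`.
#' @param test An `roi_dataset` from the test phase.
#' @param subsets Optional named list of logical vectors over the test
#'   dataset's trials (eligibility is intersected automatically).
#' @return Data frame with one row per subset: `condition`, `n_correct`,
#'   `n_trials`, `accuracy` (percent).
#' @export
cross_classify <- function(clf, test, subsets = NULL) {
  stopifnot(inherits(clf, "linear_classifier"), inherits(test, "roi_dataset"))
  rows <- decoding_rows(test)
  if (is.null(subsets)) {
    subsets <- default_subsets(test$trials)
  }
  y <- target_label(test$trials)
  pred <- rep(NA_character_, nrow(test$trials))
  pred[rows] <- predict_classifier(clf, test$X[rows, , drop = FALSE])
  out <- lapply(names(subsets), function(nm) {
    use <- intersect(rows, which(subsets[[nm]]))
    counts <- table(factor(y[use], levels = CLASS_LEVELS))
    if (length(use) == 0 || counts[1] != counts[2]) {
      stop_integrity("test subset '", nm, "' is not class-balanced (",
                     paste(counts, collapse = " vs "), ")")
    }
    n_correct <- sum(pred[use] == y[use])
    data.frame(condition = nm, n_correct = n_correct, n_trials = length(use),
               accuracy = 100 * n_correct / length(use),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Positive-control gate for fragile decoding analyses
#'
#' The amygdala regulate-trial decoding (and the reverse-direction analysis
#' training on regulation view trials) is only interpreted when its
#' positive control - cross-classification of view trials - is itself
#' significant. The gate opens iff `p < alpha` (strict).
#'
#' @param view_result_p P-value of the view-trial cross-classification.
#' @param alpha Significance level (default 0.05).
#' @return TRUE to proceed, FALSE to report the gated analysis as not run.
#' @export
amygdala_gate <- function(view_result_p, alpha = 0.05) {
  stopifnot(is.numeric(view_result_p), length(view_result_p) == 1)
  view_result_p < alpha
}
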