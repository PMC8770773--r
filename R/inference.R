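#' @title Group-level permutation and bootstrap inference for decoding
#' @description
#' Decoding accuracies are tested against an empirical null built in two
#' stages. Within participant, the training labels are permuted (each
#' permutation preserves the class counts), feature selection and SVM
#' training are re-run, and the permuted model is evaluated on the fixed,
#' unpermuted test trials; repeating this `n_perm` times yields a
#' participant-level null (10,000 iterations at full study scale). At the group
#' level, `n_boot` bootstrap iterations each draw one null value per
#' participant with replacement and average them, producing a null
#' distribution of group mean accuracies. P-values are empirical with the
#' add-one rule, so they are never zero. For between-condition comparisons,
#' the same permutation sequence (fixed by the seed) is applied when
#' evaluating each condition, and the null of accuracy differences is formed
#' from the seed-paired iterations.
#' @name inference
NULL

#' Within-participant permutation null
#'
#' Iteration j permutes the training labels with the j-th seeded
#' permutation, re-runs feature selection and SVM training on the permuted
#' labels, and evaluates on the fixed test subsets. The permutation sequence
#' depends only on `(seed, n_perm, n training trials)`, so nulls computed for
#' different conditions (or test phases) of the same participant under the
#' same seed use identical permutations and are seed-paired.
#'
#' @param train,test `roi_dataset` objects (training and test phase).
#' @param K Number of features to select in every iteration.
#' @param n_perm Number of permutations (>= 1; 10,000 at full study scale).
#' @param seed Integer seed for the permutation sequence.
#' @param subsets Optional named list of logical test-trial filters, as in
#'   [cross_classify()]; defaults to one subset per instruction.
#' @return An object of class `participant_null`: list with `acc`
#'   (matrix, `n_perm` x conditions, percent), `conditions`, `n_perm`,
#'   `seed`, and `participant_id`.
#' @export
participant_null <- function(train, test, K, n_perm, seed, subsets = NULL) {
  stopifnot(inherits(train, "roi_dataset"), inherits(test, "roi_dataset"))
  if (n_perm < 1) stop_config("n_perm must be >= 1")
  n_perm <- as.integer(n_perm)

  tr_rows <- decoding_rows(train)
  Xtr <- train$X[tr_rows, , drop = FALSE]
  ytr <- factor(target_label(train$trials[tr_rows, , drop = FALSE]),
                levels = CLASS_LEVELS)
  if (nlevels(droplevels(ytr)) < 2) stop_config("training data must contain both classes")
  n_train <- length(ytr)

  te_rows <- decoding_rows(test)
  Xte <- test$X[te_rows, , drop = FALSE]
  yte <- target_label(test$trials[te_rows, , drop = FALSE])
  if (is.null(subsets)) subsets <- default_subsets(test$trials)
  sub_idx <- lapply(subsets, function(f) which(te_rows %in% which(f)))
  keep <- vapply(sub_idx, length, 0L) > 0
  sub_idx <- sub_idx[keep]
  conditions <- names(sub_idx)

  # the permutation sequence is what makes nulls comparable across
  # conditions; it must not depend on the test data
  perms <- with_seed(derive_seed(seed, "label_permutations", n_train),
                     matrix(replicate(n_perm, sample.int(n_train)), ncol = n_perm))

  y01 <- as.double(as.integer(ytr) - 1L)
  acc <- matrix(NA_real_, n_perm, length(conditions),
                dimnames = list(NULL, conditions))
  for (j in seq_len(n_perm)) {
    yp <- y01[perms[, j]]
    plus <- yp == 1
    scores <- colMeans(Xtr[plus, , drop = FALSE]) -
      colMeans(Xtr[!plus, , drop = FALSE])
    idx <- order(-scores, seq_along(scores))[seq_len(K)]
    Xs <- Xtr[, idx, drop = FALSE]
    cost <- 1 / mean(sqrt(rowSums(Xs^2)))
    fit <- svm_train_linear(Xs, yp, cost)
    codes <- svm_predict_codes(fit, Xte[, idx, drop = FALSE])
    pred <- CLASS_LEVELS[codes + 1L]
    for (s in seq_along(sub_idx)) {
      u <- sub_idx[[s]]
      acc[j, s] <- 100 * mean(pred[u] == yte[u])
    }
  }
  structure(
    list(acc = acc, conditions = conditions, n_perm = n_perm,
         seed = as.integer(seed), participant_id = train$participant_id),
    class = "participant_null"
  )
}

null_vector <- function(pn, condition = NULL) {
  stopifnot(inherits(pn, "participant_null"))
  if (is.null(condition)) {
    if (ncol(pn$acc) != 1) {
      stop_config("participant_null holds several conditions; name one of: ",
                  paste(pn$conditions, collapse = ", "))
    }
    return(pn$acc[, 1])
  }
  if (!condition %in% pn$conditions) {
    stop_config("condition '", condition, "' not present in this null")
  }
  pn$acc[, condition]
}

#' Group-level bootstrap null
#'
#' Each of the `n_boot` iterations draws, with replacement, one value from
#' every participant's null distribution and records the mean, yielding a
#' null distribution of group mean accuracies.
#'
#' @param nulls Non-empty list of `participant_null` objects (or plain
#'   numeric vectors) sharing `n_perm`.
#' @param n_boot Number of bootstrap iterations (10,000 at full study scale).
#' @param seed Integer seed.
#' @param condition Condition name to extract when the participant nulls
#'   hold several conditions.
#' @return Numeric vector of `n_boot` group mean accuracies (percent).
#' @export
group_null <- function(nulls, n_boot, seed, condition = NULL) {
  if (length(nulls) == 0) stop_config("empty participant list")
  vecs <- lapply(nulls, function(x) {
    if (inherits(x, "participant_null")) null_vector(x, condition) else as.numeric(x)
  })
  n_perm <- unique(vapply(vecs, length, 0L))
  if (length(n_perm) != 1) stop_config("participants must share n_perm")
  P <- do.call(cbind, vecs) # n_perm x participants
  n_part <- ncol(P)
  draw <- with_seed(derive_seed(seed, "group_bootstrap"),
                    matrix(sample.int(n_perm, n_boot * n_part, replace = TRUE),
                           n_boot, n_part))
  vals <- matrix(0, n_boot, n_part)
  for (i in seq_len(n_part)) vals[, i] <- P[draw[, i], i]
  rowMeans(vals)
}

#' Empirical p-value with the add-one rule
#'
#' One-tailed (greater): `p = (1 + #(null >= observed)) / (1 + n)`.
#' Two-tailed: twice the smaller tail, capped at 1. P-values are therefore
#' strictly positive and at most 1.
#'
#' @param observed Observed group statistic (percent accuracy, or an
#'   accuracy difference in percentage points).
#' @param null Numeric null distribution.
#' @param tail `"greater"`, `"less"`, or `"two.sided"`.
#' @return An object of class `permutation_test`: list with `observed`,
#'   `p`, `tail`, `n_null`.
#' @export
empirical_p <- function(observed, null, tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(length(null) >= 1, is.finite(observed))
  n <- length(null)
  p_greater <- (1 + sum(null >= observed)) / (1 + n)
  p_less <- (1 + sum(null <= observed)) / (1 + n)
  p <- switch(tail,
    greater = p_greater,
    less = p_less,
    two.sided = min(1, 2 * min(p_greater, p_less))
  )
  structure(list(observed = observed, p = p, tail = tail, n_null = n),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed = %.2f, p = %.4g (%s, n = %d)\n",
              x$observed, x$p, x$tail, x$n_null))
  invisible(x)
}

#' Group test of a decoding accuracy against chance
#'
#' Convenience wrapper: observed group accuracy is the mean of the
#' participants' observed accuracies; the null is the group bootstrap of the
#' participant permutation nulls.
#'
#' @param observed Numeric vector of per-participant observed accuracies (%).
#' @param nulls List of `participant_null` objects.
#' @param n_boot,seed Bootstrap parameters.
#' @param condition Condition to extract from the participant nulls.
#' @param tail Test tail; accuracy-vs-chance tests are one-tailed (greater)
#'   by default.
#' @return A `permutation_test`.
#' @export
group_accuracy_test <- function(observed, nulls, n_boot, seed, condition = NULL,
                                tail = "greater") {
  gn <- group_null(nulls, n_boot, seed, condition)
  empirical_p(mean(observed), gn, tail)
}

#' Seed-paired between-condition accuracy difference test
#'
#' Builds, for every permutation iteration and participant, the difference
#' between the condition-A and condition-B null accuracies (valid because
#' the two nulls share their permutation sequence), bootstrap-aggregates the
#' differences to the group level, and compares the observed group accuracy
#' difference to that null. Two-tailed by default.
#'
#' @param obs_a,obs_b Per-participant observed accuracies (%) for the two
#'   conditions, in the same participant order as the nulls.
#' @param nulls_a,nulls_b Lists of `participant_null` objects. `nulls_b`
#'   defaults to `nulls_a` (the usual case: one null object per participant
#'   holding both condition columns, seed-paired by construction). When
#'   given separately, their seeds and `n_perm` must match participant-wise.
#' @param cond_a,cond_b Condition names to extract.
#' @param n_boot,seed Bootstrap parameters.
#' @param tail Test tail (default two-sided).
#' @return An object of class `difference_test`: a `permutation_test` whose
#'   `observed` is the group accuracy difference (A - B, percentage points).
#' @export
condition_difference_test <- function(obs_a, obs_b, nulls_a, nulls_b = nulls_a,
                                      cond_a = NULL, cond_b = NULL,
                                      n_boot = 10000, seed = 1,
                                      tail = "two.sided") {
  stopifnot(length(obs_a) == length(obs_b),
            length(nulls_a) == length(nulls_b),
            length(obs_a) == length(nulls_a))
  paired <- mapply(function(a, b) {
    inherits(a, "participant_null") && inherits(b, "participant_null") &&
      a$seed == b$seed && a$n_perm == b$n_perm
  }, nulls_a, nulls_b)
  if (!all(paired)) {
    stop_integrity("condition nulls are not seed-paired; ",
                   "recompute both conditions under the same seed")
  }
  diffs <- mapply(function(a, b) null_vector(a, cond_a) - null_vector(b, cond_b),
                  nulls_a, nulls_b, SIMPLIFY = FALSE)
  gn <- group_null(diffs, n_boot, seed)
  res <- empirical_p(mean(obs_a) - mean(obs_b), gn, tail)
  class(res) <- c("difference_test", class(res))
  res
}
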