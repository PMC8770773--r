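# Thin fast path to libsvm for the permutation loops.
#
# Group-level inference retrains the classifier thousands of times per
# participant on permuted labels. e1071::svm spends most of its time in
# R-level input handling, so the package calls e1071's registered compiled
# routine `svmtrain` directly with pre-validated dense arguments
# (C-classification, linear kernel) and predicts from the explicit weight
# vector. Tests assert prediction-level equivalence with e1071::svm.

svmtrain_symbol <- local({
  sym <- NULL
  function() {
    if (is.null(sym)) {
      loadNamespace("e1071") # ensure the shared library is loaded
      sym <<- getNativeSymbolInfo("svmtrain", PACKAGE = "e1071")
    }
    sym
  }
})

# x: numeric matrix (rows = trials); y01: double vector of 0/1 class codes
# (0 = first factor level). Returns the linear decision function
# f(z) = z . w - rho, with `labels` giving the class code predicted when
# f(z) > 0 (labels[1]) vs f(z) <= 0 (labels[2]).
svm_train_linear <- function(x, y01, cost) {
  nr <- nrow(x)
  cret <- .C(svmtrain_symbol(),
    as.double(t(x)), as.integer(nr), as.integer(ncol(x)),
    as.double(y01), as.integer(0), as.integer(0),
    as.integer(0),            # type: C-classification
    as.integer(0),            # kernel: linear
    as.integer(3),            # degree (unused)
    as.double(1 / ncol(x)),   # gamma (unused for linear)
    as.double(0),             # coef0 (unused)
    as.double(cost), as.double(0.5),
    as.integer(0), as.double(0), as.integer(0), # class weights: none
    as.double(40),            # cache MB
    as.double(0.001),         # tolerance (libsvm default)
    as.double(0.1),           # epsilon (unused)
    as.integer(1),            # shrinking
    as.integer(0), as.integer(0), as.integer(0), # cross, sparse, probability
    nclasses = integer(1), nr = integer(1), index = integer(nr),
    labels = integer(2), nSV = integer(2), rho = double(1),
    coefs = double(nr), sigma = double(1), probA = double(1), probB = double(1),
    cresults = double(0), ctotal1 = double(1), ctotal2 = double(1),
    error = paste(rep(" ", 255), collapse = ""))
  nsv <- cret$nr
  idx <- cret$index[seq_len(nsv)]
  w <- drop(crossprod(x[idx, , drop = FALSE], cret$coefs[seq_len(nsv)]))
  list(w = w, rho = cret$rho, labels = cret$labels[1:2])
}

svm_decision <- function(fit, x) {
  drop(x %*% fit$w) - fit$rho
}

# predicted 0/1 class codes for test rows
svm_predict_codes <- function(fit, x) {
  d <- svm_decision(fit, x)
  ifelse(d > 0, fit$labels[1], fit$labels[2])
}
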