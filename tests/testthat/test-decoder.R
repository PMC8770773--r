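test_that("feature selection ranks by CS+ minus CS- difference with index ties", {
  X <- matrix(c(1, 1, 0, 0,   # voxel 1: diff 1
                0, 0, 0.1, 0.1), # voxel 2: diff -0.1
              nrow = 4)
  d <- make_toy_dataset(X, c("CSplus", "CSplus", "CSminus", "CSminus"))
  sel <- select_features(d, 1)
  expect_equal(sel$indices, 1L)
  expect_equal(unname(sel$scores), c(1, -0.1))

  # K = n_voxels keeps everything, regardless of sign
  expect_warning(sel_all <- select_features(d, 2), "fewer than K")
  expect_setequal(sel_all$indices, 1:2)

  # exact ties break by ascending voxel index
  Xt <- matrix(rep(c(1, 1, 0, 0), 3), nrow = 4)
  dt <- make_toy_dataset(Xt, c("CSplus", "CSplus", "CSminus", "CSminus"))
  expect_equal(select_features(dt, 2)$indices, c(1L, 2L))

  expect_error(select_features(d, 3), "exceeds")
})

test_that("selection matches the independent ranking oracle and finds signal", {
  set.seed(5)
  hits <- 0
  for (rep in 1:10) {
    n <- 24; p <- 120; signal <- 1:20
    y <- rep(c("CSplus", "CSminus"), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[y == "CSplus", signal] <- X[y == "CSplus", signal] + 1
    d <- make_toy_dataset(X, y)
    sel <- select_features(d, 30)
    expect_identical(sel$indices, oracle_rank_features(X, y, 30))
    hits <- hits + length(intersect(sel$indices, signal))
  }
  # far more signal voxels recovered than the chance rate 30/120
  expect_gt(hits / 10, 20 * 30 / 120 * 2)
})

test_that("the SVM separates separable toys and matches e1071 exactly", {
  X <- rbind(c(2, 0), c(2, 2), c(0, 0), c(0, 2))
  y <- c("CSplus", "CSplus", "CSminus", "CSminus")
  d <- make_toy_dataset(X, y)
  sel <- suppressWarnings(select_features(d, 2))
  clf <- train_classifier(d, sel)
  expect_equal(cross_classify(clf, d)$accuracy, 100)

  # duplicated training set gives the identical decision function
  d2 <- make_toy_dataset(rbind(X, X), rep(y, 2))
  clf2 <- train_classifier(d2, suppressWarnings(select_features(d2, 2)))
  expect_equal(clf$w / sqrt(sum(clf$w^2)), clf2$w / sqrt(sum(clf2$w^2)),
               tolerance = 1e-6)

  # prediction-level equivalence with e1071::svm on random data
  set.seed(31)
  for (rep in 1:20) {
    n <- 30; p <- 12
    Xr <- matrix(rnorm(n * p), n, p)
    yr <- sample(rep(c("CSplus", "CSminus"), n / 2))
    dr <- make_toy_dataset(Xr, yr)
    selr <- suppressWarnings(select_features(dr, p))
    clfr <- train_classifier(dr, selr)
    Xt <- matrix(rnorm(40 * p), 40, p)
    ours <- imagfear:::predict_classifier(clfr, Xt)
    ref <- e1071::svm(Xr, factor(yr, levels = c("CSminus", "CSplus")),
                      kernel = "linear", cost = clfr$cost, scale = FALSE)
    theirs <- as.character(predict(ref, Xt))
    expect_identical(ours, theirs)
  }
})

test_that("the learned separator matches the analytic maximum margin", {
  # classes at x1 = 2 and x1 = 0, x2 uninformative: the hard-margin separator
  # is the hyperplane x1 = 1 with weight direction (1, 0)
  X <- rbind(c(2, 0), c(2, 2), c(0, 0), c(0, 2))
  y <- c("CSplus", "CSplus", "CSminus", "CSminus")
  d <- make_toy_dataset(X, y)
  clf <- train_classifier(d, suppressWarnings(select_features(d, 2)), cost = 1000)
  w_unit <- clf$w / sqrt(sum(clf$w^2))
  expect_equal(abs(w_unit), c(1, 0), tolerance = 1e-4)
  # the decision surface crosses x1 = 1: f((1, t)) = 0
  mid <- imagfear:::svm_decision(clf, matrix(c(1, 0.7), 1))
  expect_equal(mid, 0, tolerance = 1e-4)

  expect_error(train_classifier(
    make_toy_dataset(X, rep("CSplus", 4)), structure(
      list(indices = 1:2, K = 2L, scores = c(0, 0)),
      class = "feature_selection")), "both classes|2 trials")
})

test_that("cross-classification scores subsets and enforces balance", {
  X <- rbind(c(2, 0), c(2, 2), c(0, 0), c(0, 2))
  y <- c("CSplus", "CSplus", "CSminus", "CSminus")
  d <- make_toy_dataset(X, y)
  clf <- train_classifier(d, suppressWarnings(select_features(d, 2)))

  inverted <- make_toy_dataset(X, rev(y))
  expect_equal(cross_classify(clf, inverted)$accuracy, 0)

  unbalanced <- make_toy_dataset(X[1:3, ], y[1:3])
  expect_error(cross_classify(clf, unbalanced), "not class-balanced")

  # reinforced trials never enter a decoding subset
  shocked <- d
  shocked$trials$reinforced[1] <- TRUE
  expect_error(cross_classify(clf, shocked), "not class-balanced")
})

test_that("regulate trials are scored against the viewed stimulus", {
  sch <- apply_exclusions(build_phase_schedule("regulation", 1, 4))
  lab <- target_label(sch$trials)
  reg <- sch$trials$instruction == "regulate"
  expect_identical(lab[reg], sch$trials$viewed_stimulus[reg])
  im <- apply_exclusions(build_phase_schedule("conditioning", 1, 4))$trials
  expect_identical(target_label(im)[im$instruction == "imagine"],
                   im$imagined_stimulus[im$instruction == "imagine"])
})

test_that("feature selection and training never peek at test data", {
  d <- make_signal_pair(3, n_voxels = 50, ct_runs = 2, cond_runs = 2)
  sel1 <- select_features(d$train, 20)
  clf1 <- train_classifier(d$train, sel1)
  # corrupt the test set completely
  d$test$X <- -d$test$X + 100
  d$test$trials$viewed_stimulus <- rev(d$test$trials$viewed_stimulus)
  sel2 <- select_features(d$train, 20)
  clf2 <- train_classifier(d$train, sel2)
  expect_identical(sel1$indices, sel2$indices)
  expect_identical(clf1$w, clf2$w)
  expect_identical(clf1$fingerprint, clf2$fingerprint)
})

test_that("pure-noise accuracy is binomially distributed around 50%", {
  set.seed(8)
  accs <- suppressWarnings(vapply(1:200, function(s) {
    n <- 20; p <- 15
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("CSplus", "CSminus"), each = n / 2)
    d <- make_toy_dataset(X, y)
    clf <- train_classifier(d, select_features(d, 10))
    Xt <- matrix(rnorm(12 * p), 12, p)
    dt <- make_toy_dataset(Xt, rep(c("CSplus", "CSminus"), each = 6))
    cross_classify(clf, dt)$accuracy
  }, 0.0))
  expect_equal(mean(accs), 50, tolerance = 2.5)
  expect_gt(sd(accs), 5) # per-draw accuracies scatter like binomial(12, .5)
})

test_that("the positive-control gate uses a strict threshold", {
  expect_true(amygdala_gate(0.0095))
  expect_false(amygdala_gate(0.23))
  expect_false(amygdala_gate(0.05)) # exactly alpha does not open the gate
  expect_true(amygdala_gate(0.09, alpha = 0.1))
})
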