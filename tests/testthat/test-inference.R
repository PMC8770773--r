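test_that("participant nulls are deterministic and seed-paired across conditions", {
  d <- make_noise_pair(4, n_voxels = 30, ct_runs = 2, cond_runs = 2)
  a <- participant_null(d$train, d$test, K = 10, n_perm = 25, seed = 6)
  b <- participant_null(d$train, d$test, K = 10, n_perm = 25, seed = 6)
  expect_identical(a, b)
  c <- participant_null(d$train, d$test, K = 10, n_perm = 25, seed = 7)
  expect_false(identical(a$acc, c$acc))

  # two subsets covering the same trials give identical null columns: the
  # permutation sequence (and hence the model per iteration) is shared
  im <- d$test$trials$instruction == "imagine"
  s <- participant_null(d$train, d$test, K = 10, n_perm = 25, seed = 6,
                        subsets = list(A = im, B = im))
  expect_identical(s$acc[, "A"], s$acc[, "B"])

  # computing one condition alone reproduces the same column as computing
  # both together: nulls for different conditions share permutations
  vw <- d$test$trials$instruction == "view"
  alone <- participant_null(d$train, d$test, K = 10, n_perm = 25, seed = 6,
                            subsets = list(view = vw))
  expect_identical(alone$acc[, "view"], a$acc[, "view"])

  expect_error(participant_null(d$train, d$test, 10, 0, 1), "n_perm")
})

test_that("permuted-label nulls hover at chance even for separable data", {
  d <- make_signal_pair(9, n_voxels = 60, view_gain = 3, noise_sd = 2,
                        ct_runs = 3, cond_runs = 3)
  clf <- train_classifier(d$train, suppressWarnings(select_features(d$train, 30)))
  obs <- cross_classify(clf, d$test)
  expect_gt(obs$accuracy[obs$condition == "view"], 90) # strong observed signal
  pn <- participant_null(d$train, d$test, K = 30, n_perm = 150, seed = 2)
  expect_equal(mean(pn$acc[, "view"]), 50, tolerance = 4)
})

test_that("the group bootstrap aggregates participant nulls correctly", {
  flat <- lapply(1:5, function(i) rep(50, 40))
  gn <- group_null(flat, n_boot = 100, seed = 1)
  expect_true(all(gn == 50))

  # a single participant: the null is a resample of that participant's values
  v <- c(10, 20, 30, 40)
  g1 <- group_null(list(v), n_boot = 500, seed = 2)
  expect_true(all(g1 %in% v))
  expect_setequal(unique(g1), v)

  # law of total expectation: group null mean ~ mean of participant means
  set.seed(3)
  parts <- lapply(1:8, function(i) rnorm(200, mean = 45 + i, sd = 8))
  g <- group_null(parts, n_boot = 4000, seed = 4)
  expect_equal(mean(g), mean(vapply(parts, mean, 0.0)), tolerance = 0.2)

  expect_error(group_null(list(), 10, 1), "empty")
  expect_error(group_null(list(1:10, 1:5), 10, 1), "share n_perm")
})

test_that("empirical p-values follow the add-one counting rule", {
  null <- as.numeric(1:100)
  top <- empirical_p(1000, null, "greater")
  expect_equal(top$p, 1 / 101)
  expect_equal(empirical_p(-5, null, "greater")$p, 1)
  expect_equal(empirical_p(1000, null, "less")$p, 1)
  expect_equal(empirical_p(50, null, "greater")$p, (1 + 51) / 101)
  # two-tailed: doubled smaller tail, capped at 1
  expect_equal(empirical_p(1000, null, "two.sided")$p, 2 / 101)
  expect_equal(empirical_p(50.5, null, "two.sided")$p, 1)
  # strictly positive everywhere
  expect_gt(empirical_p(1e9, null, "greater")$p, 0)
})

test_that("p-values are approximately uniform under the null", {
  # analytic check at the bootstrap level: when the observed statistic is an
  # independent draw from the same distribution as the null entries, the
  # one-tailed p is uniform up to resolution 1/(n+1)
  # with n = 99 null values the add-one rule gives p < 0.05 iff at most 3
  # null values reach the observed draw: P = 4/100; the mean p is 0.505
  set.seed(12)
  ps <- vapply(1:400, function(i) {
    null <- rnorm(99)
    empirical_p(rnorm(1), null, "greater")$p
  }, 0.0)
  expect_true(abs(mean(ps < 0.05) - 0.04) < 0.025)
  expect_true(abs(mean(ps) - 0.505) < 0.035)
})

test_that("difference tests demand seed pairing and respect symmetry", {
  d <- make_noise_pair(15, n_voxels = 30, ct_runs = 2, cond_runs = 2)
  pn <- participant_null(d$train, d$test, K = 10, n_perm = 30, seed = 3)
  d2 <- make_noise_pair(16, n_voxels = 30, ct_runs = 2, cond_runs = 2)
  pn2 <- participant_null(d2$train, d2$test, K = 10, n_perm = 30, seed = 3)
  nulls <- list(pn, pn2)
  obs_v <- c(55, 50); obs_i <- c(50, 45)

  r <- condition_difference_test(obs_v, obs_i, nulls, cond_a = "view",
                                 cond_b = "imagine", n_boot = 300, seed = 9)
  expect_equal(r$observed, 5)
  swapped <- condition_difference_test(obs_i, obs_v, nulls, cond_a = "imagine",
                                       cond_b = "view", n_boot = 300, seed = 9)
  expect_equal(swapped$observed, -5)
  expect_equal(swapped$p, r$p)

  # identical conditions: zero difference, p near 1
  same <- condition_difference_test(obs_v, obs_v, nulls, cond_a = "view",
                                    cond_b = "view", n_boot = 300, seed = 9)
  expect_equal(same$observed, 0)
  expect_gt(same$p, 0.5)

  # unpaired seeds are an integrity error
  pn_other <- participant_null(d2$train, d2$test, K = 10, n_perm = 30, seed = 4)
  expect_error(
    condition_difference_test(obs_v, obs_i, nulls, list(pn, pn_other),
                              cond_a = "view", cond_b = "imagine",
                              n_boot = 300, seed = 9),
    "seed-paired")
})

test_that("attenuated imagery is detected by the seed-paired difference test", {
  # high-SNR attenuation: view accuracy should beat imagine accuracy and the
  # difference test should reject in most simulated groups
  rejections <- suppressWarnings(vapply(1:10, function(g) {
    obs_v <- numeric(8); obs_i <- numeric(8); nulls <- vector("list", 8)
    for (i in 1:8) {
      d <- make_signal_pair(derive_seed(g, "grp", i), n_voxels = 60,
                            view_gain = 1.5, imagery_gain = 0.75,
                            noise_sd = 4, ct_runs = 6, cond_runs = 6)
      clf <- train_classifier(d$train, select_features(d$train, 30))
      acc <- cross_classify(clf, d$test)
      obs_v[i] <- acc$accuracy[acc$condition == "view"]
      obs_i[i] <- acc$accuracy[acc$condition == "imagine"]
      nulls[[i]] <- participant_null(d$train, d$test, K = 30, n_perm = 120,
                                     seed = derive_seed(g, "perm", i))
    }
    r <- condition_difference_test(obs_v, obs_i, nulls, cond_a = "view",
                                   cond_b = "imagine", n_boot = 400,
                                   seed = derive_seed(g, "boot"))
    (r$p < 0.05) && (r$observed > 0)
  }, NA))
  expect_gte(mean(rejections), 0.6)
})
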