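test_that("prototypes have equal norm and the requested correlation", {
  for (r in c(-0.5, 0, 0.3, 0.9)) {
    tr <- pattern_truth(80, prototype_cor = r, seed = 4)
    np <- sqrt(sum(tr$prototype_plus^2))
    nm <- sqrt(sum(tr$prototype_minus^2))
    expect_equal(np, nm, tolerance = 1e-12)
    expect_equal(np, sqrt(80), tolerance = 1e-12)
    expect_equal(sum(tr$prototype_plus * tr$prototype_minus) / np / nm, r,
                 tolerance = 1e-12)
  }
  expect_identical(pattern_truth(30, seed = 9)$prototype_plus,
                   pattern_truth(30, seed = 9)$prototype_plus)
  expect_error(pattern_truth(30, prototype_cor = 1), "prototype_cor")
  expect_error(pattern_truth(30, prototype_cor = -1.2), "prototype_cor")
})

test_that("roi datasets follow the mixing model in the low-noise limit", {
  sch <- apply_exclusions(build_phase_schedule("conditioning", 2, 3))
  tr <- pattern_truth(40, view_gain = 2, imagery_gain = 0, noise_sd = 1e-9,
                      participant_variability_sd = 0, seed = 1)
  ds <- simulate_roi_dataset(sch, tr, seed = 2)
  expect_equal(nrow(ds$X), nrow(sch$trials)) # rows align with the schedule
  vplus <- which(ds$trials$instruction == "view" &
                   ds$trials$viewed_stimulus == "CSplus")
  expect_equal(ds$X[vplus[1], ], 2 * tr$prototype_plus, tolerance = 1e-6)
  # imagery_gain = 0: imagine rows carry no stimulus information
  im <- which(ds$trials$instruction == "imagine")
  expect_true(max(abs(ds$X[im, ])) < 1e-6)

  # degenerate mixing: regulate trials identical in expectation to view trials
  reg_sch <- apply_exclusions(build_phase_schedule("regulation", 2, 3))
  tr2 <- pattern_truth(40, view_gain = 1, regulate_view_gain = 1,
                       regulate_imagery_gain = 0, noise_sd = 1e-9,
                       participant_variability_sd = 0, seed = 1)
  ds2 <- simulate_roi_dataset(reg_sch, tr2, seed = 2)
  t2 <- ds2$trials
  rp <- which(t2$instruction == "regulate" & t2$viewed_stimulus == "CSplus")[1]
  vp <- which(t2$instruction == "view" & t2$viewed_stimulus == "CSplus")[1]
  expect_equal(ds2$X[rp, ], ds2$X[vp, ], tolerance = 1e-6)
})

test_that("zero-gain data decode at chance on average", {
  accs <- suppressWarnings(vapply(1:100, function(s) {
    d <- make_noise_pair(s, n_voxels = 30, ct_runs = 2, cond_runs = 2)
    sel <- select_features(d$train, 10)
    clf <- train_classifier(d$train, sel)
    mean(cross_classify(clf, d$test)$accuracy)
  }, 0.0))
  expect_equal(mean(accs), 50, tolerance = 1.5) # binomial MC tolerance
})

test_that("the SCR kernel peaks at the closed-form time with unit height", {
  lat <- 1; rise <- 0.75; decay <- 2
  t_peak <- lat + rise * decay / (decay - rise) * log(decay / rise)
  tt <- seq(0, 15, by = 1e-4)
  k <- scr_kernel(tt, lat, rise, decay)
  expect_equal(max(k), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(k)], t_peak, tolerance = 1e-3)
  expect_true(all(k[tt <= lat] == 0))
})

test_that("simulated traces honour amplitudes, drift, and onsets", {
  sch <- apply_exclusions(build_phase_schedule("classifier_training", 1, 2))
  flat <- scr_truth(amplitudes = c(view_CSplus = 0, view_CSminus = 0),
                    us_amplitude = 0, baseline = 3, drift_slope = 0,
                    noise_sd = 0)
  tra <- simulate_scr(sch, flat, seed = 1)
  expect_true(all(abs(tra$samples[[1]] - 3) < 1e-12))

  # single nonzero amplitude, no noise: trace max equals amplitude + baseline
  # at the kernel's analytic peak time after the event onset
  one <- scr_truth(amplitudes = c(view_CSplus = 0.8, view_CSminus = 0),
                   us_amplitude = 0, baseline = 0, drift_slope = 0,
                   noise_sd = 0, participant_amp_sd = 0, condition_jitter_sd = 0)
  trb <- simulate_scr(sch, one, seed = 1)
  x <- trb$samples[[1]]
  expect_equal(max(x), 0.8, tolerance = 1e-3)
  onsets <- trb$onset_idx[[1]]
  t_peak <- 1 + 0.75 * 2 / (2 - 0.75) * log(2 / 0.75)
  peak_idx <- which.max(x)
  plus_onsets <- onsets[trb$trials$viewed_stimulus == "CSplus"]
  expect_true(min(abs((peak_idx - plus_onsets) / 1000 - t_peak)) < 5e-3)

  # seeds change the noise, never the onsets
  noisy <- scr_truth()
  t1 <- simulate_scr(sch, noisy, seed = 1)
  t2 <- simulate_scr(sch, noisy, seed = 2)
  expect_identical(t1$onset_idx, t2$onset_idx)
  expect_false(identical(t1$samples, t2$samples))
  expect_error(simulate_scr(apply_exclusions(build_phase_schedule("conditioning", 1, 1)),
                            scr_truth(amplitudes = c(view_CSplus = 0.1)), 1),
               "no SCR amplitude")
})

test_that("ratings are integer, clipped, and converge to their truth", {
  tr <- ratings_truth(c(a_CSplus = 7, a_CSminus = 7), sd = 0, participant_sd = 0)
  r <- simulate_ratings(tr, 10, seed = 1)
  expect_true(all(r$rating == 7))

  tr2 <- ratings_truth(c(view_CSplus = 5, view_CSminus = 2), sd = 1,
                       participant_sd = 0.3)
  big <- simulate_ratings(tr2, 4000, seed = 2)
  m <- tapply(big$rating, big$condition, mean)
  expect_equal(unname(m["view_CSplus"]), 5, tolerance = 0.1)
  expect_equal(unname(m["view_CSminus"]), 2, tolerance = 0.15) # floor clipping biases up a little
  expect_true(all(big$rating >= 1 & big$rating <= 7))
  expect_true(is.integer(big$rating))
})

test_that("seed derivation is deterministic, tag-sensitive, and 31-bit", {
  expect_identical(derive_seed(5, "a", 1), derive_seed(5, "a", 1))
  expect_false(derive_seed(5, "a", 1) == derive_seed(5, "a", 2))
  expect_false(derive_seed(5, "a") == derive_seed(6, "a"))
  seeds <- vapply(1:50, function(i) derive_seed(i, "x", i), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(length(unique(seeds)), 50)
})

test_that("group decoding accuracy rises with the signal-to-noise ratio", {
  acc_at_gain <- function(gain) {
    mean(suppressWarnings(vapply(1:12, function(s) {
      d <- make_signal_pair(s, n_voxels = 60, view_gain = gain,
                            imagery_gain = gain / 2, noise_sd = 8,
                            ct_runs = 2, cond_runs = 2)
      sel <- select_features(d$train, 30)
      clf <- train_classifier(d$train, sel)
      acc <- cross_classify(clf, d$test)
      acc$accuracy[acc$condition == "view"]
    }, 0.0)))
  }
  a0 <- acc_at_gain(0.01); a1 <- acc_at_gain(1); a2 <- acc_at_gain(3)
  expect_true(a0 <= a1 + 1e-9)
  expect_true(a1 <= a2 + 1e-9)
  expect_gt(a2, 70) # strong signal separates well above chance
})

test_that("imagery attenuation orders view above imagine accuracy", {
  accs <- suppressWarnings(vapply(1:15, function(s) {
    d <- make_signal_pair(s, n_voxels = 120, view_gain = 1, imagery_gain = 0.5,
                          noise_sd = 4, ct_runs = 6, cond_runs = 6)
    sel <- select_features(d$train, 60)
    clf <- train_classifier(d$train, sel)
    acc <- cross_classify(clf, d$test)
    c(view = acc$accuracy[acc$condition == "view"],
      imagine = acc$accuracy[acc$condition == "imagine"])
  }, c(view = 0.0, imagine = 0.0)))
  expect_gt(mean(accs["view", ]), mean(accs["imagine", ]))
})

test_that("imagining the opposite stimulus disrupts decoding of the viewed one", {
  reg_acc <- function(reg_imagery_gain) {
    mean(suppressWarnings(vapply(1:12, function(s) {
      ct <- apply_exclusions(build_phase_schedule("classifier_training", 3,
                                                  derive_seed(s, "ct")))
      reg <- apply_exclusions(build_phase_schedule("regulation", 3,
                                                   derive_seed(s, "rg")))
      g <- pattern_truth(80, view_gain = 1, regulate_view_gain = 0.7,
                         regulate_imagery_gain = reg_imagery_gain,
                         noise_sd = 6, seed = derive_seed(s, "truth"))
      tr <- participant_pattern_truth(g, "p01", derive_seed(s, "pt"))
      train <- simulate_roi_dataset(ct, tr, derive_seed(s, "train"))
      test <- simulate_roi_dataset(reg, tr, derive_seed(s, "test"))
      clf <- train_classifier(train, select_features(train, 40))
      acc <- cross_classify(clf, test)
      acc$accuracy[acc$condition == "regulate"]
    }, 0.0)))
  }
  expect_gt(reg_acc(0), reg_acc(0.7))
  expect_gt(reg_acc(0.7), reg_acc(1.4))
})
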