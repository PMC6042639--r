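make_const_stream <- function(n = 500, rate = 100, ax = 0, ay = 0, az = 9.81,
                              gx = 0, gy = 0, gz = 0) {
  imu_stream(data.frame(t = (seq_len(n) - 1) / rate, ax = ax, ay = ay,
                        az = az, gx = gx, gy = gy, gz = gz), rate_hz = rate)
}

test_that("gyro binning flags stationary and moving bins correctly", {
  quiet <- make_const_stream()
  mask <- gyro_bin_threshold(quiet)
  expect_equal(nrow(mask), 50L)
  expect_false(any(mask$moving))

  busy <- make_const_stream(gx = 1.0)  # |omega| = 2 x default threshold
  expect_true(all(gyro_bin_threshold(busy)$moving))

  expect_warning(m <- gyro_bin_threshold(make_const_stream(n = 5)),
                 "shorter than one")
  expect_equal(nrow(m), 0L)
})

test_that("stationary run covers the dwell truth within one bin width", {
  sim <- simulate_drag(raise_s = 0.5, dwell_s = 3.0, lower_s = 0.5,
                       pitch_excursion_rad = 1.4, seed = 4)
  mask <- gyro_bin_threshold(sim$stream)
  dw <- sim$events[sim$events$label == "dwell", ]
  inside <- mask$t_start >= dw$t_start + 0.1 - 1e-9 &
    mask$t_end <= dw$t_end - 0.1 + 1e-9
  expect_true(all(!mask$moving[inside]))
})

test_that("window features: zero SD on constants, count formula, shift invariance", {
  const <- make_const_stream(n = 301)
  w <- featurize_windows(const)
  expect_true(all(w$ax_sd == 0))
  expect_true(all(w$cor_ax_ay == 0))
  expect_equal(w$ax_mean, rep(0, nrow(w)))
  expect_equal(w$az_energy, rep(9.81^2, nrow(w)))

  cfg <- feature_config()
  for (n in c(21, 30, 31, 301, 1000)) {
    s <- make_const_stream(n = n)
    T_span <- (n - 1) / 100
    expect_equal(nrow(featurize_windows(s, cfg)),
                 floor((T_span - cfg$window_s) / cfg$hop_s + 1e-9) + 1)
  }

  sim <- simulate_drag(seed = 6)
  w1 <- featurize_windows(sim$stream)
  shifted <- sim$stream
  shifted$t <- shifted$t + 123.456
  w2 <- featurize_windows(imu_stream(shifted, rate_hz = 100))
  feats <- window_feature_names()
  expect_equal(as.data.frame(w2)[feats], as.data.frame(w1)[feats],
               tolerance = 1e-12)
  expect_equal(w2$t_start - w1$t_start, rep(123.456, nrow(w1)))
})

test_that("trained tree separates window classes and survives a save/load", {
  clf <- get_test_classifier()
  expect_true(all(clf$training$holdout_accuracy >= 0.90))
  expect_gt(clf$training$n_windows, 2000)

  sim <- simulate_drag(seed = 8)
  probe <- featurize_windows(sim$stream)
  path <- withr::local_tempfile(fileext = ".rds")
  write_classifier(clf, path)
  clf2 <- read_classifier(path)
  expect_identical(classify_windows(clf2, probe), classify_windows(clf, probe))
})

test_that("training on permuted labels performs at chance", {
  sim <- simulate_session(session_scenario(
    n_drags = 20, gap_range = c(8, 16), seed = 31,
    confounder_rates = c(drink_sip = 0, eat_bite = 0, walk = 0)))
  w <- featurize_windows(sim$stream)
  lab <- label_windows(w, sim$events)
  # balance classes so chance accuracy is exactly 1/3 whatever the
  # classifier's prediction marginals are
  n_per <- min(table(lab))
  idx <- unlist(lapply(levels(lab), function(l) {
    withr::with_seed(101 + match(l, levels(lab)),
                     sample(which(lab == l), n_per))
  }))
  w_bal <- w[idx, ]
  lab_perm <- withr::with_seed(202, sample(lab[idx]))
  split <- withr::with_seed(303, sample(length(idx)) <= length(idx) / 2)
  clf <- train_window_classifier(w_bal[split, ], lab_perm[split], seed = 5,
                                 holdout_frac = 0.1)
  pred <- classify_windows(clf, w_bal[!split, ])
  acc <- mean(pred$kind == as.character(lab_perm[!split]))
  n_te <- sum(!split)
  half_width <- 1.96 * sqrt((1 / 3) * (2 / 3) / n_te)
  expect_lt(abs(acc - 1 / 3), half_width + 0.05)

  expect_error(train_window_classifier(w_bal, rep("OTHER", nrow(w_bal))),
               "training error")
})

test_that("stage 1 recovers the gesture segments of a clean drag", {
  sim <- simulate_drag(raise_s = 0.5, dwell_s = 2.0, lower_s = 0.5,
                       pitch_excursion_rad = 1.4, noise_sd_accel = 0,
                       noise_sd_gyro = 0, seed = 1)
  for (clf in list(rule_window_classifier(), get_test_classifier())) {
    feats <- extract_motion_features(sim$stream, clf)
    jacc <- function(kind, lab) {
      f <- feats[feats$kind == kind, ]
      tr <- sim$events[sim$events$label == lab, ]
      expect_equal(nrow(f), 1L)
      inter <- max(0, min(f$t_end, tr$t_end) - max(f$t_start, tr$t_start))
      inter / (max(f$t_end, tr$t_end) - min(f$t_start, tr$t_start))
    }
    expect_gte(jacc("RAISE", "raise"), 0.7)
    expect_gte(jacc("DWELL", "dwell"), 0.7)
    expect_gte(jacc("LOWER", "lower"), 0.7)
    # boundaries within one hop of the truth
    for (pair in list(c("RAISE", "raise"), c("DWELL", "dwell"),
                      c("LOWER", "lower"))) {
      f <- feats[feats$kind == pair[1], ]
      tr <- sim$events[sim$events$label == pair[2], ]
      expect_lt(abs(f$t_start - tr$t_start), 0.1 + 1e-9)
      expect_lt(abs(f$t_end - tr$t_end), 0.1 + 1e-9)
    }
  }
})

test_that("idle streams yield no motion features", {
  idle <- simulate_free_living(60, rates = c(smoking = 0, drink_sip = 0,
                                             eat_bite = 0, walk = 0),
                               seed = 2)
  feats <- extract_motion_features(idle$stream, rule_window_classifier())
  expect_equal(nrow(feats), 0L)
})

test_that("two clean drags produce the six-event R,D,L,R,D,L pattern", {
  sim <- simulate_session(session_scenario(
    n_drags = 2, gaps = 30, noise_sd_accel = 0, noise_sd_gyro = 0, seed = 9))
  feats <- extract_motion_features(sim$stream, rule_window_classifier())
  expect_equal(feats$kind, c("RAISE", "DWELL", "LOWER",
                             "RAISE", "DWELL", "LOWER"))
})

test_that("stage-1 output is ordered, same-kind non-overlapping, shift invariant", {
  clf <- get_test_classifier()
  for (s in 1:4) {
    sim <- simulate_session(session_scenario(
      n_drags = 5, seed = s,
      confounder_rates = c(drink_sip = 30, eat_bite = 30, walk = 0)))
    feats <- extract_motion_features(sim$stream, clf)
    expect_false(is.unsorted(feats$t_start))
    for (k in unique(feats$kind)) {
      f <- feats[feats$kind == k, ]
      if (nrow(f) >= 2L) {
        expect_true(all(f$t_start[-1] >= f$t_end[-nrow(f)] - 1e-9))
      }
    }
  }
  sim <- simulate_drag(seed = 13)
  f1 <- extract_motion_features(sim$stream, clf)
  shifted <- sim$stream
  shifted$t <- shifted$t + 1000
  f2 <- extract_motion_features(imu_stream(shifted, rate_hz = 100), clf)
  expect_equal(f2$kind, f1$kind)
  expect_equal(f2$t_start - 1000, f1$t_start, tolerance = 1e-9)
})

test_that("a config mismatch with the training configuration is an error", {
  clf <- get_test_classifier()
  sim <- simulate_drag(seed = 3)
  expect_error(
    extract_motion_features(sim$stream, clf,
                            cfg = feature_config(window_s = 0.4, hop_s = 0.2)),
    "compatibility error")
})
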