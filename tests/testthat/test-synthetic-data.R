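test_that("noiseless drag emits truth intervals with the exact durations", {
  sim <- simulate_drag(raise_s = 0.5, dwell_s = 2.0, lower_s = 0.5,
                       pitch_excursion_rad = 1.4, noise_sd_accel = 0,
                       noise_sd_gyro = 0, seed = 1)
  ev <- sim$events
  dur <- function(lab) {
    x <- ev[ev$label == lab, ]
    x$t_end - x$t_start
  }
  expect_equal(dur("raise"), 0.5)
  expect_equal(dur("dwell"), 2.0)
  expect_equal(dur("lower"), 0.5)
  expect_equal(dur("drag"), 3.0)
})

test_that("pitch-rate channel integrates to the configured excursion", {
  for (exc in c(0.8, 1.4)) {
    sim <- simulate_drag(raise_s = 0.5, dwell_s = 1.0, lower_s = 0.6,
                         pitch_excursion_rad = exc, noise_sd_accel = 0,
                         noise_sd_gyro = 0, seed = 2)
    raise <- sim$events[sim$events$label == "raise", ]
    lower <- sim$events[sim$events$label == "lower", ]
    dt <- 1 / stream_rate(sim$stream)
    in_iv <- function(iv) sim$stream$t >= iv$t_start - 1e-9 &
      sim$stream$t < iv$t_end - 1e-9
    expect_equal(sum(sim$stream$gy[in_iv(raise)]) * dt, exc, tolerance = 0.02)
    expect_equal(sum(sim$stream$gy[in_iv(lower)]) * dt, -exc, tolerance = 0.02)
  }
})

test_that("fixed seed gives bit-identical streams and annotations", {
  a <- simulate_session(session_scenario(
    n_drags = 6, seed = 42,
    confounder_rates = c(drink_sip = 20, eat_bite = 20, walk = 0)))
  b <- simulate_session(session_scenario(
    n_drags = 6, seed = 42,
    confounder_rates = c(drink_sip = 20, eat_bite = 20, walk = 0)))
  expect_identical(as.data.frame(a$stream), as.data.frame(b$stream))
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  c <- simulate_free_living(600, seed = 7,
                            rates = c(smoking = 0, drink_sip = 30,
                                      eat_bite = 30, walk = 10))
  d <- simulate_free_living(600, seed = 7,
                            rates = c(smoking = 0, drink_sip = 30,
                                      eat_bite = 30, walk = 10))
  expect_identical(as.data.frame(c$stream), as.data.frame(d$stream))
})

test_that("truth smoking-instance labelling follows the session rule", {
  inst_count <- function(n_drags, gaps) {
    sim <- simulate_session(session_scenario(n_drags = n_drags, gaps = gaps,
                                             seed = 3))
    sum(sim$events$label == "smoking_instance")
  }
  expect_equal(inst_count(6, rep(60, 5)), 1L)
  expect_equal(inst_count(5, rep(60, 4)), 0L)
  # a 90 s start-to-start gap after the 6th drag splits the run into two
  # 6-drag runs, each its own instance
  expect_equal(inst_count(12, c(rep(60, 5), 90, rep(60, 5))), 2L)
})

test_that("free-living generator: empty rates, determinism, Poisson mean", {
  bg <- simulate_free_living(120, rates = c(smoking = 0, drink_sip = 0,
                                            eat_bite = 0, walk = 0), seed = 1)
  expect_equal(nrow(bg$events), 0L)
  expect_equal(nrow(bg$stream), 12000L)
  # background is a resting wrist: gravity on z, quiet gyroscope
  expect_equal(median(bg$stream$az), 9.81, tolerance = 0.1)
  expect_lt(sd(bg$stream$gy), 0.1)

  # instance count across seeds matches rate * duration within 3 SE
  rate_h <- 2; dur_s <- 7200
  counts <- vapply(1:100, function(s) {
    ev <- simulate_free_living(dur_s, rates = c(smoking = rate_h),
                               seed = s, signal = FALSE)$events
    sum(ev$label == "smoking_instance")
  }, 0L)
  expected <- rate_h * dur_s / 3600
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-12)
})

test_that("truth tracks are consistent: nesting, bounds, non-overlap", {
  for (s in 1:5) {
    ev <- simulate_free_living(1800, rates = c(smoking = 4, drink_sip = 20,
                                               eat_bite = 40, walk = 4),
                               seed = s, signal = FALSE)$events
    expect_true(validate_event_tracks(ev))
    drags <- ev[ev$label == "drag", ]
    for (k in seq_len(nrow(drags))) {
      inside <- function(lab) {
        sub <- ev[ev$label == lab, ]
        sum(sub$t_start >= drags$t_start[k] - 1e-9 &
              sub$t_end <= drags$t_end[k] + 1e-9)
      }
      expect_equal(inside("raise"), 1L)
      expect_equal(inside("dwell"), 1L)
      expect_equal(inside("lower"), 1L)
    }
    # default smoking templates are strictly inside the detector bounds
    raises <- ev[ev$label == "raise", ]
    dwells <- ev[ev$label == "dwell", ]
    smoking_raise <- vapply(seq_len(nrow(raises)), function(i) {
      any(abs(drags$t_start - raises$t_start[i]) < 1e-9)
    }, TRUE)
    smoking_dwell <- vapply(seq_len(nrow(dwells)), function(i) {
      any(drags$t_start < dwells$t_start[i] & drags$t_end > dwells$t_end[i] - 1e-9)
    }, TRUE)
    rd <- (raises$t_end - raises$t_start)[smoking_raise]
    dd <- (dwells$t_end - dwells$t_start)[smoking_dwell]
    expect_true(all(rd >= 0.3 & rd <= 0.7))
    expect_true(all(dd >= 0.4 & dd <= 8.0))
  }
})

test_that("impossible placements raise placement errors", {
  expect_error(
    simulate_session(session_scenario(n_drags = 6, gaps = rep(60, 5),
                                      total_duration_s = 100, seed = 1)),
    "placement error")
  expect_error(
    simulate_session(session_scenario(n_drags = 2, gaps = 0.5, seed = 1)),
    "placement error")
})
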