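test_that("event matching: identity, misses, and one-to-one double counts", {
  track <- make_drags(c(0, 10, 20, 30, 40), duration = 3)
  m <- match_events(track, track)
  expect_equal(m$tp, 5L)
  expect_length(m$fp, 0L)
  expect_length(m$fn, 0L)

  m2 <- match_events(track[0, ], track[1:3, ])
  expect_equal(m2$tp, 0L)
  expect_length(m2$fn, 3L)

  pred <- tibble::tibble(t_start = c(0, 2.1), t_end = c(2, 4))
  truth <- tibble::tibble(t_start = 1, t_end = 3.5)
  m3 <- match_events(pred, truth)
  expect_equal(m3$tp, 1L)
  expect_length(m3$fp, 1L)
  expect_length(m3$fn, 0L)
  expect_equal(m3$pairs$pred, 2L)  # larger overlap wins the pair

  expect_error(
    match_events(tibble::tibble(t_start = c(0, 1), t_end = c(2, 3)), truth),
    "input error")
})

test_that("greedy matching attains the optimal cardinality on small cases", {
  withr::with_seed(37, {
    for (rep in 1:200) {
      pred <- random_track(sample(0:6, 1), span = 40)
      truth <- random_track(sample(0:6, 1), span = 40)
      tol <- sample(c(0, 1, 5), 1)
      m <- match_events(pred, truth, tolerance_s = tol)
      expect_equal(m$tp, brute_force_match_count(pred, truth, tol),
                   info = paste("rep", rep))
      expect_equal(m$tp + length(m$fp), nrow(pred))
      expect_equal(m$tp + length(m$fn), nrow(truth))
    }
  })
})

test_that("scores follow the count definitions and flag degenerate cases", {
  rep1 <- score_match(list(tp = 6, fp = 1, fn = 2))
  expect_equal(rep1$precision, 6 / 7)
  expect_equal(rep1$recall, 0.75)
  expect_true(is.na(rep1$accuracy))

  rep2 <- score_match(list(tp = 0, fp = 0, fn = 3))
  expect_true(is.na(rep2$precision))
  expect_equal(rep2$recall, 0)

  lab <- score_match(list(tp = 6, fp = 1, fn = 2), tn = 11)
  expect_equal(lab$accuracy, (6 + 11) / 20)
  expect_error(score_match(list(tp = 1, fp = 0, fn = 0), mode = "laboratory"),
               "mode error")
  expect_error(score_match(list(tp = 1, fp = 0, fn = 0), tn = 5,
                           mode = "free_living"), "mode error")

  withr::with_seed(41, {
    for (rep in 1:50) {
      counts <- as.list(stats::setNames(sample(0:20, 3, replace = TRUE),
                                        c("tp", "fp", "fn")))
      r <- score_match(counts)
      if (counts$tp + counts$fp > 0) {
        expect_equal(r$precision, counts$tp / (counts$tp + counts$fp))
      } else {
        expect_true(is.na(r$precision))
      }
      if (counts$tp + counts$fn > 0) {
        expect_equal(r$recall, counts$tp / (counts$tp + counts$fn))
      }
    }
  })
})

test_that("Wilson intervals match the score-test oracle", {
  for (case in list(c(8, 10), c(1, 40), c(0, 15), c(25, 25))) {
    got <- wilson_ci(case[1], case[2])
    want <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-9)
  }
})

test_that("Cohen's kappa: closed-form cases and conventions", {
  expect_equal(cohens_kappa(c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1)), 1)

  # marginals 20/20 on both sides with observed agreement 20/40:
  # p_o equals p_e, so kappa is 0
  a <- rep(c(0, 1), each = 20)
  b <- c(rep(0, 10), rep(1, 10), rep(0, 10), rep(1, 10))
  expect_equal(cohens_kappa(a, b), 0)

  # 2x2 table (20,5 / 10,15): p_o = 0.7, p_e = 0.5, kappa = 0.4
  a <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(a, b), 0.4)

  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)  # degenerate identical
  expect_error(cohens_kappa(1:3, 1:4), "input error")
})

test_that("kappa agrees with an independent implementation on random tables", {
  withr::with_seed(43, {
    for (rep in 1:25) {
      n <- 60
      a <- sample(c("A", "B", "C"), n, replace = TRUE)
      b <- ifelse(runif(n) < 0.6, a, sample(c("A", "B", "C"), n, replace = TRUE))
      got <- cohens_kappa(a, b)
      want <- e1071::classAgreement(table(a, b))$kappa
      expect_equal(got, want, tolerance = 1e-12)
      expect_equal(cohens_kappa(b, a), got)  # symmetry
    }
  })
  # invariance to a label swap applied to both sequences
  a <- c(0, 0, 1, 1, 0, 1, 0)
  b <- c(0, 1, 1, 1, 0, 0, 0)
  expect_equal(cohens_kappa(1 - a, 1 - b), cohens_kappa(a, b))
})

test_that("presence bins mark overlapped bins only", {
  ev <- tibble::tibble(t_start = c(100, 1500), t_end = c(700, 1550))
  expect_equal(presence_bins(ev, 1800, bin_s = 600),
               c(TRUE, TRUE, TRUE))
  expect_equal(presence_bins(ev[0, ], 1800, bin_s = 600),
               c(FALSE, FALSE, FALSE))
  expect_equal(presence_bins(ev[2, ], 1800, bin_s = 600),
               c(FALSE, FALSE, TRUE))
})
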