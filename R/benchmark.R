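#' Simulate a laboratory-style validation session
#'
#' Scripted sequence of seated tasks mirroring a supervised validation
#' protocol: an eating bout (bites with hands/cutlery), a drinking bout
#' (sips from a glass) and, unless `include_smoking = FALSE`, one
#' smoked cigarette, separated by idle periods.
#'
#' @param seed integer seed.
#' @param include_smoking include the cigarette task.
#' @param n_bites,n_sips,n_drags event counts per task.
#' @param params gesture parameter set.
#' @param noise_sd_accel,noise_sd_gyro channel noise SDs.
#' @param rate_hz sampling rate.
#' @return list with `stream` and truth `events`.
#' @export
simulate_lab_session <- function(seed = 1, include_smoking = TRUE,
                                 n_bites = 15, n_sips = 6, n_drags = 10,
                                 params = gesture_params(),
                                 noise_sd_accel = 0.3, noise_sd_gyro = 0.05,
                                 rate_hz = 100) {
  withr::with_seed(seed, {
    sch <- empty_schedule()
    t_cur <- 10
    add_bout <- function(kind, n_ev, gap_range, t_cur) {
      for (k in seq_len(n_ev)) {
        g <- draw_gesture(kind, t_cur, params)
        sch <<- rbind(sch, g)
        t_cur <- t_cur + if (k < n_ev) {
          max(draw_range(gap_range), g$duration_s + 1)
        } else {
          g$duration_s
        }
      }
      t_cur
    }
    t_cur <- add_bout("eat_bite", n_bites, c(10, 30), t_cur) + 60
    t_cur <- add_bout("drink_sip", n_sips, c(40, 120), t_cur) + 60
    if (include_smoking) {
      t_cur <- add_bout("smoking", n_drags, c(20, 60), t_cur)
    }
    build_stream(sch, total_s = t_cur + 20, rate_hz = rate_hz,
                 noise_sd_accel = noise_sd_accel,
                 noise_sd_gyro = noise_sd_gyro)
  })
}

#' Benchmark the pipeline on simulated scenarios
#'
#' Runs simulate -> detect -> score for each seed and aggregates
#' event-matched counts at the smoking-instance level. Scenarios:
#' `"laboratory"` (eating + drinking + one cigarette per session),
#' `"confounder_only"` (the same without the cigarette) and
#' `"free_living"` (2 h of idle/walking background with Poisson-placed
#' smoking sessions and confounders, scored additionally by Cohen's
#' kappa between detected and diary smoking presence in 10-minute
#' bins, pooled across seeds).
#'
#' @param scenario scenario name.
#' @param seeds integer vector of seeds (one simulated session each).
#' @param classifier stage-1 classifier; `NULL` trains the default tree
#'   from simulated sessions using `classifier_seed`.
#' @param config a [pipeline_config()].
#' @param classifier_seed seed for default classifier training.
#' @param free_living_duration_s recording length per free-living seed.
#' @param free_living_rates events-per-hour for the free-living
#'   scenario.
#' @return a `benchmark_result`: per-seed tibble, pooled
#'   [score_match()] report and (free-living) pooled kappa.
#' @export
benchmark_pipeline <- function(scenario = c("laboratory", "confounder_only",
                                            "free_living"),
                               seeds = 1:10, classifier = NULL,
                               config = pipeline_config(),
                               classifier_seed = 99,
                               free_living_duration_s = 7200,
                               free_living_rates = c(smoking = 1,
                                                     drink_sip = 4,
                                                     eat_bite = 10,
                                                     walk = 2)) {
  scenario <- match.arg(scenario)
  if (is.null(classifier)) {
    classifier <- train_default_classifier(seed = classifier_seed,
                                           cfg = config$features)
  }
  tol <- config$evaluation$instance_tolerance_s
  bin_s <- config$evaluation$kappa_bin_s
  per_seed <- list()
  pred_bins <- logical(0); truth_bins <- logical(0)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (s in seeds) {
    sim <- switch(scenario,
      laboratory = simulate_lab_session(seed = s),
      confounder_only = simulate_lab_session(seed = s,
                                             include_smoking = FALSE),
      free_living = simulate_free_living(free_living_duration_s,
                                         rates = free_living_rates,
                                         seed = s))
    det <- detect_smoking(sim$stream, classifier, config)
    truth_inst <- filter_events(sim$events, label = "smoking_instance",
                                source = "truth")
    m <- match_events(det$instances, truth_inst, tolerance_s = tol)
    tp <- tp + m$tp; fp <- fp + length(m$fp); fn <- fn + length(m$fn)
    per_seed[[length(per_seed) + 1L]] <- tibble::tibble(
      seed = s, n_truth = nrow(truth_inst), n_detected = nrow(det$instances),
      tp = m$tp, fp = length(m$fp), fn = length(m$fn))
    if (scenario == "free_living") {
      dur <- sim$stream$t[nrow(sim$stream)] + 1 / stream_rate(sim$stream)
      pred_bins <- c(pred_bins, presence_bins(det$instances, dur, bin_s))
      truth_bins <- c(truth_bins, presence_bins(truth_inst, dur, bin_s))
    }
  }
  pooled <- score_match(list(tp = tp, fp = fp, fn = fn))
  kappa <- if (scenario == "free_living") {
    cohens_kappa(pred_bins, truth_bins)
  } else NA_real_
  structure(list(scenario = scenario, per_seed = do.call(rbind, per_seed),
                 pooled = pooled, kappa = kappa),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> scenario=%s seeds=%d\n", x$scenario,
              nrow(x$per_seed)))
  print(x$pooled)
  if (!is.na(x$kappa)) cat(sprintf("  kappa (binned presence) %.3f\n", x$kappa))
  invisible(x)
}
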