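#' Stage-1 feature-extraction configuration
#'
#' Parameters for turning a uniform IMU stream into discrete motion
#' features: accelerometer analysis windows feed the window classifier
#' (RAISE / LOWER / OTHER), while the gyroscope is binned and
#' thresholded into a moving/stationary mask from which DWELL (hand
#' stationary at mouth) events are derived.
#'
#' @param window_s analysis window length in seconds.
#' @param hop_s hop between window starts in seconds (`<= window_s`).
#' @param gyro_bin_s gyroscope bin width in seconds.
#' @param gyro_threshold_rad_s angular-rate magnitude threshold (rad/s)
#'   separating moving from stationary bins.
#' @param min_dwell_quiet_s minimum continuous stationary span (seconds)
#'   required to open a DWELL event.
#' @param dwell_pitch_min_rad minimum gravity-estimated wrist pitch
#'   (radians) over a stationary run for it to count as
#'   hand-stationary-at-mouth rather than a resting hand.
#' @return a `feature_config` list.
#' @export
feature_config <- function(window_s = 0.2, hop_s = 0.1, gyro_bin_s = 0.1,
                           gyro_threshold_rad_s = 0.5,
                           min_dwell_quiet_s = 0.3,
                           dwell_pitch_min_rad = 0.6) {
  vals <- c(window_s, hop_s, gyro_bin_s, gyro_threshold_rad_s,
            min_dwell_quiet_s, dwell_pitch_min_rad)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("parameter error: all feature_config values must be positive",
         call. = FALSE)
  }
  if (hop_s > window_s) {
    stop("parameter error: hop_s must not exceed window_s", call. = FALSE)
  }
  structure(list(window_s = window_s, hop_s = hop_s, gyro_bin_s = gyro_bin_s,
                 gyro_threshold_rad_s = gyro_threshold_rad_s,
                 min_dwell_quiet_s = min_dwell_quiet_s,
                 dwell_pitch_min_rad = dwell_pitch_min_rad),
            class = "feature_config")
}

#' Gyroscope binning and stationarity threshold
#'
#' Splits the stream into consecutive bins of `gyro_bin_s` and flags a
#' bin as moving when the mean angular-rate magnitude
#' `sqrt(gx^2 + gy^2 + gz^2)` reaches `gyro_threshold_rad_s`. Per-bin
#' mean accelerometer values are carried along so downstream code can
#' estimate the gravity pitch of stationary spans.
#'
#' @param stream a uniform [imu_stream()].
#' @param cfg a [feature_config()].
#' @return tibble with one row per bin: `t_start`, `t_end`, `moving`,
#'   `omega_mean`, `ax_mean`, `az_mean`. Empty (with a warning) when the
#'   stream is shorter than one bin.
#' @export
gyro_bin_threshold <- function(stream, cfg = feature_config()) {
  rate <- stream_rate(stream)
  bw <- max(1L, round(cfg$gyro_bin_s * rate))
  n <- nrow(stream)
  n_bin <- n %/% bw
  if (n_bin < 1L) {
    warning("stream shorter than one gyroscope bin; empty mask")
    return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                          moving = logical(), omega_mean = numeric(),
                          ax_mean = numeric(), az_mean = numeric()))
  }
  used <- n_bin * bw
  grp <- rep(seq_len(n_bin), each = bw)
  omega <- sqrt(stream$gx[1:used]^2 + stream$gy[1:used]^2 +
                  stream$gz[1:used]^2)
  om <- tapply_mean(omega, grp, n_bin)
  t0 <- stream$t[1L]
  tibble::tibble(
    t_start = t0 + (seq_len(n_bin) - 1L) * bw / rate,
    t_end = t0 + seq_len(n_bin) * bw / rate,
    moving = om >= cfg$gyro_threshold_rad_s,
    omega_mean = om,
    ax_mean = tapply_mean(stream$ax[1:used], grp, n_bin),
    az_mean = tapply_mean(stream$az[1:used], grp, n_bin))
}

tapply_mean <- function(x, grp, ngrp) {
  as.numeric(rowsum(x, grp, reorder = TRUE)) / tabulate(grp, ngrp)
}

FEATURE_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")
FEATURE_STATS <- c("mean", "sd", "min", "max", "energy")
FEATURE_CORS <- list(c("ax", "ay"), c("ax", "az"), c("ay", "az"),
                     c("gx", "gy"), c("gx", "gz"), c("gy", "gz"))

#' Feature names used by the window classifier, in fixed order
#' @return character vector of feature column names.
#' @export
window_feature_names <- function() {
  c(as.vector(t(outer(FEATURE_CHANNELS, FEATURE_STATS, paste, sep = "_"))),
    vapply(FEATURE_CORS, function(p) paste0("cor_", p[1L], "_", p[2L]), ""))
}

#' Sliding-window summary features
#'
#' Cuts the stream into windows of `window_s` advanced by `hop_s` and
#' computes, per window and channel, mean, standard deviation, min, max
#' and energy (mean square), plus within-window Pearson correlations for
#' the accelerometer and gyroscope axis pairs (0 when a channel is
#' constant). Window positions are relative to the first sample, so the
#' features are invariant to shifting all timestamps by a constant.
#'
#' @param stream a uniform [imu_stream()].
#' @param cfg a [feature_config()].
#' @return tibble with `t_start`, `t_end`, `t_center` and one column per
#'   feature in [window_feature_names()] order; zero rows when the
#'   stream is shorter than one window.
#' @export
featurize_windows <- function(stream, cfg = feature_config()) {
  rate <- stream_rate(stream)
  w <- max(1L, round(cfg$window_s * rate))   # window spans w+1 samples
  h <- max(1L, round(cfg$hop_s * rate))
  n <- nrow(stream)
  n_win <- if (n - 1L >= w) (n - 1L - w) %/% h + 1L else 0L
  empty <- tibble::as_tibble(
    c(list(t_start = numeric(), t_end = numeric(), t_center = numeric()),
      stats::setNames(rep(list(numeric()), length(window_feature_names())),
                      window_feature_names())))
  if (n_win < 1L) return(empty)
  starts <- (seq_len(n_win) - 1L) * h
  idx <- outer(starts, seq_len(w + 1L), `+`)  # n_win x (w+1) sample indices
  m <- w + 1L
  mom <- lapply(stream[FEATURE_CHANNELS], function(x) {
    M <- matrix(x[idx], n_win, m)
    mu <- rowMeans(M)
    mu2 <- rowMeans(M * M)
    v <- pmax(mu2 - mu * mu, 0)
    list(M = M, mean = mu, energy = mu2, var = v,
         sd = sqrt(v * m / (m - 1L)),
         min = do.call(pmin, lapply(seq_len(m), function(j) M[, j])),
         max = do.call(pmax, lapply(seq_len(m), function(j) M[, j])))
  })
  out <- vector("list", length(window_feature_names()))
  names(out) <- window_feature_names()
  for (ch in FEATURE_CHANNELS) {
    for (st in FEATURE_STATS) out[[paste(ch, st, sep = "_")]] <- mom[[ch]][[st]]
  }
  for (p in FEATURE_CORS) {
    a <- mom[[p[1L]]]; b <- mom[[p[2L]]]
    cov_ab <- rowMeans(a$M * b$M) - a$mean * b$mean
    denom <- sqrt(a$var * b$var)
    r <- ifelse(denom > 0, cov_ab / denom, 0)
    out[[paste0("cor_", p[1L], "_", p[2L])]] <- pmin(pmax(r, -1), 1)
  }
  t0 <- stream$t[1L]
  tibble::as_tibble(c(list(t_start = t0 + starts / rate,
                           t_end = t0 + (starts + w) / rate,
                           t_center = t0 + (starts + w / 2) / rate),
                      out))
}

#' Label windows from truth annotations
#'
#' Assigns each window the kind of the truth interval containing its
#' centre: `RAISE` for `raise` intervals, `LOWER` for `lower` intervals,
#' `OTHER` everywhere else (including dwells, which stage 1 detects from
#' the gyroscope mask, not the classifier).
#'
#' @param windows output of [featurize_windows()].
#' @param truth truth [event_intervals()].
#' @return factor of window kinds.
#' @export
label_windows <- function(windows, truth) {
  kind <- rep("OTHER", nrow(windows))
  for (map in list(c("raise", "RAISE"), c("lower", "LOWER"))) {
    iv <- filter_events(truth, label = map[1L], source = "truth")
    if (nrow(iv) == 0L) next
    iv <- iv[order(iv$t_start), ]
    pos <- findInterval(windows$t_center, iv$t_start)
    hit <- pos > 0L & windows$t_center < iv$t_end[pmax(pos, 1L)]
    kind[hit] <- map[2L]
  }
  factor(kind, levels = c("RAISE", "LOWER", "OTHER"))
}

#' Train the stage-1 window classifier
#'
#' Fits a depth-limited CART decision tree (via \pkg{rpart}) mapping
#' per-window accelerometer/gyroscope summary features to
#' RAISE / LOWER / OTHER, holding out a fraction of windows to report
#' per-class accuracy. Deterministic given `seed`.
#'
#' @param windows feature table from [featurize_windows()].
#' @param labels factor/character of window kinds (>= 2 classes).
#' @param max_depth maximum tree depth.
#' @param seed integer seed controlling the holdout split.
#' @param holdout_frac fraction of windows held out for accuracy
#'   reporting.
#' @param cfg the [feature_config()] the windows were computed with;
#'   embedded so detection can verify compatibility.
#' @return a `window_classifier` object.
#' @export
train_window_classifier <- function(windows, labels, max_depth = 6, seed = 1,
                                    holdout_frac = 0.25,
                                    cfg = feature_config()) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training error: need at least 2 classes in labels", call. = FALSE)
  }
  feats <- window_feature_names()
  df <- as.data.frame(windows)[feats]
  df$.kind <- droplevels(labels)
  withr::with_seed(seed, {
    n <- nrow(df)
    ho <- sample.int(n, size = max(1L, floor(holdout_frac * n)))
    fit <- rpart::rpart(.kind ~ ., data = df[-ho, ], method = "class",
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = 1e-3, minsplit = 20,
                          xval = 0))
    pred <- predict(fit, df[ho, , drop = FALSE], type = "class")
    tab <- table(truth = df$.kind[ho], pred = pred)
    per_class <- diag(tab) / pmax(rowSums(tab), 1L)
  })
  structure(list(model = fit, config = cfg, feature_names = feats,
                 classes = levels(df$.kind),
                 training = list(seed = seed, n_windows = nrow(df),
                                 max_depth = max_depth,
                                 holdout_accuracy = per_class),
                 version = 1L),
            class = "window_classifier")
}

#' Rule-based fallback window classifier
#'
#' Classifies a window as RAISE when the mean wrist pitch rate
#' (`gy_mean`) reaches `pitch_rate_threshold`, LOWER when it is below
#' its negative, OTHER otherwise. A transparent, training-free stand-in
#' for the decision tree, usable when no labelled windows are at hand.
#'
#' @param cfg the [feature_config()] the classifier operates under.
#' @param pitch_rate_threshold mean pitch-rate threshold in rad/s.
#' @return a `rule_classifier` object.
#' @export
rule_window_classifier <- function(cfg = feature_config(),
                                   pitch_rate_threshold = 0.5) {
  stopifnot(pitch_rate_threshold > 0)
  structure(list(config = cfg, pitch_rate_threshold = pitch_rate_threshold,
                 classes = c("RAISE", "LOWER", "OTHER"), version = 1L),
            class = "rule_classifier")
}

#' Classify feature windows
#' @param classifier a `window_classifier` or `rule_classifier`.
#' @param windows feature table from [featurize_windows()].
#' @return tibble with `kind` and `score` (confidence in `[0, 1]`).
#' @export
classify_windows <- function(classifier, windows) {
  UseMethod("classify_windows")
}

#' @export
classify_windows.window_classifier <- function(classifier, windows) {
  if (nrow(windows) == 0L) {
    return(tibble::tibble(kind = character(), score = numeric()))
  }
  prob <- predict(classifier$model,
                  as.data.frame(windows)[classifier$feature_names],
                  type = "prob")
  j <- max.col(prob, ties.method = "first")
  tibble::tibble(kind = colnames(prob)[j], score = prob[cbind(seq_len(nrow(prob)), j)])
}

#' @export
classify_windows.rule_classifier <- function(classifier, windows) {
  thr <- classifier$pitch_rate_threshold
  kind <- ifelse(windows$gy_mean >= thr, "RAISE",
                 ifelse(windows$gy_mean <= -thr, "LOWER", "OTHER"))
  tibble::tibble(kind = kind, score = rep(1, nrow(windows)))
}

#' Save / load a window classifier
#'
#' Versioned on-disk artifact with the training [feature_config()]
#' embedded; a reloaded classifier gives identical predictions.
#'
#' @param classifier a classifier object.
#' @param path file path.
#' @return `path` (write) or the classifier (read).
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, c("window_classifier", "rule_classifier")))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("window_classifier", "rule_classifier"))) {
    stop("classifier artifact error: unrecognised object in ", path,
         call. = FALSE)
  }
  obj
}

#' Train a classifier on freshly simulated sessions
#'
#' Convenience wrapper: simulates a few dense smoking sessions with
#' drinking/eating/walking confounders, labels the windows from truth,
#' balances the OTHER class down to three times the RAISE count, and
#' fits [train_window_classifier()].
#'
#' @param seed integer seed (drives both simulation and training).
#' @param cfg a [feature_config()].
#' @param n_sessions number of training sessions to simulate.
#' @param max_depth tree depth limit.
#' @return a `window_classifier`.
#' @export
train_default_classifier <- function(seed = 1, cfg = feature_config(),
                                     n_sessions = 3, max_depth = 6) {
  wins <- list(); labs <- list()
  for (k in seq_len(n_sessions)) {
    # a dense drag run with hand-to-mouth confounders, plus a separate
    # background recording with walking bouts (walks need open time that
    # a dense drag run does not leave)
    sims <- list(
      simulate_session(session_scenario(
        n_drags = 20, gap_range = c(8, 16),
        confounder_rates = c(drink_sip = 30, eat_bite = 60, walk = 0),
        seed = seed * 1000L + k)),
      simulate_free_living(600, rates = c(smoking = 0, drink_sip = 20,
                                          eat_bite = 40, walk = 12),
                           seed = seed * 1000L + 500L + k))
    for (sim in sims) {
      w <- featurize_windows(sim$stream, cfg)
      wins[[length(wins) + 1L]] <- w
      labs[[length(labs) + 1L]] <- label_windows(w, sim$events)
    }
  }
  windows <- do.call(rbind, wins)
  labels <- factor(unlist(lapply(labs, as.character)),
                   levels = c("RAISE", "LOWER", "OTHER"))
  keep <- withr::with_seed(seed + 7L, {
    is_other <- labels == "OTHER"
    n_keep <- min(sum(is_other), 3L * sum(labels == "RAISE"))
    c(which(!is_other), sample(which(is_other), n_keep))
  })
  train_window_classifier(windows[keep, ], labels[keep],
                          max_depth = max_depth, seed = seed, cfg = cfg)
}

#' Extract motion-feature events (stage 1)
#'
#' Runs the window classifier over the stream and merges consecutive
#' same-label windows (adjacent hops) into RAISE / LOWER events whose
#' bounds are the merged window centres padded by half a hop. DWELL
#' (hand stationary at mouth) events come from the gyroscope
#' stationarity mask: maximal stationary runs of at least
#' `min_dwell_quiet_s` whose gravity-estimated pitch is at least
#' `dwell_pitch_min_rad` (a resting hand is stationary but not at the
#' mouth, so it is not a dwell).
#'
#' @param stream a uniform [imu_stream()].
#' @param classifier a trained `window_classifier` or a
#'   `rule_classifier`.
#' @param cfg a [feature_config()]; defaults to the classifier's
#'   embedded config and must agree with it on `window_s` and `hop_s`.
#' @param include_other also emit merged OTHER events (default off).
#' @return tibble of motion-feature events: `kind`, `t_start`, `t_end`,
#'   `score`, ordered by `t_start`; same-kind events never overlap.
#' @export
extract_motion_features <- function(stream, classifier, cfg = NULL,
                                    include_other = FALSE) {
  if (is.null(cfg)) cfg <- classifier$config
  if (is.null(cfg)) cfg <- feature_config()
  tc <- classifier$config
  if (!is.null(tc) &&
      (abs(tc$window_s - cfg$window_s) > 1e-9 ||
       abs(tc$hop_s - cfg$hop_s) > 1e-9)) {
    stop("compatibility error: feature_config window_s/hop_s differ from ",
         "the classifier's training configuration", call. = FALSE)
  }
  empty <- tibble::tibble(kind = character(), t_start = numeric(),
                          t_end = numeric(), score = numeric())
  windows <- featurize_windows(stream, cfg)
  events <- empty
  if (nrow(windows) > 0L) {
    pred <- classify_windows(classifier, windows)
    r <- rle(pred$kind)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    events <- tibble::tibble(
      kind = r$values,
      t_start = windows$t_center[starts] - cfg$hop_s / 2,
      t_end = windows$t_center[stops] + cfg$hop_s / 2,
      score = vapply(seq_along(starts), function(i) {
        mean(pred$score[starts[i]:stops[i]])
      }, 0))
    if (!include_other) events <- events[events$kind != "OTHER", ]
  }
  mask <- suppressWarnings(gyro_bin_threshold(stream, cfg))
  if (nrow(mask) > 0L && any(!mask$moving)) {
    r <- rle(!mask$moving)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    quiet <- which(r$values)
    dw <- lapply(quiet, function(i) {
      i0 <- starts[i]; i1 <- stops[i]
      dur <- mask$t_end[i1] - mask$t_start[i0]
      pitch <- atan2(mean(mask$ax_mean[i0:i1]), mean(mask$az_mean[i0:i1]))
      if (dur >= cfg$min_dwell_quiet_s - 1e-9 &&
          pitch >= cfg$dwell_pitch_min_rad) {
        tibble::tibble(kind = "DWELL", t_start = mask$t_start[i0],
                       t_end = mask$t_end[i1], score = 1)
      } else NULL
    })
    dw <- do.call(rbind, dw[!vapply(dw, is.null, TRUE)])
    if (!is.null(dw)) events <- rbind(events, dw)
  }
  if (nrow(events) == 0L) return(empty)
  events[order(events$t_start, events$t_end), ]
}
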